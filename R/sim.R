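# Synthetic pan-genome generator with known ground truth.
#
# Emulates, at desk scale, the statistical structure the analysis modules
# assume: (a) a families x accessions presence/absence matrix with
# configurable core/softcore/dispensable/private proportions, (b) homology
# hit tables with planted orthogroup over-splits (to exercise fusion) and
# gene-model split artifacts (to exercise split/merge flagging), (c)
# per-accession synteny-block annotations on a shared reference coordinate
# system with planted inversions, indels and non-syntenic centromeres, and
# (d) tandem satellite arrays plus noisy depth tracks feeding the
# depth-ratio repeat-length estimator.  Everything is driven by one seed
# through fixed per-component substreams, so outputs are byte-identical
# across runs.

# Synthetic stand-in consensus for the ~178-bp centromeric satellite
# monomer (AT-rich random sequence; real satellite consensus not required
# by any algorithm here).
MOTIF_CEN_DEFAULT <- paste0(
  "GTCTTTGGAAATTAGTCTACGTTCAGTTCACGGAACGAGTCTTCTATCATTGCATGTAGACACATCTAGG",
  "TTATCCTATCCTATGTGCAATTGGAGTCTTTCCAAGTCGTACTAAATACTGGTTTTAAATTAAATTATTA",
  "CAAGTGGGGTTTCTGAGATGAGCTATTGCTCACCTTTA")

# Plant telomeric repeat unit.
MOTIF_TEL_DEFAULT <- "TTTAGGG"

# per-component substream seeds derived from the one user seed
.sub_seed <- function(seed, component) {
  offset <- match(component,
                  c("pav", "homology", "synteny", "repeats", "fusion",
                    "pipeline"))
  (as.integer(seed) %% 214748L) * 10000L + offset
}

#' Configuration for the synthetic pan-genome generator
#'
#' Defaults mirror the study conditions the package targets: 69 accessions,
#' category proportions 60/5/17/18% (core/softcore/dispensable/private), a
#' five-chromosome reference with centromere spans, rare megabase arm
#' inversions including one inversion shared by 8 accessions, a 178-bp
#' centromeric and 7-bp telomeric motif, and 30x short-read depth.
#' Sequence-bearing components (repeat arrays, depth tracks) are generated
#' at reduced per-chromosome background lengths so the whole pipeline runs
#' in seconds; coordinate-only components (synteny blocks) use full-length
#' chromosomes since intervals cost nothing.
#'
#' @param n_accessions Number of accessions (default 69).
#' @param n_families Number of gene families (default 5000).
#' @param category_props Named fractions (core, softcore, dispensable,
#'   private) summing to 1.
#' @param split_merge_rate Fraction of multi-accession families planted as
#'   gene-model split artifacts.
#' @param fuse_rate Fraction of multi-accession families planted as
#'   over-split orthogroup pairs joined by a qualifying reciprocal best
#'   hit.
#' @param near_miss_rate Fraction of families given a sub-threshold
#'   (coverage 0.94) cross-family hit that must not trigger fusion.
#' @param ref_chrom_lengths Named bp lengths of reference chromosomes.
#' @param centromere_spans Data.frame `chrom`, `start`, `end` of centromere
#'   intervals (reference coordinates).
#' @param inversion_rate_per_genome Expected private arm inversions per
#'   accession (Poisson).
#' @param inversion_size_range Min/max private inversion size in bp.
#' @param indel_rate_per_genome Expected indels per accession (Poisson).
#' @param indel_size_max Maximum indel size in bp (minimum is 20).
#' @param shared_inversion List `chrom`, `start`, `length`, `n_carriers`
#'   describing one inversion shared by a subset of accessions; `NULL`
#'   disables it.
#' @param motif_cen Centromeric satellite monomer sequence (178 bp
#'   default).
#' @param motif_tel Telomeric repeat unit (7 bp default).
#' @param copy_range Min/max centromeric motif copies per chromosome.
#' @param tel_copies Telomeric motif copies appended at each sequence end.
#' @param motif_divergence Per-copy i.i.d. substitution rate of the
#'   satellite (default 0.05).
#' @param size_coupling_noise_sd SD (bp) of Gaussian noise added to the
#'   linear genome-size/repeat-content coupling.
#' @param background_length Non-repeat background bp per chromosome in the
#'   sequence-level simulation.
#' @param depth_mean Mean short-read fold-coverage.
#' @param multi_copy_rate Fraction of presence cells given gene count 2
#'   instead of 1.
#' @param seed Integer master seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accessions = 69L,
                       n_families = 5000L,
                       category_props = c(core = 0.60, softcore = 0.05,
                                          dispensable = 0.17, private = 0.18),
                       split_merge_rate = 0.05,
                       fuse_rate = 0.02,
                       near_miss_rate = 0.02,
                       ref_chrom_lengths = c(Chr1 = 30e6, Chr2 = 20e6,
                                             Chr3 = 23e6, Chr4 = 18e6,
                                             Chr5 = 27e6),
                       centromere_spans = data.frame(
                         chrom = c("Chr1", "Chr2", "Chr3", "Chr4", "Chr5"),
                         start = c(14e6, 2e6, 12e6, 2.8e6, 11e6),
                         end   = c(17e6, 5e6, 15e6, 5.5e6, 14e6)),
                       inversion_rate_per_genome = 0.1,
                       inversion_size_range = c(1e6, 2.4e6),
                       indel_rate_per_genome = 20,
                       indel_size_max = 10000,
                       shared_inversion = list(chrom = "Chr4", start = 1.5e6,
                                               length = 1.2e6, n_carriers = 8L),
                       motif_cen = MOTIF_CEN_DEFAULT,
                       motif_tel = MOTIF_TEL_DEFAULT,
                       copy_range = c(100L, 500L),
                       tel_copies = 30L,
                       motif_divergence = 0.05,
                       size_coupling_noise_sd = 2000,
                       background_length = 20000L,
                       depth_mean = 30,
                       multi_copy_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_families = as.integer(n_families),
              category_props = category_props,
              split_merge_rate = split_merge_rate,
              fuse_rate = fuse_rate,
              near_miss_rate = near_miss_rate,
              ref_chrom_lengths = ref_chrom_lengths,
              centromere_spans = centromere_spans,
              inversion_rate_per_genome = inversion_rate_per_genome,
              inversion_size_range = inversion_size_range,
              indel_rate_per_genome = indel_rate_per_genome,
              indel_size_max = indel_size_max,
              shared_inversion = shared_inversion,
              motif_cen = toupper(motif_cen),
              motif_tel = toupper(motif_tel),
              copy_range = as.integer(copy_range),
              tel_copies = as.integer(tel_copies),
              motif_divergence = motif_divergence,
              size_coupling_noise_sd = size_coupling_noise_sd,
              background_length = as.integer(background_length),
              depth_mean = depth_mean,
              multi_copy_rate = multi_copy_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` (or plain list with the same fields).
#' @return The config, invisibly; stops on any violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  p <- cfg$category_props
  if (length(p) != 4L ||
      !setequal(names(p), c("core", "softcore", "dispensable", "private")))
    stop("category_props must name core, softcore, dispensable, private")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("category_props must be non-negative and sum to 1 (got sum ",
         format(sum(p), digits = 15), ")")
  if (cfg$n_accessions < 3L) stop("need at least 3 accessions")
  if (any(cfg$ref_chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  cs <- cfg$centromere_spans
  if (nrow(cs)) {
    bad <- cs$start < 1 | cs$end > cfg$ref_chrom_lengths[cs$chrom] |
      cs$start > cs$end
    if (any(bad)) stop("centromere span(s) outside chromosome bounds")
  }
  for (m in c(cfg$motif_cen, cfg$motif_tel))
    if (!grepl("^[ACGT]+$", m)) stop("motifs must be plain A/C/G/T DNA")
  if (!is.null(cfg$shared_inversion)) {
    si <- cfg$shared_inversion
    if (si$start + si$length - 1 > cfg$ref_chrom_lengths[[si$chrom]])
      stop("shared inversion extends beyond its chromosome")
  }
  # a private inversion must fit on some chromosome arm
  arm_max <- max(vapply(names(cfg$ref_chrom_lengths), function(ch) {
    len <- cfg$ref_chrom_lengths[[ch]]
    cen <- cfg$centromere_spans[cfg$centromere_spans$chrom == ch, ]
    if (!nrow(cen)) return(len)
    max(cen$start[[1L]] - 1, len - cen$end[[1L]])
  }, numeric(1)))
  if (cfg$inversion_rate_per_genome > 0 &&
      cfg$inversion_size_range[[1L]] > arm_max)
    stop("minimum inversion size exceeds the longest chromosome arm")
  invisible(cfg)
}

.acc_names <- function(n) sprintf("Acc%03d", seq_len(n))
# sample from the elements of x (safe for length-1 x, unlike sample())
.resample <- function(x, n, replace = TRUE) {
  x[sample.int(length(x), n, replace = replace)]
}
.fam_names <- function(n) sprintf("FAM%05d", seq_len(n))

#' Simulate a presence/absence matrix with known category labels
#'
#' Families are assigned categories by a multinomial draw from
#' `category_props`.  Core families are present in all accessions; softcore
#' in a uniform-random count strictly above `0.9 n` and below n;
#' dispensable in a uniform-random count in `[2, floor(0.9 n)]`; private in
#' exactly one (uniform-random) accession.  A small fraction of presence
#' cells carry gene count 2 (`multi_copy_rate`).
#'
#' @param config A [sim_config()].
#' @return List with `pav` (integer matrix) and `truth` (list with
#'   `family_category`, `presence_count`).
#' @export
simulate_pav <- function(config) {
  validate_sim_config(config)
  n <- config$n_accessions
  nf <- config$n_families
  b <- category_bounds(n, pan_rules(0.9))
  p <- config$category_props[c("core", "softcore", "dispensable", "private")]
  if (p[["softcore"]] > 0 && b$softcore_min > b$softcore_max)
    stop("softcore range is empty at n = ", n,
         "; set softcore proportion to 0")
  set.seed(.sub_seed(config$seed, "pav"))
  cats <- sample(names(p), nf, replace = TRUE, prob = p)
  m <- integer(nf)
  m[cats == "core"] <- n
  m[cats == "private"] <- 1L
  ns <- sum(cats == "softcore")
  if (ns) m[cats == "softcore"] <-
      .resample(seq.int(b$softcore_min, b$softcore_max), ns)
  nd <- sum(cats == "dispensable")
  if (nd) m[cats == "dispensable"] <-
      .resample(seq.int(2L, b$dispensable_max), nd)
  pav <- matrix(0L, nf, n, dimnames = list(.fam_names(nf), .acc_names(n)))
  for (i in seq_len(nf)) {
    cols <- if (m[i] == n) seq_len(n) else sample.int(n, m[i])
    pav[i, cols] <- 1L
  }
  if (config$multi_copy_rate > 0) {
    pres <- which(pav == 1L)
    extra <- pres[stats::runif(length(pres)) < config$multi_copy_rate]
    pav[extra] <- 2L
  }
  truth <- list(family_category = stats::setNames(cats, rownames(pav)),
                presence_count = stats::setNames(m, rownames(pav)))
  list(pav = pav, truth = truth)
}

#' Simulate gene models and homology hits over a presence/absence matrix
#'
#' Produces the orthogroup table, per-accession gene models (adjacent gene
#' order along one scaffold) and a homology hit table, with three kinds of
#' planted structure: (i) split artifacts — in a flagged family, one
#' accession's gene is replaced by two adjacent genes each covering less
#' than 95% of the family representative but jointly at least 95%; (ii)
#' over-split orthogroups — a flagged family is written as two orthogroups
#' joined by a reciprocal best hit at >= 95% bidirectional coverage, so
#' fusion must merge them; (iii) near misses — cross-family hits at
#' coverage 0.94 that must not fuse.
#'
#' @param sim Result of [simulate_pav()].
#' @param config The same [sim_config()].
#' @return List with `og` (`og_table`, including planted over-splits),
#'   `hits`, `gene_models`, and `truth` extended with `split_merge_flag`,
#'   `fused_pairs`, `near_miss_pairs`.
#' @export
simulate_homology <- function(sim, config) {
  set.seed(.sub_seed(config$seed, "homology"))
  pav <- sim$pav
  truth <- sim$truth
  nf <- nrow(pav)
  accs <- colnames(pav)
  fams <- rownames(pav)
  rep_len <- .resample(seq.int(600L, 3000L), nf)

  multi <- which(rowSums(pav >= 1L) >= 2L)
  n_split <- round(config$split_merge_rate * length(multi))
  n_fuse <- round(config$fuse_rate * length(multi))
  n_near <- round(config$near_miss_rate * length(multi))
  picks <- .resample(multi, min(length(multi), n_split + n_fuse + n_near),
                     replace = FALSE)
  split_fams <- utils::head(picks, n_split)
  fuse_fams <- utils::head(picks[-seq_len(n_split)], n_fuse)
  near_fams <- utils::tail(picks, n_near)

  # flat gene table: one row per gene, accession-major then family order so
  # per-accession gene order follows `ord` within accession
  cells <- which(pav >= 1L, arr.ind = TRUE)  # column-major: accession-major
  cnt <- pav[cells]
  fam_i <- rep(cells[, 1L], cnt)
  acc_i <- rep(cells[, 2L], cnt)
  copy_i <- sequence(cnt)
  gt <- data.frame(
    gene = sprintf("%s_%s_g%d", accs[acc_i], fams[fam_i], copy_i),
    fam = fam_i, acc = acc_i,
    len = rep_len[fam_i] + sample.int(50L, length(fam_i), replace = TRUE) - 25L,
    ord = as.numeric(seq_along(fam_i)),
    drop = logical(length(fam_i)),
    stringsAsFactors = FALSE)
  fam_rows <- split(seq_len(nrow(gt)), gt$fam)

  hit_acc <- list()
  add_hits <- function(q, t, cq, ct, ts, te, score) {
    hit_acc[[length(hit_acc) + 1L]] <<- data.frame(
      query = q, target = t, cov_query = cq, cov_target = ct,
      t_start = ts, t_end = te, score = score, stringsAsFactors = FALSE)
  }

  split_flag <- stats::setNames(logical(nf), fams)
  new_rows <- list()

  # (i) split artifacts: one accession's gene replaced by two adjacent genes
  for (f in split_fams) {
    rows <- fam_rows[[as.character(f)]]
    a_all <- gt$acc[rows]
    a_split <- .resample(unique(a_all), 1L)
    rep_row <- rows[a_all != a_split][[1L]]
    gt$len[[rep_row]] <- max(gt$len[rows]) + 100L
    L <- gt$len[[rep_row]]
    old_row <- rows[a_all == a_split][[1L]]
    gt$drop[[old_row]] <- TRUE
    cut <- stats::runif(1, 0.38, 0.55)
    joint <- stats::runif(1, 0.955, 0.99)
    s1 <- c(1, round(cut * L))
    s2 <- c(round(cut * L) + 1, round(joint * L))
    g1 <- paste0(gt$gene[[old_row]], "a")
    g2 <- paste0(gt$gene[[old_row]], "b")
    new_rows[[length(new_rows) + 1L]] <- data.frame(
      gene = c(g1, g2), fam = f, acc = a_split,
      len = c(round((s1[2] - s1[1] + 1) * 1.05),
              round((s2[2] - s2[1] + 1) * 1.05)),
      ord = gt$ord[[old_row]] + c(0, 0.5), drop = FALSE,
      stringsAsFactors = FALSE)
    rg <- gt$gene[[rep_row]]
    add_hits(c(g1, g2), rg, c(0.97, 0.97),
             c((s1[2] - s1[1] + 1) / L, (s2[2] - s2[1] + 1) / L),
             c(s1[1], s2[1]), c(s1[2], s2[2]), stats::runif(2, 40, 60))
    split_flag[[f]] <- TRUE
  }

  # baseline within-family hits (members vs family representative)
  base <- setdiff(which(vapply(fam_rows, length, integer(1)) >= 2L),
                  match(as.character(split_fams), names(fam_rows)))
  for (k in base) {
    rows <- fam_rows[[k]]
    rep_row <- rows[[1L]]
    others <- .resample(rows[-1L], min(2L, length(rows) - 1L),
                        replace = FALSE)
    for (r in others) {
      sc <- stats::runif(1, 40, 70)
      ct1 <- stats::runif(1, 0.95, 1); ct2 <- stats::runif(1, 0.95, 1)
      add_hits(c(gt$gene[[r]], gt$gene[[rep_row]]),
               c(gt$gene[[rep_row]], gt$gene[[r]]),
               stats::runif(2, 0.95, 1), c(ct1, ct2),
               c(1, 1),
               c(round(ct1 * gt$len[[rep_row]]), round(ct2 * gt$len[[r]])),
               c(sc, sc))
    }
  }

  # (ii) over-split orthogroups with planted qualifying RBH
  fused_pairs <- NULL
  og_of_fam <- fams  # family id -> orthogroup id written out
  extra_og <- list() # og id -> integer rows of gt
  split_part <- integer(nrow(gt))  # 0 = family og, 1/2 = over-split halves
  for (f in fuse_fams) {
    rows <- fam_rows[[as.character(f)]]
    a_all <- unique(gt$acc[rows])
    part_a <- .resample(a_all, ceiling(length(a_all) / 2), replace = FALSE)
    in_a <- gt$acc[rows] %in% part_a
    split_part[rows] <- ifelse(in_a, 1L, 2L)
    ga <- gt$gene[rows[in_a][[1L]]]
    gb <- gt$gene[rows[!in_a][[1L]]]
    la <- gt$len[rows[in_a][[1L]]]
    lb <- gt$len[rows[!in_a][[1L]]]
    sc <- stats::runif(1, 95, 100)
    ct1 <- stats::runif(1, 0.955, 0.995); ct2 <- stats::runif(1, 0.955, 0.995)
    add_hits(c(ga, gb), c(gb, ga),
             stats::runif(2, 0.955, 0.995), c(ct1, ct2),
             c(1, 1), c(round(ct1 * lb), round(ct2 * la)), c(sc, sc))
    fused_pairs <- rbind(fused_pairs,
                         data.frame(og_a = paste0(fams[[f]], "a"),
                                    og_b = paste0(fams[[f]], "b"),
                                    stringsAsFactors = FALSE))
  }

  # (iii) near-miss cross-family hits (coverage 0.94, must not fuse)
  near_pairs <- NULL
  near_fams <- near_fams[seq_len(2 * (length(near_fams) %/% 2))]
  if (length(near_fams) >= 2L) {
    for (i in seq(1L, length(near_fams) - 1L, by = 2L)) {
      f1 <- near_fams[[i]]; f2 <- near_fams[[i + 1L]]
      r1 <- fam_rows[[as.character(f1)]][[1L]]
      r2 <- fam_rows[[as.character(f2)]][[1L]]
      sc <- stats::runif(1, 98, 100)
      add_hits(c(gt$gene[[r1]], gt$gene[[r2]]),
               c(gt$gene[[r2]], gt$gene[[r1]]),
               c(0.94, 0.94), c(0.94, 0.94), c(1, 1),
               c(round(0.94 * gt$len[[r2]]), round(0.94 * gt$len[[r1]])),
               c(sc, sc))
      near_pairs <- rbind(near_pairs,
                          data.frame(fam_a = fams[[f1]], fam_b = fams[[f2]],
                                     stringsAsFactors = FALSE))
    }
  }

  # finalize gene table: apply split replacements, keep stable order
  gt2 <- rbind(gt[!gt$drop, c("gene", "fam", "acc", "len", "ord")],
               do.call(rbind, c(new_rows, list(NULL)))[
                 , c("gene", "fam", "acc", "len", "ord"), drop = FALSE])
  gt2 <- gt2[order(gt2$acc, gt2$ord), , drop = FALSE]
  # over-split half membership aligned to gt2 (split genes never in fuse fams)
  fam2 <- gt2$fam
  part2 <- integer(nrow(gt2))
  for (f in fuse_fams) {
    rows0 <- fam_rows[[as.character(f)]]
    part_map <- stats::setNames(split_part[rows0], gt$gene[rows0])
    sel <- fam2 == f
    part2[sel] <- part_map[gt2$gene[sel]]
  }

  # gene models: per accession, genes laid end to end on one scaffold
  starts <- unlist(lapply(split(gt2$len, gt2$acc), function(l)
    cumsum(c(1, utils::head(l + 100, -1)))), use.names = FALSE)
  gene_models <- data.frame(accession = accs[gt2$acc], gene = gt2$gene,
                            chrom = "Chr1", start = starts,
                            end = starts + gt2$len - 1,
                            stringsAsFactors = FALSE)

  # orthogroup table: family-major; over-split families written as two ogs
  og_id <- ifelse(part2 == 0L, fams[fam2],
                  paste0(fams[fam2], c("", "a", "b")[part2 + 1L]))
  by_og <- split(seq_len(nrow(gt2)), og_id)
  og_members <- lapply(by_og, function(rws) {
    per <- split(gt2$gene[rws], accs[gt2$acc[rws]])
    out <- stats::setNames(vector("list", length(accs)), accs)
    out[names(per)] <- per
    out
  })
  og_members <- og_members[order(names(og_members))]

  hits <- do.call(rbind, hit_acc)
  rownames(hits) <- NULL
  truth$split_merge_flag <- split_flag
  truth$fused_pairs <- fused_pairs
  truth$near_miss_pairs <- near_pairs
  list(og = og_table(og_members, accs), hits = hits,
       gene_models = gene_models, truth = truth)
}

#' Synthetic fusion test cases
#'
#' Generates `n_cases` independent two-orthogroup cases; for each, a
#' cross-group hit pair is planted that either qualifies for fusion
#' (bidirectional coverage >= 0.95 and reciprocal best hit), fails on
#' coverage, or fails reciprocity (the second gene's best hit is a decoy).
#'
#' @param n_cases Number of cases.
#' @param seed Integer seed.
#' @param p_qualify Probability that a case qualifies (default 0.5).
#' @return List with `og`, `hits` and `truth` (data.frame `og_a`, `og_b`,
#'   `scenario`, `expect_fused`).
#' @export
simulate_fusion_cases <- function(n_cases, seed = 1L, p_qualify = 0.5) {
  set.seed(.sub_seed(seed, "fusion"))
  accs <- c("AccA", "AccB")
  fams <- list(); hits <- list(); truth <- list()
  scen <- sample(c("qualify", "low_cov", "non_reciprocal"), n_cases,
                 replace = TRUE,
                 prob = c(p_qualify, (1 - p_qualify) / 2, (1 - p_qualify) / 2))
  for (i in seq_len(n_cases)) {
    fa <- sprintf("C%04da", i); fb <- sprintf("C%04db", i)
    ga <- paste0(fa, "_g"); gb <- paste0(fb, "_g")
    fams[[fa]] <- list(AccA = ga, AccB = character(0))
    fams[[fb]] <- list(AccA = character(0), AccB = gb)
    sc <- stats::runif(1, 80, 100)
    case_hits <- switch(
      scen[[i]],
      qualify = data.frame(
        query = c(ga, gb), target = c(gb, ga),
        cov_query = stats::runif(2, 0.95, 1),
        cov_target = stats::runif(2, 0.95, 1),
        score = c(sc, sc), stringsAsFactors = FALSE),
      low_cov = {
        lo <- stats::runif(1, 0.5, 0.9499)
        data.frame(
          query = c(ga, gb), target = c(gb, ga),
          cov_query = c(lo, stats::runif(1, 0.95, 1)),
          cov_target = c(stats::runif(1, 0.95, 1), lo),
          score = c(sc, sc), stringsAsFactors = FALSE)
      },
      non_reciprocal = {
        gd <- paste0(fb, "_decoy")
        fams[[fb]]$AccB <- c(gb, gd)
        data.frame(
          query = c(ga, gb, gb, gd),
          target = c(gb, ga, gd, gb),
          cov_query = stats::runif(4, 0.95, 1),
          cov_target = stats::runif(4, 0.95, 1),
          score = c(sc, sc - 1, sc + 5, sc + 5),  # gb's best is the decoy
          stringsAsFactors = FALSE)
      })
    hits[[i]] <- case_hits
    truth[[i]] <- data.frame(og_a = fa, og_b = fb, scenario = scen[[i]],
                             expect_fused = scen[[i]] == "qualify",
                             stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hits)
  hits$t_start <- 1; hits$t_end <- round(hits$cov_target * 1000)
  list(og = og_table(fams, accs), hits = hits,
       truth = do.call(rbind, truth))
}

# sample a non-overlapping interval of given width on [1, len] avoiding
# `occupied` (IRanges); NULL if no luck after `tries`
.place_interval <- function(len, width, occupied, tries = 60L) {
  if (width > len) return(NULL)
  for (t in seq_len(tries)) {
    s <- sample.int(len - width + 1L, 1L)
    cand <- IRanges::IRanges(s, s + width - 1L)
    if (!length(occupied) ||
        sum(IRanges::countOverlaps(cand, occupied)) == 0L)
      return(cand)
  }
  NULL
}

#' Simulate per-accession synteny-block annotations
#'
#' Each accession's annotation tiles the reference: chromosome arms are SYN
#' except planted events; centromere spans are emitted as a random
#' haplotype of non-syntenic blocks (NOTAL/INV/TRANS/DUP segments).
#' Planted events are private arm inversions (Poisson per accession),
#' deletions (emitted as NOTAL; 20 bp to `indel_size_max`), insertions
#' (recorded in truth only, zero reference footprint) and optionally one
#' inversion shared by `shared_inversion$n_carriers` accessions.
#'
#' @param config A [sim_config()].
#' @return List with `blocks` (data.frame over all accessions), `truth`
#'   (data.frame of planted SVs: `accession`, `type`, `chrom`, `start`,
#'   `end`, `length`) and `shared_carriers` (accession names carrying the
#'   shared inversion).
#' @export
simulate_synteny <- function(config) {
  validate_sim_config(config)
  set.seed(.sub_seed(config$seed, "synteny"))
  accs <- .acc_names(config$n_accessions)
  lens <- config$ref_chrom_lengths
  cens <- config$centromere_spans
  si <- config$shared_inversion
  carriers <- character(0)
  if (!is.null(si))
    carriers <- sort(sample(accs, min(si$n_carriers, length(accs))))

  blocks <- list(); truth <- list()
  cen_types <- c("NOTAL", "INV", "TRANS", "DUP")
  for (a in accs) {
    for (chrom in names(lens)) {
      len <- lens[[chrom]]
      events <- list()  # list of (start, end, type, record_in_truth)
      occupied <- IRanges::IRanges()
      cen <- cens[cens$chrom == chrom, , drop = FALSE]
      if (nrow(cen)) {
        # random centromeric haplotype: 3-8 non-syntenic segments
        cs <- cen$start[[1L]]; ce <- cen$end[[1L]]
        k <- sample(3:8, 1L)
        cuts <- sort(sample.int(ce - cs, k - 1L)) + cs
        seg_start <- c(cs, cuts)
        seg_end <- c(cuts - 1L, ce)
        seg_type <- sample(cen_types, k, replace = TRUE,
                           prob = c(0.55, 0.15, 0.15, 0.15))
        for (s in seq_len(k))
          events[[length(events) + 1L]] <-
            list(seg_start[[s]], seg_end[[s]], seg_type[[s]], FALSE)
        occupied <- c(occupied, IRanges::IRanges(cs, ce))
      }
      if (!is.null(si) && chrom == si$chrom && a %in% carriers) {
        ss <- si$start; se <- si$start + si$length - 1
        events[[length(events) + 1L]] <- list(ss, se, "INV", TRUE)
        occupied <- c(occupied, IRanges::IRanges(ss, se))
      }
      n_inv <- stats::rpois(1L, config$inversion_rate_per_genome /
                              length(lens))
      for (k in seq_len(n_inv)) {
        w <- round(stats::runif(1, config$inversion_size_range[[1L]],
                                config$inversion_size_range[[2L]]))
        iv <- .place_interval(len, w, occupied)
        if (is.null(iv)) next
        events[[length(events) + 1L]] <-
          list(IRanges::start(iv), IRanges::end(iv), "INV", TRUE)
        occupied <- c(occupied, iv)
      }
      n_indel <- stats::rpois(1L, config$indel_rate_per_genome / length(lens))
      for (k in seq_len(n_indel)) {
        w <- round(stats::runif(1, 20, config$indel_size_max))
        if (stats::runif(1) < 0.5) {  # deletion: NOTAL footprint on ref
          iv <- .place_interval(len, w, occupied)
          if (is.null(iv)) next
          events[[length(events) + 1L]] <-
            list(IRanges::start(iv), IRanges::end(iv), "NOTAL", TRUE)
          occupied <- c(occupied, iv)
        } else {  # insertion: point on ref, recorded in truth only
          pos <- sample.int(len, 1L)
          truth[[length(truth) + 1L]] <- data.frame(
            accession = a, type = "INS", chrom = chrom,
            start = pos, end = pos, length = w, stringsAsFactors = FALSE)
        }
      }
      # assemble tiling: events sorted, SYN gap-fill
      if (length(events)) {
        ev <- do.call(rbind, lapply(events, function(e)
          data.frame(start = e[[1L]], end = e[[2L]], type = e[[3L]],
                     in_truth = e[[4L]], stringsAsFactors = FALSE)))
        ev <- ev[order(ev$start), , drop = FALSE]
      } else {
        ev <- data.frame(start = numeric(0), end = numeric(0),
                         type = character(0), in_truth = logical(0))
      }
      tile <- list(); pos <- 1
      for (r in seq_len(nrow(ev))) {
        if (ev$start[[r]] > pos)
          tile[[length(tile) + 1L]] <-
            data.frame(start = pos, end = ev$start[[r]] - 1, type = "SYN",
                       stringsAsFactors = FALSE)
        tile[[length(tile) + 1L]] <-
          data.frame(start = ev$start[[r]], end = ev$end[[r]],
                     type = ev$type[[r]], stringsAsFactors = FALSE)
        pos <- ev$end[[r]] + 1
      }
      if (pos <= len)
        tile[[length(tile) + 1L]] <-
          data.frame(start = pos, end = len, type = "SYN",
                     stringsAsFactors = FALSE)
      tl <- do.call(rbind, tile)
      inv <- tl$type == "INV"
      blocks[[length(blocks) + 1L]] <- data.frame(
        accession = a, ref_chrom = chrom,
        ref_start = tl$start, ref_end = tl$end,
        qry_chrom = chrom,
        qry_start = ifelse(inv, tl$end, tl$start),
        qry_end = ifelse(inv, tl$start, tl$end),
        type = tl$type, stringsAsFactors = FALSE)
      keep <- ev$in_truth
      if (any(keep)) {
        tv <- ev[keep, , drop = FALSE]
        truth[[length(truth) + 1L]] <- data.frame(
          accession = a, type = ifelse(tv$type == "NOTAL", "DEL", tv$type),
          chrom = chrom, start = tv$start, end = tv$end,
          length = tv$end - tv$start + 1, stringsAsFactors = FALSE)
      }
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(accession = character(0), type = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               length = numeric(0))
  rownames(truth_df) <- NULL
  list(blocks = do.call(rbind, blocks), truth = truth_df,
       shared_carriers = carriers)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.32, 0.18, 0.18, 0.32)), collapse = "")
}

.mutate_motif <- function(motif, rate) {
  if (rate <= 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[[i]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[i]]), 1L)
  paste(chars, collapse = "")
}

#' Simulate assemblies with tandem repeat arrays and depth tracks
#'
#' Per accession and chromosome, a true centromeric copy number is drawn
#' from `copy_range`; the assembled sequence carries
#' `floor(truncation * copies)` tandem copies (each independently mutated
#' at `motif_divergence`) embedded in random background, with exact
#' telomeric arrays at both ends.  True genome size is the linear coupling
#' `constant + total true repeat length + Gaussian noise`.  Depth tracks:
#' the genome track is Poisson around `depth_mean` per assembled position;
#' the motif-concatemer track (4 motif copies) receives total depth
#' `depth_mean * true repeat length` plus Poisson noise, so the
#' depth-ratio estimator can recover the true repeat length regardless of
#' assembly truncation.
#'
#' @param config A [sim_config()].
#' @param accessions Optional subset of accession names to simulate.
#' @param truncation Named per-accession assembly completeness factors in
#'   (0, 1]; default 1 (complete assemblies).
#' @param noise Logical; `FALSE` produces noise-free depth tracks and no
#'   size-coupling noise.
#' @return List with `seqs` (named list of `DNAStringSet`), `genome_depth`
#'   and `concat_depth` (named lists of depth tracks), and `truth`
#'   (list: `per_chrom` data.frame of true/assembled repeat bp, `per_acc`
#'   data.frame of true/assembled genome size).
#' @export
simulate_repeats_and_depth <- function(config, accessions = NULL,
                                       truncation = NULL, noise = TRUE) {
  validate_sim_config(config)
  set.seed(.sub_seed(config$seed, "repeats"))
  accs <- if (is.null(accessions)) .acc_names(config$n_accessions)
          else accessions
  chroms <- names(config$ref_chrom_lengths)
  mlen <- nchar(config$motif_cen)
  clen <- config$concat_len <- 4L * mlen
  tel <- strrep(config$motif_tel, config$tel_copies)

  seqs <- list(); gdepth <- list(); cdepth <- list()
  per_chrom <- list(); per_acc <- list()
  for (a in accs) {
    trunc_a <- if (!is.null(truncation) && a %in% names(truncation))
      truncation[[a]] else 1
    chrom_seqs <- character(0)
    true_rep_total <- 0; asm_rep_total <- 0
    for (chrom in chroms) {
      copies <- .resample(seq.int(config$copy_range[[1L]],
                                  config$copy_range[[2L]]), 1L)
      asm_copies <- max(0L, floor(copies * trunc_a))
      array_seq <- paste(vapply(seq_len(asm_copies), function(i)
        .mutate_motif(config$motif_cen, config$motif_divergence),
        character(1)), collapse = "")
      half <- config$background_length %/% 2L
      body <- paste0(tel, .random_dna(half), array_seq,
                     .random_dna(config$background_length - half), tel)
      chrom_seqs[[chrom]] <- body
      per_chrom[[length(per_chrom) + 1L]] <- data.frame(
        accession = a, chrom = chrom,
        true_copies = copies,
        true_repeat_bp = copies * mlen,
        assembled_repeat_bp = asm_copies * mlen,
        stringsAsFactors = FALSE)
      true_rep_total <- true_rep_total + copies * mlen
      asm_rep_total <- asm_rep_total + asm_copies * mlen
    }
    asm_size <- sum(nchar(chrom_seqs))
    const <- length(chroms) * (config$background_length +
                                 2L * nchar(tel))
    noise_bp <- if (noise) stats::rnorm(1, 0, config$size_coupling_noise_sd)
                else 0
    true_size <- const + true_rep_total + noise_bp
    per_acc[[length(per_acc) + 1L]] <- data.frame(
      accession = a, assembly_size = asm_size,
      true_genome_size = true_size,
      true_repeat_bp = true_rep_total,
      assembled_repeat_bp = asm_rep_total,
      stringsAsFactors = FALSE)
    seqs[[a]] <- Biostrings::DNAStringSet(chrom_seqs)
    gdepth[[a]] <- lapply(chrom_seqs, function(s) {
      n <- nchar(s)
      if (noise) stats::rpois(n, config$depth_mean)
      else rep(config$depth_mean, n)
    })
    lam <- config$depth_mean * true_rep_total / clen
    cdepth[[a]] <- list(concatemer = if (noise) stats::rpois(clen, lam)
                        else rep(lam, clen))
  }
  pc <- do.call(rbind, per_chrom); rownames(pc) <- NULL
  pa <- do.call(rbind, per_acc); rownames(pa) <- NULL
  list(seqs = seqs, genome_depth = gdepth, concat_depth = cdepth,
       truth = list(per_chrom = pc, per_acc = pa))
}
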