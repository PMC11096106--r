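# Gene-family presence/absence classification, orthogroup correction and
# pan/core rarefaction.

#' Classification rules for pan-genome gene-family categories
#'
#' @param softcore_fraction Fraction of accessions above which (strict
#'   inequality) a non-core family is softcore.  With the default 0.9 and
#'   n = 69 accessions the softcore range is 63-68 and the dispensable
#'   upper bound is 62.
#' @return A `pan_rules` list.
#' @export
pan_rules <- function(softcore_fraction = 0.9) {
  stopifnot(softcore_fraction > 0, softcore_fraction < 1)
  structure(list(softcore_fraction = softcore_fraction), class = "pan_rules")
}

#' Category bounds implied by the classification rules
#'
#' @param n Number of accessions.
#' @param rules A [pan_rules()] object.
#' @return Named list: `core` (= n), `softcore_min`, `softcore_max`,
#'   `dispensable_max`.  The softcore range may be empty (e.g. n = 10 with
#'   the 0.9 threshold: no integer m satisfies 9 < m < 10).
#' @export
category_bounds <- function(n, rules = pan_rules()) {
  cut <- rules$softcore_fraction * n
  soft_min <- floor(cut) + 1L          # smallest integer strictly above cut
  if (soft_min <= cut) soft_min <- soft_min + 1L  # guard exact-integer cut
  list(core = n,
       softcore_min = soft_min,
       softcore_max = n - 1L,
       dispensable_max = soft_min - 1L)
}

#' Classify gene families by presence count
#'
#' A family present in m of n accessions is `core` when m = n, `softcore`
#' when n > m > softcore_fraction * n (strict), `dispensable` when
#' 2 <= m <= the softcore lower bound minus one, and `private` when m = 1.
#' Families absent everywhere are labelled `absent` and excluded from the
#' category counts.
#'
#' @param pav Counts matrix, families x accessions (counts >= 1 mean
#'   presence).
#' @param rules A [pan_rules()] object.
#' @return List with `category` (named factor per family, levels absent <
#'   private < dispensable < softcore < core), `counts` (named integer
#'   vector over the four categories), `n` and `m` (per-family presence
#'   counts).
#' @export
classify_families <- function(pav, rules = pan_rules()) {
  stopifnot(is.matrix(pav))
  n <- ncol(pav)
  if (n < 3L) stop("classification needs at least 3 accessions")
  m <- rowSums(pav >= 1L)
  b <- category_bounds(n, rules)
  lev <- c("absent", "private", "dispensable", "softcore", "core")
  cat <- rep("dispensable", nrow(pav))
  cat[m == 0L] <- "absent"
  cat[m == 1L] <- "private"
  cat[m >= b$softcore_min & m <= b$softcore_max] <- "softcore"
  cat[m == n] <- "core"
  category <- factor(cat, levels = lev, ordered = TRUE)
  names(category) <- rownames(pav)
  counts <- table(factor(cat[m >= 1L],
                         levels = c("core", "softcore", "dispensable", "private")))
  list(category = category, counts = c(unclass(counts)), n = n, m = m)
}

#' Per-accession gene-level category composition
#'
#' Fractions of each accession's genes (counts, not families) belonging to
#' each category; rows sum to 1 for accessions with at least one gene.
#'
#' @param pav Counts matrix.
#' @param classification Result of [classify_families()].
#' @return Matrix accessions x 4 of fractions.
#' @export
composition <- function(pav, classification) {
  cats <- c("core", "softcore", "dispensable", "private")
  cat_f <- as.character(classification$category)
  out <- sapply(cats, function(cc) {
    rows <- which(cat_f == cc)
    if (!length(rows)) return(numeric(ncol(pav)))
    colSums(pav[rows, , drop = FALSE])
  })
  tot <- rowSums(out)
  out <- sweep(out, 1L, pmax(tot, 1), "/")
  rownames(out) <- colnames(pav)
  out
}

# gene id -> family / accession lookup for an og_table
.og_index <- function(og) {
  accs <- attr(og, "accessions")
  per_fam <- lapply(og, function(fam) {
    g <- fam[accs]
    n <- lengths(g)
    list(gene = unlist(g, use.names = FALSE),
         acc = rep(accs, n))
  })
  n_per_fam <- vapply(per_fam, function(x) length(x$gene), integer(1))
  data.frame(gene = unlist(lapply(per_fam, `[[`, "gene"), use.names = FALSE),
             family = rep(names(og), n_per_fam),
             accession = unlist(lapply(per_fam, `[[`, "acc"),
                                use.names = FALSE),
             stringsAsFactors = FALSE)
}

# best hit per query: highest score, ties broken lexicographically by target
.best_hits <- function(hits) {
  o <- order(hits$query, -hits$score, hits$target, method = "radix")
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query), c("query", "target")]
}

#' Fuse over-split orthogroups using reciprocal-best-hit evidence
#'
#' A homology hit qualifies when both coverages are at or above
#' `cov_threshold` and the gene pair is a reciprocal best hit (each gene is
#' the other's highest-scoring match; score ties are broken
#' lexicographically by gene id).  Qualifying hits joining genes of
#' different families merge those families by transitive closure, so the
#' family count never increases and re-application is a no-op.
#'
#' @param og An `og_table`.
#' @param hits Data.frame with columns `query`, `target`, `cov_query`,
#'   `cov_target`, `score` (both hit directions listed).
#' @param cov_threshold Bidirectional coverage threshold (default 0.95).
#' @return The fused `og_table`; merged families take the lexicographically
#'   smallest member id.
#' @export
fuse_orthogroups <- function(og, hits, cov_threshold = 0.95) {
  idx <- .og_index(og)
  if (nrow(hits)) {
    unknown <- setdiff(unique(c(hits$query, hits$target)), idx$gene)
    if (length(unknown))
      stop("hits reference unknown gene(s): ",
           paste(utils::head(unknown, 10L), collapse = ", "))
  }
  fam_of <- stats::setNames(idx$family, idx$gene)
  cand <- hits[hits$cov_query >= cov_threshold &
                 hits$cov_target >= cov_threshold, , drop = FALSE]
  # reciprocal best hit over the full hit table, not just candidates
  best <- .best_hits(hits)
  best_of <- stats::setNames(best$target, best$query)
  rbh <- !is.na(best_of[cand$query]) & best_of[cand$query] == cand$target &
    !is.na(best_of[cand$target]) & best_of[cand$target] == cand$query
  cand <- cand[rbh, , drop = FALSE]

  # union-find over integer family indices
  fam_ids <- names(og)
  parent <- seq_along(fam_ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  qf <- match(fam_of[cand$query], fam_ids)
  tf <- match(fam_of[cand$target], fam_ids)
  for (i in seq_len(nrow(cand))) {
    fa <- find(qf[[i]]); fb <- find(tf[[i]])
    if (fa != fb) parent[[max(fa, fb)]] <- min(fa, fb)
  }
  roots <- vapply(seq_along(fam_ids), find, integer(1))
  accs <- attr(og, "accessions")
  og_list <- unclass(og)
  comp <- split(seq_along(fam_ids), roots)
  merged <- lapply(comp, function(members) {
    if (length(members) == 1L) return(og_list[[members]])
    out <- stats::setNames(vector("list", length(accs)), accs)
    for (a in accs) {
      g <- unlist(lapply(members, function(mi) og_list[[mi]][[a]]),
                  use.names = FALSE)
      out[[a]] <- if (is.null(g)) character(0) else g
    }
    out
  })
  # merged family takes the lexicographically smallest member id
  names(merged) <- vapply(comp, function(members)
    min(fam_ids[members]), character(1))
  og_table(merged[order(names(merged))], accs)
}

#' Flag gene families that are split/merge annotation artifacts
#'
#' A family is flagged when some accession carries two or more genes,
#' adjacent in that accession's gene order, whose alignments to the family's
#' representative gene each cover less than `cov_threshold` of it but whose
#' union of covered positions reaches the threshold — the signature of one
#' locus annotated as a single gene in some accessions and split into
#' several in others.  The representative is the family member from
#' `reference` when one exists, otherwise the longest member (ties broken
#' lexicographically).
#'
#' @param og An `og_table` (after fusion).
#' @param gene_models Data.frame with columns `accession`, `gene`, `chrom`,
#'   `start`, `end` covering every gene in `og`.
#' @param hits Hit table as in [fuse_orthogroups()] with additional columns
#'   `t_start`, `t_end`: the 1-based span covered on the target gene.
#' @param cov_threshold Joint-coverage threshold (default 0.95).
#' @param reference Optional reference accession name.
#' @return Named logical vector over families.
#' @export
flag_split_merge <- function(og, gene_models, hits, cov_threshold = 0.95,
                             reference = NULL) {
  need <- c("accession", "gene", "chrom", "start", "end")
  stopifnot(all(need %in% names(gene_models)))
  idx <- .og_index(og)
  gm_pos <- match(idx$gene, gene_models$gene)
  if (anyNA(gm_pos))
    stop("missing gene coordinates for: ",
         paste(utils::head(idx$gene[is.na(gm_pos)], 10L), collapse = ", "))
  # per-gene attributes aligned to idx rows (all lookups integer-indexed)
  glen_i <- (gene_models$end - gene_models$start + 1)[gm_pos]
  ord <- order(gene_models$accession, gene_models$chrom, gene_models$start)
  rank_all <- integer(nrow(gene_models))
  key <- paste(gene_models$accession, gene_models$chrom)[ord]
  rank_all[ord] <- stats::ave(seq_along(ord), key, FUN = seq_along)
  rank_i <- rank_all[gm_pos]
  chrom_i <- gene_models$chrom[gm_pos]

  fam_rows <- split(seq_len(nrow(idx)), idx$family)
  # hits grouped by the family of their target gene
  tgt_fam <- idx$family[match(hits$target, idx$gene)]
  hits_by_fam <- split(seq_len(nrow(hits)), tgt_fam)
  flags <- stats::setNames(logical(length(og)), names(og))

  for (fid in names(fam_rows)) {
    rows <- fam_rows[[fid]]
    if (length(rows) < 2L) next
    genes <- idx$gene[rows]
    # representative: reference-accession member if present, else longest
    in_ref <- if (is.null(reference)) logical(length(rows))
              else idx$accession[rows] == reference
    rep_row <- if (any(in_ref)) rows[in_ref][order(genes[in_ref])][[1L]]
               else rows[order(-glen_i[rows], genes)][[1L]]
    rep_gene <- idx$gene[[rep_row]]
    rep_len <- glen_i[[rep_row]]
    hrows <- hits_by_fam[[fid]]
    if (is.null(hrows)) next
    to_rep <- hits[hrows[hits$target[hrows] == rep_gene], , drop = FALSE]
    if (!nrow(to_rep)) next
    for (a in unique(idx$accession[rows])) {
      arows <- rows[idx$accession[rows] == a]
      if (length(arows) < 2L) next
      arows <- arows[order(rank_i[arows])]
      rk <- rank_i[arows]; ch <- chrom_i[arows]
      run_id <- cumsum(c(TRUE, diff(rk) != 1L |
                           ch[-1L] != ch[-length(ch)]))
      for (run in split(idx$gene[arows], run_id)) {
        if (length(run) < 2L) next
        hi <- to_rep[to_rep$query %in% run, , drop = FALSE]
        if (length(unique(hi$query)) < 2L) next
        cov_each <- vapply(split(hi, hi$query), function(h)
          .union_len(h$t_start, h$t_end) / rep_len, numeric(1))
        if (any(cov_each >= cov_threshold)) next
        joint <- .union_len(hi$t_start, hi$t_end) / rep_len
        if (joint >= cov_threshold) {
          flags[[fid]] <- TRUE
          break
        }
      }
      if (flags[[fid]]) break
    }
  }
  flags
}

# total length of the union of 1-based inclusive intervals
.union_len <- function(start, end) {
  if (!length(start)) return(0)
  r <- IRanges::reduce(IRanges::IRanges(start, end))
  sum(IRanges::width(r))
}

#' Convert an orthogroup table to a presence/absence count matrix
#'
#' @param og An `og_table`.
#' @return Integer matrix families x accessions of gene counts.
#' @export
og_to_pav <- function(og) {
  accs <- attr(og, "accessions")
  m <- t(vapply(og, function(fam)
    vapply(accs, function(a) length(fam[[a]]), integer(1)),
    integer(length(accs))))
  dimnames(m) <- list(names(og), accs)
  m
}

#' Monte Carlo pan/core rarefaction curve
#'
#' For each subset size k, draws `replicates` uniform subsets of accessions
#' without replacement and counts pan families (present in at least one
#' sampled accession) and core families (present in all sampled).
#'
#' @param pav Counts matrix.
#' @param sizes Integer subset sizes (default 2 to n-2).
#' @param replicates Subsets per size (default 2000).
#' @param seed Integer seed; the curve is deterministic given the seed.
#' @return Data.frame with columns `k`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`, plus attributes `replicates` and `seed`.
#' @export
rarefaction_mc <- function(pav, sizes = NULL, replicates = 2000, seed = 1) {
  pres <- pav >= 1L
  n <- ncol(pres)
  if (is.null(sizes)) sizes <- seq(2L, max(2L, n - 2L))
  if (any(sizes > n)) stop("subset size exceeds number of accessions")
  if (any(sizes < 1L)) stop("subset sizes must be >= 1")
  set.seed(seed)
  res <- lapply(sizes, function(k) {
    pan <- numeric(replicates); core <- numeric(replicates)
    for (r in seq_len(replicates)) {
      cols <- sample.int(n, k)
      sub <- pres[, cols, drop = FALSE]
      rs <- rowSums(sub)
      pan[r] <- sum(rs > 0L)
      core[r] <- sum(rs == k)
    }
    c(k, mean(pan), stats::sd(pan), mean(core), stats::sd(core))
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("k", "pan_mean", "pan_sd", "core_mean", "core_sd")
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  out
}

#' Exact expected pan/core rarefaction curve
#'
#' Closed-form expectations over all k-subsets: a family present in m of n
#' accessions is missed by a random k-subset with probability
#' C(n - m, k) / C(n, k) and is core of the subset with probability
#' C(m, k) / C(n, k).
#'
#' @param pav Counts matrix.
#' @param sizes Integer subset sizes.
#' @return Data.frame with columns `k`, `pan`, `core`.
#' @export
rarefaction_exact <- function(pav, sizes = NULL) {
  m <- rowSums(pav >= 1L)
  m <- m[m > 0L]
  n <- ncol(pav)
  if (is.null(sizes)) sizes <- seq(2L, max(2L, n - 2L))
  if (any(sizes > n)) stop("subset size exceeds number of accessions")
  res <- vapply(sizes, function(k) {
    ln_nk <- lchoose(n, k)
    p_miss <- exp(lchoose(n - m, k) - ln_nk)   # lchoose = -Inf when n-m < k
    p_core <- exp(lchoose(m, k) - ln_nk)
    c(sum(1 - p_miss), sum(p_core))
  }, numeric(2))
  data.frame(k = sizes, pan = res[1L, ], core = res[2L, ])
}
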