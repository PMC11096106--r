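# End-to-end orchestration: simulate -> classify -> syndiv -> svmerge ->
# censize -> report, driven by one YAML config and one seed.  Every stage
# writes its outputs plus a manifest (inputs, parameters, seed, md5
# digests), so identical (config, seed) pairs reproduce identical digests.

.log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
}

.write_manifest <- function(dir, stage, params, files, status = "ok") {
  files <- files[file.exists(files)]
  man <- list(stage = stage,
              status = status,
              parameters = params,
              files = as.list(stats::setNames(
                unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_accessions,n_families Scale of the simulated panel.
#' @return Nested list mirroring the YAML config schema; every stage block
#'   has an `enabled` flag plus stage parameters.
#' @export
pipeline_config <- function(out_dir = "pansynkit_out", seed = 42L,
                            n_accessions = 12L, n_families = 500L) {
  # at small n the strict softcore range (0.9 n < m < n) can be empty; fold
  # the softcore mass into dispensable in that case
  soft_ok <- floor(0.9 * n_accessions) + 1 <= n_accessions - 1
  props <- if (soft_ok)
    c(core = 0.60, softcore = 0.05, dispensable = 0.17, private = 0.18)
  else c(core = 0.60, softcore = 0, dispensable = 0.22, private = 0.18)
  list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(enabled = TRUE, n_accessions = n_accessions,
                    n_families = n_families,
                    category_props = props),
    classify = list(enabled = TRUE, softcore_fraction = 0.9,
                    cov_threshold = 0.95, replicates = 200L),
    syndiv = list(enabled = TRUE, window = 100000L, step = 50000L,
                  low = 0.2, high = 0.5),
    svmerge = list(enabled = TRUE, tier = "large"),
    censize = list(enabled = TRUE, max_divergence = 0.2),
    report = list(enabled = TRUE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return Config list (missing keys filled with defaults).
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- pipeline_config()
  merge <- function(d, u) {
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]]))
        merge(d[[k]], u[[k]]) else u[[k]]
    }
    d
  }
  merge(def, user)
}

#' Run the full pipeline
#'
#' Stages run in dependency order; each writes its outputs and a manifest
#' with md5 digests into `out_dir`.  A stage failure stops the run with the
#' partial outputs retained and the failing stage's manifest marked
#' `failed`.
#'
#' @param config List from [pipeline_config()] / [read_pipeline_config()],
#'   or a path to a YAML file.
#' @return Invisibly, the aggregated report list (also written to
#'   `report.json` when the report stage is enabled).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- config$out_dir
  seed <- config$seed
  report <- list(seed = seed)

  scfg <- sim_config(n_accessions = config$simulate$n_accessions,
                     n_families = config$simulate$n_families,
                     category_props = unlist(config$simulate$category_props),
                     seed = seed)

  if (isTRUE(config$simulate$enabled)) {
    .log_msg("stage simulate: ", scfg$n_accessions, " accessions, ",
             scfg$n_families, " families")
    tryCatch({
      sim <- simulate_pav(scfg)
      hom <- simulate_homology(sim, scfg)
      syn <- simulate_synteny(scfg)
      rep_acc <- utils::head(.acc_names(scfg$n_accessions), 6L)
      reps <- simulate_repeats_and_depth(scfg, accessions = rep_acc)
      write_pav(sim$pav, file.path(out, "pav.tsv"))
      write_orthogroups(hom$og, file.path(out, "orthogroups.tsv"))
      utils::write.table(hom$hits, file.path(out, "hits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_gff3(hom$gene_models, file.path(out, "gene_models.gff3"))
      syri_dir <- file.path(out, "syri")
      dir.create(syri_dir, showWarnings = FALSE)
      for (a in unique(syn$blocks$accession))
        write_syri(syn$blocks[syn$blocks$accession == a, ],
                   file.path(syri_dir, paste0(a, ".syri.tsv")))
      write_sv(syn$truth, file.path(out, "planted_svs.tsv"))
      fa_dir <- file.path(out, "fasta"); dir.create(fa_dir, showWarnings = FALSE)
      dp_dir <- file.path(out, "depth"); dir.create(dp_dir, showWarnings = FALSE)
      for (a in names(reps$seqs)) {
        write_fasta(reps$seqs[[a]], file.path(fa_dir, paste0(a, ".fa")))
        write_depth(reps$genome_depth[[a]],
                    file.path(dp_dir, paste0(a, ".genome.depth.tsv")))
        write_depth(reps$concat_depth[[a]],
                    file.path(dp_dir, paste0(a, ".concat.depth.tsv")))
      }
      truth <- list(family_category = as.list(hom$truth$family_category),
                    split_merge_flag = as.list(hom$truth$split_merge_flag),
                    shared_carriers = syn$shared_carriers,
                    repeat_truth = reps$truth$per_acc)
      jsonlite::write_json(truth, file.path(out, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      .write_manifest(out, "simulate",
                      list(seed = seed, n_accessions = scfg$n_accessions,
                           n_families = scfg$n_families),
                      c(file.path(out, c("pav.tsv", "orthogroups.tsv",
                                         "hits.tsv", "gene_models.gff3",
                                         "planted_svs.tsv", "truth.json")),
                        list.files(syri_dir, full.names = TRUE),
                        list.files(fa_dir, full.names = TRUE),
                        list.files(dp_dir, full.names = TRUE)))
    }, error = function(e) {
      .write_manifest(out, "simulate", list(seed = seed), character(0),
                      status = paste("failed:", conditionMessage(e)))
      stop("simulate stage failed: ", conditionMessage(e))
    })
  }

  if (isTRUE(config$classify$enabled)) {
    need <- file.path(out, c("orthogroups.tsv", "hits.tsv",
                             "gene_models.gff3"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("classify stage inputs missing: ",
           paste(basename(miss), collapse = ", "))
    .log_msg("stage classify")
    og <- read_orthogroups(need[[1L]])
    hits <- utils::read.table(need[[2L]], header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    gm <- read_gff3(need[[3L]])
    gm$accession <- sub("_FAM.*$", "", gm$gene)
    fused <- fuse_orthogroups(og, hits, config$classify$cov_threshold)
    pav <- og_to_pav(fused)
    rules <- pan_rules(config$classify$softcore_fraction)
    cls <- classify_families(pav, rules)
    flags <- flag_split_merge(fused, gm, hits, config$classify$cov_threshold)
    comp <- composition(pav, cls)
    curve <- rarefaction_mc(pav, replicates = config$classify$replicates,
                            seed = .sub_seed(seed, "pipeline"))
    exact <- rarefaction_exact(pav, curve$k)
    cat_tsv <- data.frame(family = names(cls$category),
                          category = as.character(cls$category),
                          split_merge = flags[names(cls$category)])
    utils::write.table(cat_tsv, file.path(out, "categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(accession = rownames(comp), comp),
                       file.path(out, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(curve, pan_exact = exact$pan,
                             core_exact = exact$core),
                       file.path(out, "rarefaction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(out, "classify",
                    config$classify,
                    file.path(out, c("categories.tsv", "composition.tsv",
                                     "rarefaction.tsv")))
    report$category_counts <- as.list(cls$counts)
    report$n_split_merge <- sum(flags)
    report$pan_at_n <- unname(cls$counts["core"] + cls$counts["softcore"] +
                                cls$counts["dispensable"] + cls$counts["private"])
  }

  if (isTRUE(config$syndiv$enabled)) {
    syri_dir <- file.path(out, "syri")
    files <- list.files(syri_dir, pattern = "\\.syri\\.tsv$",
                        full.names = TRUE)
    if (!length(files)) stop("syndiv stage inputs missing: syri/*.syri.tsv")
    .log_msg("stage syndiv: ", length(files), " accessions")
    blocks <- do.call(rbind, lapply(files, function(f)
      read_syri(f, sub("\\.syri\\.tsv$", "", basename(f)))))
    ind <- project_synteny(blocks, scfg$ref_chrom_lengths)
    ws <- synteny_diversity(ind, config$syndiv$window, config$syndiv$step)
    fr <- fraction_by_threshold(ws, config$syndiv$low, config$syndiv$high)
    utils::write.table(ws, file.path(out, "syndiv_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(out, "syndiv", config$syndiv,
                    file.path(out, "syndiv_windows.tsv"))
    report$syndiv_fraction_below <- unname(fr[["below"]])
    report$syndiv_fraction_above <- unname(fr[["above"]])
  }

  if (isTRUE(config$svmerge$enabled)) {
    svf <- file.path(out, "planted_svs.tsv")
    if (!file.exists(svf)) stop("svmerge stage input missing: planted_svs.tsv")
    .log_msg("stage svmerge")
    svs <- read_sv(svf)
    params <- tier_params(config$svmerge$tier)
    svs <- svs[svs$length >= params$size_range[[1L]] &
                 svs$length <= params$size_range[[2L]], , drop = FALSE]
    clusters <- merge_svs(svs, params)
    utils::write.table(clusters, file.path(out, "sv_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(out, "svmerge", config$svmerge,
                    file.path(out, "sv_clusters.tsv"))
    summ <- sv_summary(clusters)
    report$sv_clusters <- nrow(clusters)
    report$sv_support_spectrum <- as.list(summ$support_spectrum)
  }

  if (isTRUE(config$censize$enabled)) {
    fa_dir <- file.path(out, "fasta"); dp_dir <- file.path(out, "depth")
    fas <- list.files(fa_dir, pattern = "\\.fa$", full.names = TRUE)
    if (!length(fas)) stop("censize stage inputs missing: fasta/*.fa")
    .log_msg("stage censize: ", length(fas), " accessions")
    params <- repeat_params(scfg$motif_cen,
                            max_divergence = config$censize$max_divergence)
    rows <- lapply(fas, function(f) {
      acc <- sub("\\.fa$", "", basename(f))
      seqs <- read_fasta(f)
      gtrack <- read_depth(file.path(dp_dir, paste0(acc, ".genome.depth.tsv")))
      ctrack <- read_depth(file.path(dp_dir, paste0(acc, ".concat.depth.tsv")))
      arrays <- do.call(rbind, lapply(names(seqs), function(ch) {
        arr <- find_repeat_arrays(seqs[[ch]], params)
        if (nrow(arr)) cbind(chrom = ch, arr) else NULL
      }))
      rep_bp <- if (is.null(arrays)) 0 else sum(arrays$end - arrays$start + 1)
      md <- genome_mean_depth(gtrack, arrays)
      est <- estimate_repeat_length(ctrack, md)
      data.frame(accession = acc, assembly_size = sum(Biostrings::width(seqs)),
                 assembled_repeat_bp = rep_bp,
                 estimated_repeat_bp = est,
                 completeness = as.numeric(completeness_ratio(rep_bp, est)),
                 stringsAsFactors = FALSE)
    })
    size_table <- do.call(rbind, rows)
    utils::write.table(size_table, file.path(out, "size_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cors <- size_correlations(
      size_table,
      comparisons = rbind(c("assembly_size", "assembled_repeat_bp"),
                          c("assembly_size", "estimated_repeat_bp")))
    utils::write.table(cors, file.path(out, "size_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(out, "censize", config$censize,
                    file.path(out, c("size_table.tsv",
                                     "size_correlations.tsv")))
    report$size_vs_repeat_r <- cors$r[[1L]]
    report$mean_completeness <- mean(size_table$completeness)
  }

  if (isTRUE(config$report$enabled)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .write_manifest(out, "report", list(), file.path(out, "report.json"))
  }
  invisible(report)
}
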