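test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(category_props = c(core = 0.5, softcore = 0.2,
                                             dispensable = 0.2,
                                             private = 0.2)),
               "sum to 1")
  expect_error(sim_config(ref_chrom_lengths = c(Chr1 = -5)), "> 0")
  expect_error(sim_config(
    ref_chrom_lengths = c(Chr1 = 1e6),
    centromere_spans = data.frame(chrom = "Chr1", start = 5e5, end = 2e6),
    shared_inversion = NULL),
    "centromere")
  expect_error(sim_config(motif_tel = "TTTAGGN"), "DNA")
})

test_that("degenerate category proportions produce degenerate matrices", {
  cfg <- sim_config(n_accessions = 10, n_families = 100,
                    category_props = c(core = 1, softcore = 0,
                                       dispensable = 0, private = 0),
                    seed = 2)
  sim <- simulate_pav(cfg)
  expect_true(all(rowSums(sim$pav >= 1L) == 10L))

  cfgp <- sim_config(n_accessions = 10, n_families = 10,
                     category_props = c(core = 0, softcore = 0,
                                        dispensable = 0, private = 1),
                     multi_copy_rate = 0, seed = 2)
  simp <- simulate_pav(cfgp)
  expect_true(all(rowSums(simp$pav) == 1L))
})

test_that("re-classification recovers planted category labels exactly", {
  for (seed in c(1, 7, 23)) {
    cfg <- sim_config(n_accessions = 69, n_families = 400, seed = seed)
    sim <- simulate_pav(cfg)
    cls <- classify_families(sim$pav)
    expect_identical(as.character(cls$category),
                     unname(sim$truth$family_category[names(cls$category)]))
  }
})

test_that("softcore demand at n = 10 is rejected (empty legal range)", {
  expect_error(simulate_pav(sim_config(n_accessions = 10, n_families = 50)),
               "softcore range is empty")
})

test_that("generator output is deterministic given the seed", {
  cfg <- small_cfg(seed = 31L)
  a <- simulate_pav(cfg); b <- simulate_pav(cfg)
  expect_identical(a, b)
  ha <- simulate_homology(a, cfg); hb <- simulate_homology(b, cfg)
  expect_identical(ha$hits, hb$hits)
  expect_identical(ha$gene_models, hb$gene_models)
  sa <- simulate_synteny(cfg); sb <- simulate_synteny(cfg)
  expect_identical(sa, sb)
})

test_that("planted split families are flagged with no false positives", {
  cfg <- small_cfg(seed = 41L, split_merge_rate = 0.1)
  sim <- simulate_pav(cfg)
  hom <- simulate_homology(sim, cfg)
  fused <- fuse_orthogroups(hom$og, hom$hits)
  flags <- flag_split_merge(fused, hom$gene_models, hom$hits)
  truth <- hom$truth$split_merge_flag
  planted <- names(truth)[truth]
  expect_gt(length(planted), 0L)
  expect_true(all(flags[planted]))
  expect_false(any(flags[setdiff(names(flags), planted)]))
})

test_that("split genes jointly tile the representative but not individually", {
  cfg <- small_cfg(seed = 43L, split_merge_rate = 0.15)
  hom <- simulate_homology(simulate_pav(cfg), cfg)
  split_hits <- hom$hits[hom$hits$cov_target < 0.95 &
                           hom$hits$t_start > 1, , drop = FALSE]
  expect_gt(nrow(split_hits), 0L)
  expect_true(all(split_hits$cov_target < 0.95))
})

test_that("synteny generator tiles the reference completely per accession", {
  cfg <- small_cfg(seed = 51L)
  syn <- simulate_synteny(cfg)
  for (a in unique(syn$blocks$accession)) {
    for (chrom in names(cfg$ref_chrom_lengths)) {
      b <- syn$blocks[syn$blocks$accession == a &
                        syn$blocks$ref_chrom == chrom, ]
      b <- b[order(b$ref_start), ]
      expect_equal(b$ref_start[[1L]], 1)
      expect_equal(b$ref_end[[nrow(b)]],
                   unname(cfg$ref_chrom_lengths[[chrom]]))
      if (nrow(b) > 1L)
        expect_true(all(b$ref_start[-1L] == b$ref_end[-nrow(b)] + 1))
    }
  }
  # planted SVs lie within chromosome bounds
  tr <- syn$truth
  expect_true(all(tr$end <= cfg$ref_chrom_lengths[tr$chrom]))
  expect_true(all(tr$start >= 1))
})

test_that("indicator gap coincides exactly with a planted inversion", {
  cfg <- small_cfg(seed = 52L)
  syn <- simulate_synteny(cfg)
  ind <- project_synteny(syn$blocks, cfg$ref_chrom_lengths)
  carrier <- syn$shared_carriers[[1L]]
  si <- cfg$shared_inversion
  iv <- ind[[carrier]][[si$chrom]]
  gap <- IRanges::setdiff(
    IRanges::IRanges(1, cfg$ref_chrom_lengths[[si$chrom]]), iv)
  hit <- IRanges::findOverlaps(
    IRanges::IRanges(si$start, si$start + si$length - 1), gap,
    type = "within")
  expect_equal(length(hit), 1L)
})

test_that("repeat/depth generator couples genome size to repeat content", {
  cfg <- small_cfg(seed = 61L)
  reps <- simulate_repeats_and_depth(cfg, noise = FALSE)
  pa <- reps$truth$per_acc
  # zero coupling noise: exact linear relation, r = 1
  expect_equal(stats::cor(pa$true_genome_size, pa$true_repeat_bp), 1)
  # noise-free concatemer depth sums to depth_mean * true repeat length
  for (a in pa$accession[1:3]) {
    s <- sum(reps$concat_depth[[a]]$concatemer)
    expect_equal(s, cfg$depth_mean *
                   pa$true_repeat_bp[pa$accession == a])
  }
})

test_that("truncated assemblies report reduced assembled repeat length", {
  cfg <- small_cfg(seed = 62L, copy_range = c(150L, 300L))
  tr <- c(Acc001 = 0.9)
  reps <- simulate_repeats_and_depth(cfg, accessions = c("Acc001"),
                                     truncation = tr, noise = FALSE)
  pc <- reps$truth$per_chrom
  expect_true(all(pc$assembled_repeat_bp <= pc$true_repeat_bp))
  ratio <- sum(pc$assembled_repeat_bp) / sum(pc$true_repeat_bp)
  expect_lt(abs(ratio - 0.9), 0.02)  # floor() granularity only
})

test_that("generated files round-trip through the io readers", {
  cfg <- small_cfg(seed = 71L)
  out <- withr::local_tempdir()
  sim <- simulate_pav(cfg)
  write_pav(sim$pav, file.path(out, "pav.tsv"))
  expect_equal(read_pav(file.path(out, "pav.tsv")), sim$pav)

  syn <- simulate_synteny(cfg)
  a1 <- syn$blocks$accession[[1L]]
  one <- syn$blocks[syn$blocks$accession == a1, ]
  write_syri(one, file.path(out, "a1.syri.tsv"))
  back <- read_syri(file.path(out, "a1.syri.tsv"), a1)
  expect_equal(back[, c("ref_chrom", "ref_start", "ref_end", "type")],
               one[, c("ref_chrom", "ref_start", "ref_end", "type")],
               ignore_attr = TRUE)

  reps <- simulate_repeats_and_depth(cfg, accessions = "Acc001")
  write_depth(reps$genome_depth$Acc001, file.path(out, "d.tsv"))
  rb <- read_depth(file.path(out, "d.tsv"))
  expect_equal(lapply(rb, sum), lapply(reps$genome_depth$Acc001, sum))
})
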