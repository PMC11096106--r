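test_that("projection keeps only SYN coverage and merges intervals", {
  blocks <- rbind(blk("a1", "c", c(1, 201), c(100, 300), "SYN"),
                  blk("a2", "c", 1, 300, "INV"))
  ind <- project_synteny(blocks, c(c = 300))
  expect_equal(sum(IRanges::width(ind$a1$c)), 200)
  expect_equal(sum(IRanges::width(ind$a2$c)), 0)

  # overlapping SYN blocks merge
  ov <- blk("a1", "c", c(1, 50), c(100, 150), "SYN")
  ind2 <- project_synteny(ov, c(c = 300))
  expect_equal(length(ind2$a1$c), 1L)
  expect_equal(sum(IRanges::width(ind2$a1$c)), 150)

  expect_error(project_synteny(blk("a1", "c", 1, 500, "SYN"), c(c = 300)),
               "beyond")
})

test_that("closed-form windows: all syntenic 0, none 1, (1,1,0) two-thirds", {
  all_syn <- rbind(blk("a1", "c", 1, 100, "SYN"),
                   blk("a2", "c", 1, 100, "SYN"),
                   blk("a3", "c", 1, 100, "SYN"))
  expect_equal(synteny_diversity(project_synteny(all_syn, c(c = 100)),
                                 100)$pi_syn, 0)
  none <- rbind(blk("a1", "c", 1, 100, "NOTAL"),
                blk("a2", "c", 1, 100, "NOTAL"))
  expect_equal(synteny_diversity(project_synteny(none, c(c = 100)),
                                 100)$pi_syn, 1)
  mixed <- rbind(blk("a1", "c", 1, 100, "SYN"),
                 blk("a2", "c", 1, 100, "SYN"),
                 blk("a3", "c", 1, 100, "NOTAL"))
  expect_equal(synteny_diversity(project_synteny(mixed, c(c = 100)),
                                 100)$pi_syn, 2 / 3)
})

test_that("interval implementation equals per-position brute force", {
  set.seed(99)
  for (rep in 1:10) {
    len <- 5000L
    blocks <- random_syn_blocks(10L, len)
    ind <- project_synteny(blocks, c(ChrT = len))
    ws <- synteny_diversity(ind, 1000, 400)
    oracle <- brute_pi_syn(blocks, len, ws)
    expect_lt(max(abs(oracle - ws$pi_syn)), 1e-12)
  }
})

test_that("windows anchor at 1, step, and truncate the final window", {
  blocks <- blk("a1", "c", 1, 250, "SYN")
  blocks <- rbind(blocks, blk("a2", "c", 1, 250, "SYN"))
  ws <- synteny_diversity(project_synteny(blocks, c(c = 250)), 100, 100)
  expect_equal(ws$start, c(1, 101, 201))
  expect_equal(ws$end, c(100, 200, 250))
  expect_equal(ws$pi_syn, rep(0, 3))
})

test_that("pi_syn is invariant to accession order and duplication never raises it", {
  set.seed(101)
  len <- 4000L
  blocks <- random_syn_blocks(6L, len)
  ind <- project_synteny(blocks, c(ChrT = len))
  ws <- synteny_diversity(ind, 800, 800)

  # relabelling accessions leaves the statistic unchanged
  relab <- blocks
  map <- setNames(sprintf("Z%02d", 6:1), sprintf("A%02d", 1:6))
  relab$accession <- map[relab$accession]
  ws2 <- synteny_diversity(project_synteny(relab, c(ChrT = len)), 800, 800)
  expect_equal(ws2$pi_syn, ws$pi_syn)

  # duplicating one accession never increases pi_syn
  dup <- blocks[blocks$accession == "A01", ]
  dup$accession <- "A99"
  ws3 <- synteny_diversity(project_synteny(rbind(blocks, dup),
                                           c(ChrT = len)), 800, 800)
  expect_true(all(ws3$pi_syn <= ws$pi_syn + 1e-12))
})

test_that("threshold fractions are length-weighted", {
  stats <- data.frame(chrom = "c", start = c(1, 101), end = c(100, 200),
                      pi_syn = c(0, 1), n_pairs = 1)
  fr <- fraction_by_threshold(stats)
  expect_equal(unname(fr), c(0.5, 0.5))
  stats0 <- data.frame(chrom = "c", start = 1, end = 100, pi_syn = 0,
                       n_pairs = 1)
  expect_equal(unname(fraction_by_threshold(stats0)), c(1, 0))
  expect_error(fraction_by_threshold(stats0[0, ]), "empty")
})

test_that("a fully non-syntenic centromere drives pi_syn to 1 inside the span", {
  cfg <- small_cfg(seed = 53L)
  syn <- simulate_synteny(cfg)
  ind <- project_synteny(syn$blocks, cfg$ref_chrom_lengths)
  ws <- synteny_diversity(ind, 50000, 50000)
  cen <- cfg$centromere_spans[cfg$centromere_spans$chrom == "Chr1", ]
  inside <- ws$chrom == "Chr1" & ws$start >= cen$start & ws$end <= cen$end
  expect_true(all(ws$pi_syn[inside] == 1))
})

test_that("pairwise colinearity matrix is symmetric with sane diagonal", {
  blocks <- rbind(blk("a1", "c", 1, 100, "SYN"),
                  blk("a2", "c", 1, 100, "SYN"),
                  blk("a3", "c", 101, 200, "SYN"))
  ind <- project_synteny(blocks, c(c = 200))
  M <- pairwise_colinearity(ind, list(c = IRanges::IRanges(1, 200)))
  expect_true(isSymmetric(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(M["a1", "a2"], 0.5)   # both syntenic on 1-100
  expect_equal(M["a1", "a3"], 0)     # disjoint
  expect_equal(M["a1", "a1"], 0.5)   # diagonal: fraction vs reference

  # identical indicators: off-diagonal equals diagonal
  two <- rbind(blk("x", "c", 1, 150, "SYN"), blk("y", "c", 1, 150, "SYN"))
  M2 <- pairwise_colinearity(project_synteny(two, c(c = 200)),
                             list(c = IRanges::IRanges(1, 200)))
  expect_equal(M2["x", "y"], M2["x", "x"])

  expect_error(pairwise_colinearity(ind, list(c = IRanges::IRanges())),
               "empty")
})

test_that("group-private rearrangements lower between-group colinearity", {
  # group 1: inversion at 1-400; group 2: inversion at 601-1000
  g1 <- lapply(c("a1", "a2"), function(a)
    rbind(blk(a, "c", 1, 400, "INV"), blk(a, "c", 401, 1000, "SYN")))
  g2 <- lapply(c("b1", "b2"), function(a)
    rbind(blk(a, "c", 1, 600, "SYN"), blk(a, "c", 601, 1000, "INV")))
  ind <- project_synteny(do.call(rbind, c(g1, g2)), c(c = 1000))
  M <- pairwise_colinearity(ind, list(c = IRanges::IRanges(1, 1000)))
  groups <- c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2")
  summ <- colinearity_group_summary(M, groups)
  within <- summ$mean_colinearity[summ$group_a == summ$group_b]
  between <- summ$mean_colinearity[summ$group_a != summ$group_b]
  expect_true(all(within > between))
})
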