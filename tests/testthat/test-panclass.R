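test_that("category thresholds match the strict softcore rule", {
  b <- category_bounds(69)
  expect_equal(b$core, 69)
  expect_equal(b$softcore_min, 63)
  expect_equal(b$softcore_max, 68)
  expect_equal(b$dispensable_max, 62)

  # n = 10 under the 0.9 threshold: no integer m with 9 < m < 10
  b10 <- category_bounds(10)
  expect_gt(b10$softcore_min, b10$softcore_max)
})

test_that("classification assigns boundary presence counts correctly", {
  n <- 69
  mk <- function(m) as.integer(seq_len(n) <= m)
  pav <- tiny_pav(list(mk(69), mk(63), mk(62), mk(1), mk(0)),
                  accs = sprintf("a%02d", 1:69))
  cls <- classify_families(pav)
  expect_equal(as.character(cls$category),
               c("core", "softcore", "dispensable", "private", "absent"))
  expect_equal(sum(cls$counts), 4L)  # absent excluded
})

test_that("classification is monotone in presence count", {
  n <- 20
  pav <- tiny_pav(lapply(0:n, function(m) as.integer(seq_len(n) <= m)),
                  accs = sprintf("a%02d", seq_len(n)))
  cls <- classify_families(pav)
  ranks <- as.integer(cls$category)  # ordered factor
  expect_true(all(diff(ranks) >= 0))
})

test_that("composition computes gene-level fractions that sum to one", {
  # all-core matrix
  pav <- tiny_pav(list(c(1, 1, 1), c(2, 1, 1)))
  cls <- classify_families(pav)
  comp <- composition(pav, cls)
  expect_equal(unname(comp[, "core"]), rep(1, 3))

  # 9 core genes + 1 private gene in accession 1
  pav2 <- tiny_pav(c(lapply(1:9, function(i) c(1, 1, 1)), list(c(1, 0, 0))))
  cls2 <- classify_families(pav2)
  comp2 <- composition(pav2, cls2)
  expect_equal(unname(comp2["acc1", "core"]), 0.9)
  expect_equal(unname(comp2["acc1", "private"]), 0.1)
  expect_equal(unname(rowSums(comp2)), rep(1, 3))
})

test_that("exact rarefaction matches hand enumeration on the 3-accession case", {
  # f1 in all three accessions, f2 in accession 1 only
  pav <- tiny_pav(list(c(1, 1, 1), c(1, 0, 0)))
  ex <- rarefaction_exact(pav, sizes = 2)
  expect_equal(ex$pan, 5 / 3)   # subsets {12},{13},{23}: pan 2,2,1
  expect_equal(ex$core, 1)

  ex3 <- rarefaction_exact(pav, sizes = 3)
  expect_equal(ex3$pan, 2)      # k = n: all families present
  expect_equal(ex3$core, 1)     # only f1 in all
})

test_that("exact rarefaction equals exhaustive subset enumeration", {
  set.seed(7)
  pav <- matrix(rbinom(10 * 40, 1, 0.5), 40, 10,
                dimnames = list(sprintf("F%02d", 1:40), sprintf("a%d", 1:10)))
  ex <- rarefaction_exact(pav, sizes = 1:10)
  for (k in 1:10) {
    oracle <- enum_rarefaction(pav, k)
    expect_equal(ex$pan[[k]], oracle$pan, tolerance = 1e-12)
    expect_equal(ex$core[[k]], oracle$core, tolerance = 1e-12)
  }
  # pan non-decreasing, core non-increasing
  expect_true(all(diff(ex$pan) >= -1e-12))
  expect_true(all(diff(ex$core) <= 1e-12))
})

test_that("Monte Carlo rarefaction is seeded, bounded and near the exact curve", {
  set.seed(13)
  pav <- matrix(rbinom(8 * 60, 1, 0.6), 60, 8)
  dimnames(pav) <- list(sprintf("F%02d", 1:60), sprintf("a%d", 1:8))
  mc1 <- rarefaction_mc(pav, sizes = 2:6, replicates = 400, seed = 5)
  mc2 <- rarefaction_mc(pav, sizes = 2:6, replicates = 400, seed = 5)
  expect_identical(mc1, mc2)
  expect_true(all(mc1$pan_mean >= mc1$core_mean))
  ex <- rarefaction_exact(pav, sizes = 2:6)
  tol <- 4 * pmax(mc1$pan_sd, 1e-9) / sqrt(400)
  expect_true(all(abs(mc1$pan_mean - ex$pan) <= pmax(tol, 0.5)))
  # k = n: single possible subset, sd must be 0
  mcn <- rarefaction_mc(pav, sizes = 8, replicates = 50, seed = 1)
  expect_equal(mcn$pan_sd, 0)
  expect_equal(mcn$pan_mean, sum(rowSums(pav) > 0))
  expect_equal(mcn$core_mean, sum(rowSums(pav) == 8))
  expect_error(rarefaction_mc(pav, sizes = 9), "exceeds")
})

test_that("fusion merges qualifying RBH pairs and nothing else", {
  og <- og_table(list(
    OGa = list(A = "gA", B = character(0)),
    OGb = list(A = character(0), B = "gB"),
    OGc = list(A = "gC", B = character(0)),
    OGd = list(A = character(0), B = "gD")),
    accessions = c("A", "B"))
  hits <- data.frame(
    query = c("gA", "gB", "gC", "gD"),
    target = c("gB", "gA", "gD", "gC"),
    cov_query = c(0.96, 0.97, 0.94, 0.99),
    cov_target = c(0.97, 0.96, 0.99, 0.94),
    score = c(10, 10, 10, 10))
  fused <- fuse_orthogroups(og, hits)
  expect_equal(length(fused), 3L)               # OGa+OGb merged
  expect_setequal(unlist(fused[["OGa"]]), c("gA", "gB"))
  expect_true(all(c("OGc", "OGd") %in% names(fused)))  # 0.94 side blocks fusion

  # no qualifying hits: table unchanged
  same <- fuse_orthogroups(og, hits[3:4, ])
  expect_equal(names(same), names(og))
  # unknown gene in hits is an error
  bad <- hits; bad$query[[1L]] <- "nope"
  expect_error(fuse_orthogroups(og, bad), "unknown gene")
})

test_that("fusion requires reciprocity, is idempotent and order-independent", {
  cases <- simulate_fusion_cases(120, seed = 3)
  fused <- fuse_orthogroups(cases$og, cases$hits)
  for (i in seq_len(nrow(cases$truth))) {
    merged <- !(cases$truth$og_b[[i]] %in% names(fused))
    expect_equal(merged, cases$truth$expect_fused[[i]],
                 label = paste("case", i, cases$truth$scenario[[i]]))
  }
  expect_lte(length(fused), length(cases$og))
  # idempotent
  again <- fuse_orthogroups(fused, cases$hits)
  expect_equal(names(again), names(fused))
  # order-independent: permute hit rows
  set.seed(1)
  shuffled <- cases$hits[sample.int(nrow(cases$hits)), ]
  fused2 <- fuse_orthogroups(cases$og, shuffled)
  expect_equal(names(fused2), names(fused))
  expect_equal(og_to_pav(fused2), og_to_pav(fused))
})

test_that("split/merge flagging needs sub-threshold parts with joint coverage", {
  og <- og_table(list(F1 = list(A = "rep1", B = c("x1", "x2")),
                      F2 = list(A = "rep2", B = c("y1", "y2")),
                      F3 = list(A = "rep3", B = "z1")),
                 accessions = c("A", "B"))
  gm <- data.frame(
    accession = c("A", "B", "B", "A", "B", "B", "A", "B"),
    gene = c("rep1", "x1", "x2", "rep2", "y1", "y2", "rep3", "z1"),
    chrom = "Chr1",
    start = c(1, 1, 600, 2000, 2000, 2600, 5000, 5000),
    end = c(1000, 500, 1100, 3000, 2500, 3100, 5800, 5900))
  hits <- data.frame(
    query = c("x1", "x2", "y1", "y2"),
    target = c("rep1", "rep1", "rep2", "rep2"),
    cov_query = 0.9, cov_target = 0.5,
    # F1: disjoint parts 0.45 + 0.53 -> joint 0.98; F2: same half twice
    t_start = c(1, 451, 1, 1),
    t_end = c(450, 980, 500, 500),
    score = 10)
  flags <- flag_split_merge(og, gm, hits)
  expect_true(flags[["F1"]])
  expect_false(flags[["F2"]])   # union stuck at 0.5
  expect_false(flags[["F3"]])   # single gene per accession: never flagged

  expect_error(flag_split_merge(og, gm[-1, ], hits), "missing gene")
})

test_that("split/merge flagging requires adjacency in gene order", {
  og <- og_table(list(F1 = list(A = "rep1", B = c("x1", "x2")),
                      F2 = list(A = "other", B = "mid")),
                 accessions = c("A", "B"))
  # an unrelated gene sits between x1 and x2 in accession B
  gm <- data.frame(
    accession = c("A", "B", "B", "A", "B"),
    gene = c("rep1", "x1", "x2", "other", "mid"),
    chrom = "Chr1",
    start = c(1, 1, 1200, 3000, 600),
    end = c(1000, 500, 1700, 3500, 1100))
  hits <- data.frame(query = c("x1", "x2"), target = "rep1",
                     cov_query = 0.9, cov_target = 0.5,
                     t_start = c(1, 451), t_end = c(450, 980), score = 10)
  flags <- flag_split_merge(og, gm, hits)
  expect_false(flags[["F1"]])
})
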