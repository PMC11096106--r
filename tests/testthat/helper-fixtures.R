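# Shared fixture builders.  Everything is generated in code; no data files.

# tiny presence/absence count matrix with named rows/cols
tiny_pav <- function(rows, accs = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(accs)) accs <- sprintf("acc%d", seq_len(ncol(m)))
  dimnames(m) <- list(sprintf("f%d", seq_len(nrow(m))), accs)
  storage.mode(m) <- "integer"
  m
}

# synteny blocks data.frame from compact arguments
blk <- function(accession, chrom, start, end, type) {
  data.frame(accession = accession, ref_chrom = chrom,
             ref_start = start, ref_end = end,
             qry_chrom = chrom, qry_start = start, qry_end = end,
             type = type, stringsAsFactors = FALSE)
}

# random synteny instance on one chromosome; every accession gets at least
# one block so it is represented in the indicator
random_syn_blocks <- function(n_acc, len, max_blocks = 6L) {
  do.call(rbind, lapply(sprintf("A%02d", seq_len(n_acc)), function(a) {
    k <- sample(0:max_blocks, 1L)
    if (k == 0L) return(blk(a, "ChrT", 1, len, "NOTAL"))
    s <- sort(sample.int(len - 50L, k))
    e <- pmin(s + sample.int(max(50L, len %/% 10L), k, replace = TRUE) + 10L,
              len)
    blk(a, "ChrT", s, e, "SYN")
  }))
}

# per-position brute-force pi_syn oracle over a logical accession x position
# matrix; independent of the interval implementation
brute_pi_syn <- function(blocks, len, windows) {
  accs <- sort(unique(blocks$accession))
  S <- matrix(FALSE, length(accs), len, dimnames = list(accs, NULL))
  syn <- blocks[blocks$type == "SYN", , drop = FALSE]
  for (i in seq_len(nrow(syn)))
    S[syn$accession[[i]], syn$ref_start[[i]]:syn$ref_end[[i]]] <- TRUE
  n <- length(accs)
  vapply(seq_len(nrow(windows)), function(w) {
    p <- windows$start[[w]]:windows$end[[w]]
    tot <- 0
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
      tot <- tot + mean(1 - S[i, p] * S[j, p])
    tot / (n * (n - 1) / 2)
  }, numeric(1))
}

# exhaustive rarefaction oracle: enumerate all k-subsets
enum_rarefaction <- function(pav, k) {
  pres <- pav >= 1L
  subs <- utils::combn(ncol(pres), k)
  pan <- apply(subs, 2L, function(cols)
    sum(rowSums(pres[, cols, drop = FALSE]) > 0L))
  core <- apply(subs, 2L, function(cols)
    sum(rowSums(pres[, cols, drop = FALSE]) == k))
  list(pan = mean(pan), core = mean(core))
}

# small simulation config used across tests (fast); 12 accessions so the
# strict softcore range (0.9 n < m < n) is non-empty
small_cfg <- function(seed = 11L, copy_range = c(20L, 60L), ...) {
  sim_config(n_accessions = 12L, n_families = 200L,
             copy_range = copy_range,
             ref_chrom_lengths = c(Chr1 = 1e6, Chr2 = 6e5),
             centromere_spans = data.frame(
               chrom = c("Chr1", "Chr2"),
               start = c(4e5, 2.5e5), end = c(6e5, 3.5e5)),
             inversion_size_range = c(5e4, 1.5e5),
             shared_inversion = list(chrom = "Chr1", start = 1e5,
                                     length = 1.2e5, n_carriers = 4L),
             background_length = 6000L,
             tel_copies = 10L,
             seed = seed, ...)
}
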