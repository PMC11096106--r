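# Windowed synteny diversity on reference coordinates.
#
# Accession i is syntenic at reference position p (s_i(p) = 1) iff p falls
# inside a SYN block of the i-vs-reference alignment; positions covered only
# by rearranged (INV/TRANS/DUP/...) or unaligned (NOTAL) blocks count as
# non-syntenic.  For a window w over n accessions,
#
#   pi_syn(w) = [2 / (n (n - 1))] * sum_{i<j} (1/|w|) sum_{p in w}
#               (1 - s_i(p) s_j(p))
#
# i.e. the mean over accession pairs of the fraction of window positions
# not jointly syntenic: 0 = the group is fully colinear, 1 = no colinearity.
# The per-position pair sum collapses to choose(S(p), 2) where
# S(p) = sum_i s_i(p), which is what the implementation exploits.

#' Project per-accession synteny blocks to reference indicator intervals
#'
#' @param blocks Data.frame of blocks (as from [read_syri()], any number of
#'   accessions) with columns `accession`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `type`.
#' @param chrom_lengths Named vector of reference chromosome lengths.
#' @return A `syn_indicator`: list accession -> chromosome ->
#'   `IRanges` of merged syntenic intervals, with a `chrom_lengths`
#'   attribute.
#' @export
project_synteny <- function(blocks, chrom_lengths) {
  beyond <- !is.na(blocks$ref_end) &
    blocks$ref_end > chrom_lengths[blocks$ref_chrom]
  if (any(beyond, na.rm = TRUE))
    stop("block(s) extend beyond chromosome end: ",
         paste(utils::head(which(beyond), 5L), collapse = ", "))
  syn <- blocks[blocks$type == "SYN", , drop = FALSE]
  accs <- sort(unique(blocks$accession))
  out <- lapply(accs, function(a) {
    sub <- syn[syn$accession == a, , drop = FALSE]
    res <- lapply(names(chrom_lengths), function(chrom) {
      s <- sub[sub$ref_chrom == chrom, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(s$ref_start, s$ref_end))
    })
    names(res) <- names(chrom_lengths)
    res
  })
  names(out) <- accs
  structure(out, chrom_lengths = chrom_lengths, class = "syn_indicator")
}

#' @export
print.syn_indicator <- function(x, ...) {
  cat("syn_indicator:", length(x), "accessions,",
      length(attr(x, "chrom_lengths")), "chromosomes\n")
  invisible(x)
}

# Rle of S(p) = number of accessions syntenic at each position of one chrom
.syn_count_rle <- function(ind, chrom) {
  len <- attr(ind, "chrom_lengths")[[chrom]]
  total <- S4Vectors::Rle(0L, len)
  for (a in names(ind))
    total <- total + IRanges::coverage(ind[[a]][[chrom]], width = len)
  total
}

#' Windowed average pairwise diversity in synteny
#'
#' Windows are anchored at position 1 and advance by `step`; the last
#' window of each chromosome is truncated to the chromosome end and kept
#' with its true length.
#'
#' @param ind A `syn_indicator` from [project_synteny()] (n >= 2
#'   accessions).
#' @param window Window size in bp.
#' @param step Step size in bp (<= window).
#' @return Data.frame with columns `chrom`, `start`, `end`, `pi_syn`,
#'   `n_pairs`.
#' @export
synteny_diversity <- function(ind, window, step = window) {
  stopifnot(window > 0, step > 0, step <= window)
  n <- length(ind)
  if (n < 2L) stop("synteny diversity needs at least 2 accessions")
  n_pairs <- n * (n - 1) / 2
  lens <- attr(ind, "chrom_lengths")
  out <- lapply(names(lens), function(chrom) {
    len <- lens[[chrom]]
    S <- .syn_count_rle(ind, chrom)
    pair_rle <- S * (S - 1L) / 2           # choose(S(p), 2), positionwise
    starts <- seq.int(1L, len, by = step)
    ends <- pmin(starts + window - 1L, len)
    v <- IRanges::Views(pair_rle, start = starts, end = ends)
    joint <- IRanges::viewSums(v)
    data.frame(chrom = chrom, start = starts, end = ends,
               pi_syn = 1 - joint / ((ends - starts + 1) * n_pairs),
               n_pairs = n_pairs, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome fractions below/above synteny-diversity thresholds
#'
#' Length-weighted fractions of the windowed genome with pi_syn strictly
#' below `low` and strictly above `high`.
#'
#' @param stats Data.frame from [synteny_diversity()].
#' @param low Lower threshold (default 0.2, the "highly colinear" bound).
#' @param high Upper threshold (default 0.5, the "highly diverse" bound).
#' @return Named numeric vector `c(below, above)`.
#' @export
fraction_by_threshold <- function(stats, low = 0.2, high = 0.5) {
  if (!nrow(stats)) stop("empty window table")
  w <- stats$end - stats$start + 1
  c(below = sum(w[stats$pi_syn < low]) / sum(w),
    above = sum(w[stats$pi_syn > high]) / sum(w))
}

#' Pairwise colinearity matrix over masked-in reference positions
#'
#' Entry (i, j) is the fraction of positions inside `arm_mask` where
#' accessions i and j are both syntenic to the reference; the diagonal
#' holds each accession's syntenic fraction against the reference itself.
#'
#' @param ind A `syn_indicator`.
#' @param arm_mask Named list (per chromosome) of `IRanges` giving the
#'   positions to evaluate (typically chromosome arms, excluding
#'   centromeres/pericentromeres).
#' @return Symmetric accession x accession matrix of fractions in [0, 1].
#' @export
pairwise_colinearity <- function(ind, arm_mask) {
  chroms <- intersect(names(attr(ind, "chrom_lengths")), names(arm_mask))
  mask <- lapply(arm_mask[chroms], IRanges::reduce)
  tot <- sum(vapply(mask, function(r) sum(IRanges::width(r)), numeric(1)))
  if (tot == 0) stop("empty arm mask")
  accs <- names(ind)
  # pre-intersect each accession with the mask
  masked <- lapply(ind, function(per_acc)
    lapply(chroms, function(ch)
      IRanges::intersect(per_acc[[ch]], mask[[ch]])))
  M <- matrix(0, length(accs), length(accs), dimnames = list(accs, accs))
  for (i in seq_along(accs)) {
    M[i, i] <- sum(vapply(masked[[i]], function(r)
      sum(IRanges::width(r)), numeric(1))) / tot
    if (i == length(accs)) break
    for (j in seq.int(i + 1L, length(accs))) {
      joint <- sum(vapply(seq_along(chroms), function(k)
        sum(IRanges::width(IRanges::intersect(masked[[i]][[k]],
                                              masked[[j]][[k]]))),
        numeric(1)))
      M[i, j] <- M[j, i] <- joint / tot
    }
  }
  M
}

#' Within- and between-group mean colinearity
#'
#' @param M Matrix from [pairwise_colinearity()].
#' @param groups Named character vector mapping accession to group.
#' @return Data.frame of group pairs with mean off-diagonal colinearity;
#'   rows with `group_a == group_b` are within-group means.
#' @export
colinearity_group_summary <- function(M, groups) {
  groups <- groups[rownames(M)]
  gl <- sort(unique(groups))
  res <- list()
  for (a in gl) for (b in gl) {
    if (b < a) next
    ia <- which(groups == a); ib <- which(groups == b)
    vals <- if (a == b) {
      if (length(ia) < 2L) NA_real_
      else M[ia, ia][upper.tri(M[ia, ia])]
    } else as.vector(M[ia, ib, drop = FALSE])
    res[[length(res) + 1L]] <- data.frame(
      group_a = a, group_b = b, mean_colinearity = mean(vals),
      n_pairs = if (a == b) choose(length(ia), 2) else length(ia) * length(ib),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
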