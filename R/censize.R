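# Tandem-repeat array annotation and depth-ratio abundance estimation.
#
# Assembled arrays are annotated by approximate motif matching (banded edit
# distance via Biostrings, greedy non-overlapping tiling, gap-merging into
# arrays).  The true genomic repeat abundance, independent of assembly
# completeness, is estimated from short-read depth piled onto a small
# concatemer of the motif: summed concatemer depth divided by genome-wide
# mean depth gives bp of genomic repeat.

#' Parameters for tandem-repeat array annotation
#'
#' @param motif DNA motif sequence (e.g. the ~178-bp centromeric satellite
#'   monomer or the 7-bp telomeric repeat).
#' @param max_divergence Maximum edit distance per motif copy, as a fraction
#'   of motif length (default 0.20).
#' @param max_gap Maximum gap in bp between matches merged into one array
#'   (default: one motif length).
#' @param concatemer_copies Motif copies in the depth-estimation concatemer
#'   (default 4).
#' @return A `repeat_params` list.
#' @export
repeat_params <- function(motif, max_divergence = 0.20, max_gap = NULL,
                          concatemer_copies = 4L) {
  motif <- toupper(as.character(motif))
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be plain A/C/G/T DNA")
  stopifnot(max_divergence >= 0, max_divergence < 0.5)
  if (is.null(max_gap)) max_gap <- nchar(motif)
  structure(list(motif = motif, max_divergence = max_divergence,
                 max_gap = max_gap, concatemer_copies = concatemer_copies),
            class = "repeat_params")
}

# greedy left-to-right selection of non-overlapping matches
.greedy_tile <- function(starts, ends) {
  if (!length(starts)) return(integer(0))
  o <- order(starts, ends)
  keep <- integer(0)
  last_end <- 0
  for (i in o) {
    if (starts[[i]] > last_end) {
      keep <- c(keep, i)
      last_end <- ends[[i]]
    }
  }
  keep
}

# motif matches on one strand of one sequence; returns IRanges
.match_motif <- function(subject, motif, max_edit) {
  m <- Biostrings::matchPattern(motif, subject, max.mismatch = max_edit,
                                with.indels = TRUE)
  IRanges::IRanges(Biostrings::start(m), Biostrings::end(m))
}

#' Annotate tandem repeat arrays in a sequence
#'
#' Scans both strands for motif matches within edit distance
#' `max_divergence * motif length`, keeps a greedy non-overlapping tiling
#' (per strand), and merges matches separated by at most `max_gap` bp into
#' arrays.  `copy_estimate` is array length divided by motif length.
#'
#' @param sequence A `DNAString`/`DNAStringSet` element or character
#'   sequence.
#' @param params A [repeat_params()] object.
#' @return Data.frame with columns `start`, `end`, `strand`,
#'   `copy_estimate` (1-based inclusive coordinates on the input sequence).
#' @export
find_repeat_arrays <- function(sequence, params) {
  seq <- Biostrings::DNAString(as.character(sequence))
  mlen <- nchar(params$motif)
  if (mlen > length(seq))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), copy_estimate = numeric(0)))
  max_edit <- floor(params$max_divergence * mlen)
  motif_f <- Biostrings::DNAString(params$motif)
  motif_r <- Biostrings::reverseComplement(motif_f)
  out <- list()
  for (strand in c("+", "-")) {
    motif <- if (strand == "+") motif_f else motif_r
    hits <- .match_motif(seq, motif, max_edit)
    keep <- .greedy_tile(IRanges::start(hits), IRanges::end(hits))
    hits <- hits[keep]
    if (!length(hits)) next
    merged <- IRanges::reduce(hits, min.gapwidth = params$max_gap + 1L)
    out[[strand]] <- data.frame(
      start = IRanges::start(merged), end = IRanges::end(merged),
      strand = strand,
      copy_estimate = IRanges::width(merged) / mlen,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), copy_estimate = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[res$end - res$start + 1L >= mlen, , drop = FALSE]
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Total assembled repeat length per chromosome
#'
#' @param seqs A `DNAStringSet` of chromosome sequences.
#' @param params A [repeat_params()] object.
#' @return Data.frame with columns `chrom`, `repeat_bp`, `n_arrays`.
#' @export
assembled_repeat_length <- function(seqs, params) {
  res <- lapply(names(seqs), function(chrom) {
    arr <- find_repeat_arrays(seqs[[chrom]], params)
    data.frame(chrom = chrom,
               repeat_bp = sum(arr$end - arr$start + 1L),
               n_arrays = nrow(arr), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Depth-ratio estimate of genomic repeat length
#'
#' The summed per-base depth over the motif concatemer, divided by the
#' genome-wide mean depth, estimates the total bp of the repeat in the
#' genome regardless of how much of it was assembled.
#'
#' @param depth_concatemer Integer vector (or single-element depth track
#'   list) of per-base depth over the concatemer.
#' @param genome_mean_depth Genome-wide mean fold-coverage (> 0), ideally
#'   computed over non-repeat positions (see [genome_mean_depth()]).
#' @return Estimated repeat length in bp.
#' @export
estimate_repeat_length <- function(depth_concatemer, genome_mean_depth) {
  if (is.list(depth_concatemer))
    depth_concatemer <- unlist(depth_concatemer, use.names = FALSE)
  if (!is.numeric(genome_mean_depth) || genome_mean_depth <= 0)
    stop("genome mean depth must be positive")
  sum(as.numeric(depth_concatemer)) / genome_mean_depth
}

#' Mean genome depth over non-repeat positions
#'
#' Masking out annotated repeat arrays avoids the circularity of partially
#' assembled arrays depressing (or collapsed arrays inflating) the
#' denominator of the depth-ratio estimator.
#'
#' @param track Named list of per-chromosome depth vectors.
#' @param arrays Optional data.frame with columns `chrom`, `start`, `end`
#'   of positions to exclude.
#' @return Mean depth over unmasked positions.
#' @export
genome_mean_depth <- function(track, arrays = NULL) {
  tot <- 0; npos <- 0
  for (chrom in names(track)) {
    v <- track[[chrom]]
    keep <- rep(TRUE, length(v))
    if (!is.null(arrays)) {
      a <- arrays[arrays$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(a)))
        keep[seq.int(max(1L, a$start[i]), min(length(v), a$end[i]))] <- FALSE
    }
    tot <- tot + sum(as.numeric(v[keep]))
    npos <- npos + sum(keep)
  }
  if (npos == 0) stop("no unmasked positions")
  tot / npos
}

#' Assembly completeness ratio
#'
#' Assembled length divided by an orthogonal estimate of the true length;
#' serves both for repeat arrays (assembled array bp vs depth-ratio
#' estimate) and whole assemblies (assembly size vs k-mer style genome-size
#' estimate).  Values above 1 are legal (over-assembly / estimator noise)
#' and flagged via an attribute.
#'
#' @param assembled_bp Assembled length (bp).
#' @param estimated_bp Estimated true length (bp, > 0).
#' @return The ratio, with attribute `over_assembled` when > 1.
#' @export
completeness_ratio <- function(assembled_bp, estimated_bp) {
  if (any(estimated_bp <= 0)) stop("estimated length must be positive")
  r <- assembled_bp / estimated_bp
  attr(r, "over_assembled") <- r > 1
  r
}

#' Pearson correlations between genome-size components
#'
#' @param table Data.frame of per-accession size columns (e.g. assembly
#'   size, total centromeric repeat bp, TE bp, per-chromosome centromere
#'   bp).
#' @param comparisons Optional 2-column character matrix / data.frame of
#'   column pairs to test; defaults to all pairs.
#' @return Data.frame with columns `a`, `b`, `r`, `p`, `n`; zero-variance
#'   columns give `r = NA` with a note column.
#' @export
size_correlations <- function(table, comparisons = NULL) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) < 3L) stop("need at least 3 accessions")
  if (is.null(comparisons)) {
    cn <- names(num)
    comparisons <- t(utils::combn(cn, 2L))
  }
  res <- lapply(seq_len(nrow(comparisons)), function(i) {
    a <- comparisons[i, 1L]; b <- comparisons[i, 2L]
    x <- num[[a]]; y <- num[[b]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(a = a, b = b, r = NA_real_, p = NA_real_,
                        n = length(x), note = "zero variance",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(a = a, b = b, r = unname(ct$estimate), p = ct$p.value,
               n = length(x), note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
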