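# Cross-accession merging of structural variants by breakpoint distance,
# following the SURVIVOR-style parameterisation: records of the same type on
# the same chromosome are single-linkage clustered when both breakpoints lie
# within max_dist of each other.  Two size tiers mirror common practice:
# 20 bp - 10 kb merged at 1 kb breakpoint distance, > 10 kb merged at 20 kb.

#' Merge parameters for SV clustering
#'
#' @param max_dist Maximum breakpoint distance in bp, applied independently
#'   to start and end coordinates (1000 for the small tier, 20000 for the
#'   large tier).
#' @param min_support Minimum accession support to report a cluster
#'   (default 1).
#' @param type_match Require identical SV type within a cluster (default
#'   TRUE).
#' @param size_range Length bounds (bp) of the tier; records outside are
#'   rejected with a warning.
#' @return A `merge_params` list.
#' @export
merge_params <- function(max_dist = 1000, min_support = 1,
                         type_match = TRUE, size_range = c(20, 10000)) {
  stopifnot(max_dist >= 0, min_support >= 1)
  structure(list(max_dist = max_dist, min_support = min_support,
                 type_match = type_match, size_range = size_range),
            class = "merge_params")
}

#' Tier presets used throughout the package
#'
#' @param tier `"small"` (20 bp - 10 kb, max_dist 1 kb) or `"large"`
#'   (> 10 kb, max_dist 20 kb).
#' @return A [merge_params()] object.
#' @export
tier_params <- function(tier = c("small", "large")) {
  tier <- match.arg(tier)
  if (tier == "small") merge_params(1000, size_range = c(20, 10000))
  else merge_params(20000, size_range = c(10001, Inf))
}

#' Single-linkage merge of SVs across accessions
#'
#' Two records link iff they have the same type (when `type_match`), the
#' same chromosome, and both |delta start| and |delta end| are at most
#' `max_dist`.  Clusters are the transitive closure of links; each cluster
#' reports per-coordinate medians as representative coordinates, the number
#' of distinct supporting accessions, and the member accession list.  With
#' `max_dist = 0` the operation degenerates to exact-coordinate
#' deduplication.
#'
#' @param records Data.frame with columns `accession`, `type`, `chrom`,
#'   `start`, `end`, `length`.
#' @param params A [merge_params()] object.
#' @return Data.frame of clusters: `cluster`, `type`, `chrom`, `start`,
#'   `end`, `length` (medians), `support`, `n_records`, `accessions`
#'   (comma-joined, sorted).
#' @export
merge_svs <- function(records, params = merge_params()) {
  if (!nrow(records)) {
    return(data.frame(cluster = integer(0), type = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      support = integer(0), n_records = integer(0),
                      accessions = character(0), stringsAsFactors = FALSE))
  }
  out_of_tier <- records$length < params$size_range[[1L]] |
    records$length > params$size_range[[2L]]
  if (any(out_of_tier)) {
    warning(sum(out_of_tier), " record(s) outside the tier size range [",
            params$size_range[[1L]], ", ", params$size_range[[2L]],
            "] bp dropped")
    records <- records[!out_of_tier, , drop = FALSE]
  }
  if (!nrow(records)) return(merge_svs(records, params))
  gkey <- if (params$type_match) paste(records$chrom, records$type)
          else records$chrom
  cluster_id <- integer(nrow(records))
  next_id <- 0L
  for (g in split(seq_len(nrow(records)), gkey)) {
    o <- g[order(records$start[g], records$end[g])]
    s <- records$start[o]; e <- records$end[o]
    k <- length(o)
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(k)) {
      j <- i + 1L
      while (j <= k && s[j] - s[i] <= params$max_dist) {
        if (abs(e[j] - e[i]) <= params$max_dist) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    cluster_id[o] <- next_id + match(roots, unique(roots))
    next_id <- next_id + length(unique(roots))
  }
  cl <- lapply(split(seq_len(nrow(records)), cluster_id), function(ix) {
    r <- records[ix, , drop = FALSE]
    accs <- sort(unique(r$accession))
    data.frame(type = r$type[[1L]], chrom = r$chrom[[1L]],
               start = stats::median(r$start), end = stats::median(r$end),
               length = stats::median(r$length),
               support = length(accs), n_records = nrow(r),
               accessions = paste(accs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cl)
  out <- out[order(out$chrom, out$start, out$type), , drop = FALSE]
  out <- out[out$support >= params$min_support, , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("cluster", "type", "chrom", "start", "end", "length",
          "support", "n_records", "accessions")]
}

#' Summaries of merged SV clusters
#'
#' @param clusters Data.frame from [merge_svs()].
#' @param size_breaks Histogram breaks in bp for the size distribution.
#' @return List with `by_type` (count and size quantiles per type),
#'   `size_hist` (data.frame of bin, count) and `support_spectrum` (named
#'   count vector: number of clusters at each support level).
#' @export
sv_summary <- function(clusters,
                       size_breaks = c(0, 100, 1000, 10000, 20000, Inf)) {
  if (!nrow(clusters)) {
    return(list(by_type = data.frame(type = character(0), n = integer(0),
                                     median_length = numeric(0),
                                     max_length = numeric(0)),
                size_hist = data.frame(bin = character(0), count = integer(0)),
                support_spectrum = integer(0)))
  }
  by_type <- do.call(rbind, lapply(split(clusters, clusters$type), function(d)
    data.frame(type = d$type[[1L]], n = nrow(d),
               median_length = stats::median(d$length),
               max_length = max(d$length), stringsAsFactors = FALSE)))
  rownames(by_type) <- NULL
  h <- table(cut(clusters$length, breaks = size_breaks, include.lowest = TRUE))
  spectrum <- table(clusters$support)
  list(by_type = by_type,
       size_hist = data.frame(bin = names(h), count = as.integer(h),
                              stringsAsFactors = FALSE),
       support_spectrum = stats::setNames(as.integer(spectrum),
                                          names(spectrum)))
}

#' Megabase-scale rearrangements among merged clusters
#'
#' @param clusters Data.frame from [merge_svs()] (large tier).
#' @param min_len Minimum representative length in bp (default 1e6).
#' @return Clusters with length >= `min_len`, sorted by decreasing length.
#' @export
find_large_rearrangements <- function(clusters, min_len = 1e6) {
  out <- clusters[clusters$length >= min_len, , drop = FALSE]
  out[order(-out$length), , drop = FALSE]
}
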