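# Readers and writers for the tabular formats the pipeline consumes and
# produces.  All genomic coordinates are 1-based inclusive, matching the
# SyRI / GFF3 convention; half-open arithmetic never leaks out of the
# window code in syndiv.R.

#' Read an orthogroup membership table
#'
#' Parses the `Orthogroups.tsv` dialect produced by all-vs-all orthology
#' clustering tools: a header line with a family-id column followed by one
#' column per accession, and rows whose cells hold comma+space-joined gene
#' identifiers (empty cell = family absent from that accession).
#'
#' @param path Path to a tab-separated orthogroup file.
#' @return An object of class `og_table`: a named list (one element per
#'   family) of named lists (one element per accession) of character vectors
#'   of gene ids, with an `accessions` attribute fixing column order.
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty orthogroup file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop("orthogroup header must name at least one accession")
  accs <- header[-1L]
  n_col <- length(header)
  fams <- vector("list", length(lines) - 1L)
  ids <- character(length(fams))
  for (i in seq_along(fams)) {
    n_tab <- lengths(gregexpr("\t", lines[[i + 1L]], fixed = TRUE))
    if (!grepl("\t", lines[[i + 1L]], fixed = TRUE)) n_tab <- 0L
    if (n_tab != n_col - 1L)
      stop("ragged orthogroup row ", i + 1L, ": ", n_tab + 1L,
           " cells, expected ", n_col)
    cells <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    cells <- c(cells, rep("", n_col - length(cells)))  # trailing empties
    ids[[i]] <- cells[[1L]]
    genes <- lapply(cells[-1L], function(x) {
      if (!nzchar(x)) character(0) else strsplit(x, ", ", fixed = TRUE)[[1L]]
    })
    names(genes) <- accs
    fams[[i]] <- genes
  }
  if (anyDuplicated(ids))
    stop("duplicate family id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(fams) <- ids
  og_table(fams, accs)
}

#' Construct an orthogroup table object
#'
#' @param families Named list: family id -> named list of per-accession
#'   character vectors of gene ids.
#' @param accessions Character vector fixing accession order.
#' @return An `og_table`.
#' @export
og_table <- function(families, accessions) {
  stopifnot(is.list(families))
  structure(families, accessions = accessions, class = "og_table")
}

#' @export
print.og_table <- function(x, ...) {
  cat("og_table:", length(x), "families x",
      length(attr(x, "accessions")), "accessions\n")
  invisible(x)
}

#' Write an orthogroup table
#'
#' Inverse of [read_orthogroups()]; genes within a cell are joined with
#' `", "` and absent cells are left empty.
#'
#' @param og An `og_table`.
#' @param path Output path.
#' @export
write_orthogroups <- function(og, path) {
  accs <- attr(og, "accessions")
  rows <- vapply(names(og), function(fid) {
    cells <- vapply(accs, function(a) {
      g <- og[[fid]][[a]]
      if (is.null(g) || length(g) == 0L) "" else paste(g, collapse = ", ")
    }, character(1))
    paste(c(fid, cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("Orthogroup", accs), collapse = "\t"), rows), path)
}

# Closed vocabulary of top-level whole-genome-alignment annotation types.
SYRI_TOP_LEVEL <- c("SYN", "INV", "TRANS", "DUP", "INVTR", "INVDP", "NOTAL")

#' Read top-level structural annotations from a SyRI output file
#'
#' Only top-level block rows (SYN, INV, TRANS, DUP, INVTR, INVDP, NOTAL) are
#' retained; alignment-level rows such as SYNAL are silently skipped, and
#' rows with unknown annotation codes are skipped with a single warning
#' reporting the count.
#'
#' @param path Path to a SyRI-style TSV (>= 11 columns: ref chrom/start/end,
#'   ref seq, qry seq, qry chrom/start/end, id, parent, type).
#' @param accession Accession name attached to every returned block.
#' @return A data.frame with columns `accession`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `qry_chrom`, `qry_start`, `qry_end`, `type`.
#' @export
read_syri <- function(path, accession) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", fill = FALSE)
  if (ncol(raw) < 11L)
    stop("expected >= 11 tab-separated columns in ", path,
         ", found ", ncol(raw))
  type <- raw[[11L]]
  known_al <- paste0(setdiff(SYRI_TOP_LEVEL, "NOTAL"), "AL")
  keep <- type %in% SYRI_TOP_LEVEL
  unknown <- !keep & !(type %in% known_al) & !grepl("AL$", type) &
    !(type %in% c("SNP", "INS", "DEL", "CPG", "CPL", "HDR", "TDM"))
  if (any(unknown))
    warning(sum(unknown), " row(s) with unknown annotation code skipped (",
            paste(unique(type[unknown]), collapse = ", "), ")")
  raw <- raw[keep, , drop = FALSE]
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "-", NA, x)))
  out <- data.frame(
    accession = rep(accession, nrow(raw)),
    ref_chrom = raw[[1L]],
    ref_start = num(raw[[2L]]),
    ref_end   = num(raw[[3L]]),
    qry_chrom = raw[[6L]],
    qry_start = num(raw[[7L]]),
    qry_end   = num(raw[[8L]]),
    type      = raw[[11L]],
    stringsAsFactors = FALSE
  )
  bad <- !is.na(out$ref_start) & !is.na(out$ref_end) & out$ref_start > out$ref_end
  if (any(bad)) stop("ref_start > ref_end in ", sum(bad), " row(s) of ", path)
  out
}

#' Write synteny/SV blocks in the SyRI output dialect
#'
#' @param blocks Data.frame as returned by [read_syri()].
#' @param path Output path.
#' @export
write_syri <- function(blocks, path) {
  fmt <- function(x) ifelse(is.na(x), "-", format(x, scientific = FALSE, trim = TRUE))
  id <- paste0(blocks$type, seq_len(nrow(blocks)))
  lines <- paste(blocks$ref_chrom, fmt(blocks$ref_start), fmt(blocks$ref_end),
                 "-", "-",
                 blocks$qry_chrom, fmt(blocks$qry_start), fmt(blocks$qry_end),
                 id, "-", blocks$type, "-", sep = "\t")
  writeLines(lines, path)
}

#' Read a per-base depth track
#'
#' Parses 3-column TSV output of `samtools depth -a` (chrom, 1-based
#' position, depth) into dense per-chromosome integer vectors.  Positions
#' missing from the file are filled with depth 0; positions must be strictly
#' increasing within each chromosome.
#'
#' @param path Path to the depth TSV.
#' @param seq_lengths Optional named vector of chromosome lengths used to pad
#'   the tail of each vector with zeros.
#' @return Named list of integer vectors, one per chromosome.
#' @export
read_depth <- function(path, seq_lengths = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "pos", "depth"),
                           colClasses = c("character", "integer", "integer"))
  out <- lapply(split(tab, tab$chrom)[unique(tab$chrom)], function(d) {
    if (is.unsorted(d$pos, strictly = TRUE))
      stop("non-monotone positions in depth track for ", d$chrom[[1L]])
    len <- max(d$pos)
    if (!is.null(seq_lengths) && d$chrom[[1L]] %in% names(seq_lengths))
      len <- max(len, seq_lengths[[d$chrom[[1L]]]])
    v <- integer(len)
    v[d$pos] <- d$depth
    v
  })
  out
}

#' Write a per-base depth track
#'
#' Zero-depth positions are written explicitly, matching `samtools depth -a`.
#'
#' @param track Named list of integer depth vectors.
#' @param path Output path.
#' @export
write_depth <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    if (length(v))
      writeLines(paste(chrom, seq_along(v), v, sep = "\t"), con)
  }
  invisible(path)
}

#' Write / read a presence-absence count matrix
#'
#' The native on-disk form is a counts TSV: a header of accession names and
#' one row per family of non-negative integer gene counts.
#'
#' @param pav Integer matrix, families x accessions, with dimnames.
#' @param path File path.
#' @return `read_pav` returns the integer matrix.
#' @export
write_pav <- function(pav, path) {
  df <- data.frame(family = rownames(pav), pav, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pav
#' @export
read_pav <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' Export a binary presence matrix in relaxed phylip format
#'
#' Accession names are truncated to 10 characters and right-padded; a
#' post-truncation name collision is an error.  Each row is the accession
#' name followed by a 0/1 string over families (presence = count >= 1).
#'
#' @param pav Counts matrix, families x accessions.
#' @param path Output path.
#' @export
write_pav_phylip <- function(pav, path) {
  nm <- substr(colnames(pav), 1L, 10L)
  if (anyDuplicated(nm))
    stop("accession name collision after 10-character truncation: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  bin <- ifelse(t(pav) >= 1L, "1", "0")   # accessions x families
  rows <- apply(bin, 1L, paste, collapse = "")
  writeLines(c(paste(ncol(pav), nrow(pav)),
               paste0(formatC(nm, width = 10L, flag = "-"), rows)), path)
  invisible(path)
}

#' Write / read structural-variant records
#'
#' Simple TSV with columns accession, type, chrom, start, end, length
#' (1-based inclusive coordinates).
#'
#' @param sv Data.frame of SV records.
#' @param path File path.
#' @export
write_sv <- function(sv, path) {
  utils::write.table(sv[, c("accession", "type", "chrom", "start", "end", "length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sv
#' @export
read_sv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "numeric", "numeric", "numeric"))
}

#' Write gene models as GFF3
#'
#' One `gene` feature per row with `ID=` attribute; used for the gene-order
#' adjacency needed by split/merge-artifact detection.
#'
#' @param genes Data.frame with columns `gene`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else rep("+", nrow(genes))
  lines <- paste(genes$chrom, "pansynkit", "gene",
                 format(genes$start, scientific = FALSE, trim = TRUE),
                 format(genes$end, scientific = FALSE, trim = TRUE),
                 ".", strand, ".", paste0("ID=", genes$gene), sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path Path to a GFF3 file of `gene` features.
#' @return Data.frame with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  data.frame(gene = as.character(gr$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read / write genome sequences
#'
#' Thin wrappers over Biostrings FASTA IO so the rest of the package deals
#' in `DNAStringSet` objects.
#'
#' @param path FASTA path.
#' @param seqs A `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
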