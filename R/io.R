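#' Read a Hi-C contact matrix from a text file
#'
#' Two per-chromosome text formats are supported. `dense` is a
#' whitespace-delimited square matrix. `triplet` is the sparse long format
#' with one `i j count` record per line, bin ordinals 0-based; only one
#' triangle needs to be given, symmetry is enforced by mirroring each record.
#'
#' @param path file path.
#' @param format `"dense"` or `"triplet"`.
#' @param resolution bin size in bp.
#' @param chrom chromosome name attached to the result.
#' @param p number of bins; required for `triplet` (a triplet file cannot
#'   reveal trailing empty bins), ignored for `dense`.
#' @param ... passed to [contact_matrix()].
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense", "triplet"),
                                resolution, chrom = "chr1", p = NULL, ...) {
  format <- match.arg(format)
  if (format == "dense") {
    mat <- tryCatch(
      as.matrix(read.table(path, header = FALSE,
                           colClasses = "numeric", comment.char = "#")),
      error = function(e) stop("failed to parse dense matrix '", path,
                               "': ", conditionMessage(e))
    )
    dimnames(mat) <- NULL
    return(contact_matrix(mat, resolution = resolution, chrom = chrom, ...))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("parse error in '", path, "' at line ", bad[1L],
         ": expected 3 fields 'i j count', got ", lengths(fields)[bad[1L]])
  rec <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 3L, byrow = TRUE)
  bad <- which(!stats::complete.cases(rec))
  if (length(bad))
    stop("parse error in '", path, "' at line ", bad[1L],
         ": non-numeric field")
  i <- rec[, 1L]; j <- rec[, 2L]; v <- rec[, 3L]
  if (any(i != floor(i)) || any(j != floor(j)) || any(i < 0) || any(j < 0))
    stop("triplet indices must be non-negative integers (0-based)")
  if (is.null(p)) p <- as.integer(max(i, j)) + 1L
  oob <- which(i >= p | j >= p)
  if (length(oob))
    stop("triplet index out of bounds at line ", oob[1L], ": bin ",
         max(i[oob[1L]], j[oob[1L]]), " with p = ", p)
  mat <- matrix(0, p, p)
  mat[cbind(i + 1L, j + 1L)] <- v
  mat[cbind(j + 1L, i + 1L)] <- v
  contact_matrix(mat, resolution = resolution, chrom = chrom, ...)
}

#' Write a Hi-C contact matrix to a text file
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @param format `"dense"` (square whitespace-delimited matrix) or
#'   `"triplet"` (upper-triangle `i j count` records, 0-based, zeros omitted).
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "contact_matrix"))
  if (format == "dense") {
    write.table(m$counts, path, row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
                 arr.ind = TRUE)
    ord <- order(idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]
    df <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L,
                     count = m$counts[idx])
    write.table(df, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Thin wrapper over `rtracklayer::import()` that validates records and
#' returns intervals sorted within chromosome. BED is 0-based half-open;
#' the returned GRanges uses the usual 1-based closed convention.
#'
#' @param path a BED3+ file.
#' @return a sorted [GenomicRanges::GRanges].
#' @export
read_intervals <- function(path) {
  raw <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3L)
    stop("BED file '", path, "' needs at least 3 columns")
  bad <- which(!(raw[[2L]] < raw[[3L]]))
  if (length(bad))
    stop("invalid interval at record ", bad[1L], ": start (", raw[bad[1L], 2L],
         ") must be < end (", raw[bad[1L], 3L], ")")
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::sort(gr)
}

#' Write genomic intervals to a BED file
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path) {
  rtracklayer::export(GenomicRanges::sort(gr), path, format = "BED")
  invisible(path)
}
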