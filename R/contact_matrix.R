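#' Binned per-chromosome Hi-C contact matrix
#'
#' Constructs the container used throughout the package: a symmetric,
#' non-negative count matrix over uniform genomic bins of width `resolution`,
#' together with its bin table. Rows with zero total coverage are flagged as
#' masked (unmappable) rather than dropped, so bin ordinals stay aligned with
#' genome coordinates.
#'
#' @param counts numeric p x p matrix, symmetric within `tol`, entries finite
#'   and non-negative.
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @param start bp coordinate of the first bin (0-based).
#' @param normalized logical; `TRUE` if the matrix has been balance-normalized.
#' @param tol relative tolerance for the symmetry check; asymmetry beyond it
#'   is an error, below it the matrix is symmetrized by averaging.
#' @return An object of class `contact_matrix`: a list with elements `counts`,
#'   `bins` (data.frame chrom/start/end/index), `resolution`, `chrom`,
#'   `normalized` and `masked` (logical vector, zero-coverage bins).
#' @export
contact_matrix <- function(counts, resolution, chrom = "chr1", start = 0,
                           normalized = FALSE, tol = 1e-6) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("'counts' must be square, got ", nrow(counts), " x ", ncol(counts))
  if (!all(is.finite(counts)))
    stop("'counts' contains non-finite entries")
  if (any(counts < 0))
    stop("'counts' contains negative entries")
  scale <- max(abs(counts), 1)
  asym <- max(abs(counts - t(counts)))
  if (asym > tol * scale)
    stop("matrix is asymmetric beyond tolerance (max |a_ij - a_ji| = ",
         format(asym), ")")
  counts <- (counts + t(counts)) / 2
  p <- nrow(counts)
  if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0)
    stop("'resolution' must be a single positive number")
  bins <- data.frame(
    chrom = chrom,
    start = start + (seq_len(p) - 1L) * resolution,
    end   = start + seq_len(p) * resolution,
    index = seq_len(p)
  )
  structure(
    list(counts = counts, bins = bins, resolution = resolution,
         chrom = chrom, normalized = normalized,
         masked = rowSums(counts) == 0),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  p <- nrow(x$counts)
  cat(sprintf("contact_matrix: %s, %d bins @ %s bp (%s)\n",
              x$chrom, p, format(x$resolution, big.mark = ","),
              if (x$normalized) "normalized" else "raw counts"))
  cat(sprintf("  masked bins: %d / %d; total counts: %s\n",
              sum(x$masked), p, format(sum(x$counts), digits = 6)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' Bin table as GRanges
#'
#' @param m a `contact_matrix`.
#' @param which optional bin ordinals (1-based) to keep.
#' @return a [GenomicRanges::GRanges] of the bins (0-based half-open bp
#'   converted to the 1-based closed GRanges convention).
#' @export
bins_as_granges <- function(m, which = NULL) {
  b <- m$bins
  if (!is.null(which)) b <- b[which, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = b$chrom,
    ranges = IRanges::IRanges(start = b$start + 1L, end = b$end),
    index = b$index
  )
}
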