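#' Build the pair table from a contact matrix
#'
#' Extracts the upper-triangle bin pairs up to a maximal separation and
#' attaches the log genomic distance used as the polymer-decay covariate.
#' The diagonal (separation 0) is excluded; adjacent pairs (separation 1)
#' carry no insulation information but anchor the short-range distance trend
#' and are kept. Pairs involving masked bins are dropped.
#'
#' @param m a [contact_matrix()].
#' @param max_gap maximal separation in bins (default 10, i.e. contacts up to
#'   10 bin widths apart enter the models).
#' @return a data.frame of class `pair_table` with columns `i`, `j` (1-based
#'   bin ordinals, `i < j`), `y` (count), `gap` (`j - i`), `d` (log bp
#'   distance); attributes `p`, `resolution`, `max_gap`, `masked`.
#' @export
build_pair_table <- function(m, max_gap = 10) {
  stopifnot(inherits(m, "contact_matrix"))
  if (max_gap < 2)
    stop("'max_gap' must be >= 2: no pair can have an in-between bin otherwise")
  p <- nrow(m$counts)
  gaps <- seq_len(min(max_gap, p - 1L))
  i <- unlist(lapply(gaps, function(g) seq_len(p - g)))
  g <- rep(gaps, times = p - gaps)
  j <- i + g
  keep <- !(m$masked[i] | m$masked[j])
  i <- i[keep]; j <- j[keep]; g <- g[keep]
  pt <- data.frame(
    i = i, j = j,
    y = m$counts[cbind(i, j)],
    gap = g,
    d = log(g * m$resolution)
  )
  pt <- pt[order(pt$i, pt$j), ]
  rownames(pt) <- NULL
  attr(pt, "p") <- p
  attr(pt, "resolution") <- m$resolution
  attr(pt, "max_gap") <- max_gap
  attr(pt, "masked") <- m$masked
  attr(pt, "chrom") <- m$chrom
  attr(pt, "bins") <- m$bins
  class(pt) <- c("pair_table", "data.frame")
  pt
}

#' Combine pair tables from replicate experiments
#'
#' Row-binds pair tables that share a bin table (e.g. replicate Hi-C maps of
#' the same region), keeping the coordinate attributes of the first. Useful
#' to train a prediction model on pooled replicates.
#'
#' @param ... `pair_table` objects with identical `p`, `resolution` and
#'   `max_gap`.
#' @return a combined `pair_table`.
#' @export
bind_pair_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) > 0, all(vapply(tabs, inherits, TRUE, "pair_table")))
  for (a in c("p", "resolution", "max_gap")) {
    vals <- vapply(tabs, function(t) attr(t, a), numeric(1))
    if (length(unique(vals)) != 1L)
      stop("pair tables differ in '", a, "'")
  }
  out <- do.call(rbind, lapply(tabs, function(t) as.data.frame(t)))
  rownames(out) <- NULL
  for (a in c("p", "resolution", "max_gap", "masked", "chrom", "bins"))
    attr(out, a) <- attr(tabs[[1L]], a)
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Build the sparse insulation design matrix
#'
#' One indicator column per candidate bin: entry (pair, bin) is 1 when the
#' bin lies strictly between the two bins of the pair, 0 otherwise. With all
#' bins as candidates every row sums to `gap - 1`; adjacent pairs give
#' all-zero rows.
#'
#' @param pairs a `pair_table` from [build_pair_table()].
#' @param candidate_bins bin ordinals (1-based) used as columns; defaults to
#'   all bins.
#' @return a sparse [Matrix::sparseMatrix] (rows = pairs, columns = candidate
#'   bins, in the order given) with attribute `candidates`.
#' @export
build_insulation_design <- function(pairs, candidate_bins = NULL) {
  p <- attr(pairs, "p")
  if (is.null(candidate_bins)) candidate_bins <- seq_len(p)
  candidate_bins <- as.integer(candidate_bins)
  if (any(candidate_bins < 1L) || any(candidate_bins > p))
    stop("candidate bins must lie in [1, ", p, "]")
  if (anyDuplicated(candidate_bins))
    stop("duplicate candidate bins")
  span <- which(pairs$gap >= 2L)
  reps <- pairs$gap[span] - 1L
  row <- rep.int(span, reps)
  bin <- rep.int(pairs$i[span], reps) + sequence(reps)
  col <- match(bin, candidate_bins)
  keep <- !is.na(col)
  X <- Matrix::sparseMatrix(
    i = row[keep], j = col[keep], x = 1,
    dims = c(nrow(pairs), length(candidate_bins)),
    dimnames = list(NULL, paste0("bin", candidate_bins))
  )
  attr(X, "candidates") <- candidate_bins
  X
}
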