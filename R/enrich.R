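#' Feature enrichment at a set of bins
#'
#' Fold-change enrichment of interval features (ChIP-seq peaks, motif
#' occurrences) at a foreground bin set versus background: the fraction of
#' foreground bins overlapping at least one feature divided by the same
#' fraction among background bins, with a binomial test of the foreground
#' overlap count against the background rate. The unit is the bin
#' (overlap yes/no), not bp coverage.
#'
#' @param foreground bin ordinals (1-based) of interest, e.g. border bins.
#' @param m the [contact_matrix()] defining the bin table.
#' @param features a [GenomicRanges::GRanges] of feature intervals (e.g.
#'   from [read_intervals()]).
#' @param background bin ordinals to compare against; default all unmasked
#'   bins.
#' @param feature_name label carried into the result.
#' @return one-row data.frame of class `enrichment_result`: `feature`,
#'   `fold_change`, `fg_rate`, `bg_rate`, `n_fg`, `n_bg`, `p` (binomial),
#'   and `defined` (`FALSE` when the background rate is zero).
#' @export
compute_enrichment <- function(foreground, m, features, background = NULL,
                               feature_name = "feature") {
  stopifnot(inherits(m, "contact_matrix"))
  p <- nrow(m$counts)
  foreground <- as.integer(foreground)
  if (!length(foreground)) stop("empty foreground bin set")
  if (any(foreground < 1L) || any(foreground > p))
    stop("foreground bins out of range")
  if (is.null(background)) background <- which(!m$masked)
  hits <- GenomicRanges::countOverlaps(bins_as_granges(m), features) > 0
  fg_rate <- mean(hits[foreground])
  bg_rate <- mean(hits[background])
  defined <- bg_rate > 0
  pval <- if (defined)
    binom.test(sum(hits[foreground]), length(foreground),
               p = bg_rate)$p.value else NA_real_
  out <- data.frame(
    feature = feature_name,
    fold_change = if (defined) fg_rate / bg_rate else NA_real_,
    fg_rate = fg_rate, bg_rate = bg_rate,
    n_fg = length(foreground), n_bg = length(background),
    p = pval, defined = defined, stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment stratified by border strength
#'
#' One enrichment per beta threshold: the foreground of stratum `t` is the
#' set of border bins with `beta < t`. Sorting the thresholds by decreasing
#' magnitude shows how enrichment scales with border strength.
#'
#' @param fit a `sim_fit`/`insulation_fit`.
#' @param m the [contact_matrix()] the fit came from.
#' @param features feature intervals ([GenomicRanges::GRanges]).
#' @param thresholds negative beta cutoffs (sorted by magnitude internally).
#' @param background passed to [compute_enrichment()].
#' @return data.frame with one row per non-empty stratum (column
#'   `threshold`); empty strata are skipped with a message.
#' @export
stratified_enrichment <- function(fit, m, features,
                                  thresholds = c(-0.5, -1.0, -1.5, -2.0),
                                  background = NULL) {
  if (any(thresholds >= 0)) stop("thresholds must be negative")
  thresholds <- thresholds[order(abs(thresholds))]
  rows <- lapply(thresholds, function(t) {
    fg <- which(fit$beta < t)
    if (!length(fg)) {
      message("stratum beta < ", t, " is empty; skipped")
      return(NULL)
    }
    r <- compute_enrichment(fg, m, features, background = background,
                            feature_name = paste0("beta<", t))
    r$threshold <- t
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all strata are empty")
  out
}
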