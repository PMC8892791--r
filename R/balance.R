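#' ICE matrix balancing
#'
#' Iterative correction of a raw contact matrix: each unmasked row/column is
#' divided by its coverage bias until all unmasked row sums agree. Masked
#' (zero-coverage) rows are left untouched and excluded from the equal-row-sum
#' target. The balanced matrix is rescaled so its total count equals the input
#' total, which keeps the count scale interpretable downstream.
#'
#' @param m a [contact_matrix()] of raw counts.
#' @param method balancing method; only `"ICE"` is implemented.
#' @param max_iter iteration cap.
#' @param rtol convergence tolerance on the row-sum coefficient of variation.
#' @return a balanced [contact_matrix()] with `normalized = TRUE`, carrying
#'   attributes `biases` (per-bin multiplicative bias, NA for masked bins) and
#'   `converged`.
#' @export
balance_matrix <- function(m, method = "ICE", max_iter = 200, rtol = 1e-4) {
  stopifnot(inherits(m, "contact_matrix"))
  method <- match.arg(method, "ICE")
  keep <- !m$masked
  if (!any(keep)) stop("all bins are masked; nothing to balance")
  W <- m$counts[keep, keep, drop = FALSE]
  b <- rep(1, nrow(W))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    s_rel <- s / mean(s)
    if (max(abs(s_rel - 1)) < rtol) { converged <- TRUE; break }
    W <- W / outer(s_rel, s_rel)
    b <- b * s_rel
  }
  if (!converged)
    warning("ICE did not converge in ", max_iter,
            " iterations; returning best iterate")
  total <- sum(m$counts[keep, keep])
  W <- W * (total / sum(W))
  out <- m
  out$counts[keep, keep] <- W
  out$counts <- (out$counts + t(out$counts)) / 2
  out$normalized <- TRUE
  biases <- rep(NA_real_, nrow(m$counts))
  biases[keep] <- b
  attr(out, "biases") <- biases
  attr(out, "converged") <- converged
  out
}
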