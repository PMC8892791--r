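#' Sparse insulation model (SIM): call TAD borders and facilitators
#'
#' The full SIM pipeline on one chromosome: build the pair table up to
#' `max_gap`, remove the polymer distance effect with a negative-binomial
#' spline regression, then regress the log-scale residuals on per-bin
#' spanning indicators under an L0 penalty chosen by 10-fold
#' cross-validation. Bins with negative coefficients insulate the contacts
#' that span them (TAD borders); positive coefficients mark facilitators.
#' When more than `prefilter_trigger` candidate bins exist, a cross-validated
#' lasso prefilter (|coefficient| > `prefilter_threshold`) reduces the set
#' before the best-subset search.
#'
#' @param m a [contact_matrix()].
#' @param max_gap maximal pair separation in bins (default 10).
#' @param spline_df spline basis dimension for the distance trend.
#' @param nlambda,cv_folds,cv_rule,seed passed to [fit_best_subset()].
#' @param prefilter_threshold,prefilter_trigger passed to
#'   [prefilter_lasso()].
#' @param strong,moderate border tier thresholds, see [classify_borders()].
#' @param force_prefilter apply the lasso prefilter regardless of the
#'   trigger (used to study prefilter fidelity).
#' @return an object of class `sim_fit` extending `insulation_fit`, with the
#'   distance trend, residuals, classification table, merged border regions
#'   and the bin table.
#' @seealso [fit_best_subset()], [classify_borders()], [fit_dim()]
#' @export
fit_sim <- function(m, max_gap = 10, spline_df = 8, nlambda = 50,
                    cv_folds = 10, cv_rule = c("1se", "min"),
                    prefilter_threshold = 0.2,
                    prefilter_trigger = 5000, strong = -2.0, moderate = -1.2,
                    seed = 1789, force_prefilter = FALSE, pseudocount = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  pairs <- build_pair_table(m, max_gap = max_gap)
  trend <- fit_distance_trend(pairs, spline_df = spline_df)
  z <- compute_residuals(pairs, trend, pseudocount = pseudocount)
  p <- nrow(m$counts)
  X <- build_insulation_design(pairs)
  spanning <- which(Matrix::colSums(X) > 0 & !m$masked)
  X <- X[, spanning, drop = FALSE]
  attr(X, "candidates") <- spanning
  # Frisch-Waugh step: the count-scale trend absorbs the per-distance mean
  # of the insulation effects, leaving a residual offset linear in the
  # indicator row sums (gap - 1). Centering the indicator columns within
  # each gap stratum (the residuals are already gap-centered) makes the
  # sparse fit estimate within-stratum contrasts, which is the insulation
  # signal proper, instead of spending coefficients on that offset.
  X <- gap_center_design(X, pairs$gap, candidates = spanning)
  cand <- prefilter_lasso(z, X, threshold = prefilter_threshold,
                          trigger = prefilter_trigger, seed = seed,
                          force = force_prefilter)
  prefiltered <- length(cand) < length(spanning)
  if (prefiltered) {
    keep <- match(cand, spanning)
    X <- X[, keep, drop = FALSE]
    attr(X, "candidates") <- cand
  }
  fit <- if (length(cand) == 0L) empty_insulation_fit(p, strong, moderate)
         else fit_best_subset(z, X, p = p, nlambda = nlambda,
                              cv_folds = cv_folds, cv_rule = cv_rule,
                              seed = seed,
                              strong = strong, moderate = moderate)
  fit$pairs <- pairs
  fit$trend <- trend
  fit$residuals <- z
  fit$bins <- m$bins
  fit$chrom <- m$chrom
  fit$resolution <- m$resolution
  fit$masked <- m$masked
  fit$max_gap <- max_gap
  fit$prefiltered <- prefiltered
  fit$regions <- merge_border_regions(fit$beta, m$bins)
  fit$call <- match.call()
  class(fit) <- c("sim_fit", class(fit))
  fit
}

# Center each design column within the gap strata; returns a dense matrix
# (centered indicators are no longer sparse) carrying the candidate ids.
gap_center_design <- function(X, gap, candidates = NULL) {
  if (is.null(candidates)) candidates <- design_candidates(X)
  Xc <- as.matrix(X)
  for (g in unique(gap)) {
    idx <- which(gap == g)
    Xc[idx, ] <- sweep(Xc[idx, , drop = FALSE], 2L,
                       colMeans(Xc[idx, , drop = FALSE]))
  }
  attr(Xc, "candidates") <- candidates
  Xc
}

# Adjacent selected bins of the same sign often split one physical border
# because their indicator columns are nearly collinear; report merged
# "border regions" for human-readable output while keeping per-bin betas.
merge_border_regions <- function(beta, bins) {
  sel <- which(beta != 0)
  if (!length(sel))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), beta = numeric(0),
                      class = character(0)))
  sgn <- sign(beta[sel])
  new_run <- c(TRUE, diff(sel) > 2 | diff(sgn) != 0)
  run <- cumsum(new_run)
  do.call(rbind, lapply(split(seq_along(sel), run), function(ix) {
    b <- sel[ix]
    data.frame(chrom = bins$chrom[b[1L]],
               start = bins$start[min(b)], end = bins$end[max(b)],
               beta = sum(beta[b]),
               class = if (sum(beta[b]) < 0) "border" else "facilitator")
  }))
}

#' @export
print.sim_fit <- function(x, ...) {
  cl <- x$classification
  nb <- sum(cl$class == "border"); nf <- sum(cl$class == "facilitator")
  cat(sprintf("sim_fit: %s, %d bins @ %s bp, max_gap = %d\n",
              x$chrom, length(x$beta),
              format(x$resolution, big.mark = ","), x$max_gap))
  cat(sprintf("  borders: %d (%d strong, %d moderate, %d weak); facilitators: %d\n",
              nb, sum(cl$tier == "strong", na.rm = TRUE),
              sum(cl$tier == "moderate", na.rm = TRUE),
              sum(cl$tier == "weak", na.rm = TRUE), nf))
  cat(sprintf("  lambda (10-fold CV): %s; distance trend: %s GAM%s\n",
              format(x$lambda, digits = 4), x$trend$family,
              if (x$prefiltered) "; lasso-prefiltered" else ""))
  invisible(x)
}

#' @export
summary.sim_fit <- function(object, ...) {
  print(object)
  sel <- object$classification[object$classification$class != "null", ]
  if (nrow(sel)) {
    sel$start <- object$bins$start[sel$bin]
    sel$end <- object$bins$end[sel$bin]
    print(sel[, c("bin", "start", "end", "beta", "class", "tier")],
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.sim_fit <- function(x, ...) {
  data.frame(chrom = x$bins$chrom, start = x$bins$start, end = x$bins$end,
             beta = x$beta, class = x$classification$class,
             tier = x$classification$tier, stringsAsFactors = FALSE)
}

#' @export
plot.sim_fit <- function(x, ...) {
  pos <- (x$bins$start + x$bins$end) / 2 / 1e6
  graphics::plot(pos, x$beta, type = "h",
                 col = ifelse(x$beta < 0, "firebrick",
                              ifelse(x$beta > 0, "steelblue", "grey")),
                 xlab = paste0(x$chrom, " position (Mb)"),
                 ylab = expression(hat(beta)), ...)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}

#' Write SIM results as a BED-like TSV
#'
#' One row per bin: chrom, start, end, beta, class, tier. CV diagnostics
#' (lambda, mean CV MSE) can be written alongside.
#'
#' @param fit a `sim_fit`.
#' @param path output TSV.
#' @param cv_path optional path for the CV curve TSV.
#' @return `path`, invisibly.
#' @export
write_sim_fit <- function(fit, path, cv_path = NULL) {
  write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cv_path))
    write.table(fit$cv, cv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
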