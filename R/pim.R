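#' Prediction insulation model (PIM): Poisson GLM of Hi-C counts
#'
#' Fits `log E[y | d, X] = b0 + b_d * d + X beta` by Poisson regression,
#' where `d` is log genomic distance and `X` the per-bin spanning
#' indicators. No sparsity penalty is used: sharp border identification is
#' not needed for prediction, and a dense beta profile captures graded
#' insulation. Bins that never span a pair (chromosome ends, masked bins)
#' are unidentifiable; their coefficients are fixed at zero and flagged.
#'
#' @param m a [contact_matrix()] of counts (non-integer values are rounded
#'   with a warning), or a `pair_table` from [build_pair_table()] — e.g.
#'   several replicate tables combined with [bind_pair_tables()].
#' @param max_gap maximal pair separation in bins (taken from the pair
#'   table when one is supplied).
#' @param candidate_bins optional restriction of the insulation variables
#'   (e.g. SIM-selected bins) for speed; default all bins.
#' @return an object of class `pim_fit`: `beta0`, `beta_d`, `beta_x`
#'   (length p, zeros for unidentifiable bins, flagged in `identifiable`),
#'   the training pair table and fitted means, and a quasi-Poisson
#'   `dispersion` diagnostic.
#' @export
fit_pim <- function(m, max_gap = 10, candidate_bins = NULL) {
  if (inherits(m, "pair_table")) {
    pairs <- m
    max_gap <- attr(pairs, "max_gap")
  } else {
    stopifnot(inherits(m, "contact_matrix"))
    pairs <- build_pair_table(m, max_gap = max_gap)
  }
  y <- pairs$y
  if (any(y != floor(y))) {
    warning("non-integer counts rounded for Poisson regression")
    y <- round(y)
  }
  p <- attr(pairs, "p")
  X <- build_insulation_design(pairs, candidate_bins = candidate_bins)
  cand <- design_candidates(X)
  spanning <- Matrix::colSums(X) > 0
  Xd <- as.matrix(X[, spanning, drop = FALSE])
  mm <- cbind(d = pairs$d, Xd)
  fit <- tryCatch({
    g <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, mm), y,
                                  family = poisson()))
    if (!g$converged || anyNA(g$coefficients)) stop("not converged")
    g
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("Poisson GLM did not converge; refitting with a tiny ridge penalty")
    gn <- glmnet::glmnet(mm, y, family = "poisson", alpha = 0,
                         lambda = 1e-6, standardize = FALSE)
    cf <- as.numeric(coef(gn))
    fitted_mu <- as.numeric(predict(gn, newx = mm, type = "response"))
    fit <- list(coefficients = setNames(cf, c("(Intercept)", colnames(mm))),
                fitted.values = fitted_mu, df.residual = length(y) - length(cf))
  }
  cf <- fit$coefficients
  beta_x <- numeric(p)
  beta_x[cand[spanning]] <- cf[colnames(Xd)]
  identifiable <- logical(p)
  identifiable[cand[spanning]] <- TRUE
  mu <- fit$fitted.values
  pearson <- (y - mu) / sqrt(mu)
  structure(list(
    beta0 = unname(cf["(Intercept)"]), beta_d = unname(cf["d"]),
    beta_x = beta_x, identifiable = identifiable,
    dispersion = sum(pearson^2) / fit$df.residual,
    pairs = pairs, fitted = mu,
    bins = attr(pairs, "bins"), resolution = attr(pairs, "resolution"),
    chrom = attr(pairs, "chrom"),
    p = p, max_gap = max_gap, call = match.call()
  ), class = "pim_fit")
}

#' @export
print.pim_fit <- function(x, ...) {
  cat(sprintf("pim_fit: %s, %d bins, max_gap = %d\n", x$chrom, x$p, x$max_gap))
  cat(sprintf("  beta_d = %.4f; %d insulation coefficients (%d unidentifiable)\n",
              x$beta_d, sum(x$identifiable), sum(!x$identifiable)))
  cat(sprintf("  quasi-Poisson dispersion: %.3f\n", x$dispersion))
  invisible(x)
}

#' @export
coef.pim_fit <- function(object, ...) {
  c("(Intercept)" = object$beta0, d = object$beta_d,
    setNames(object$beta_x, paste0("bin", seq_len(object$p))))
}

#' Chromosomal rearrangement specification
#'
#' An ordered list of deletions and inversions in bin ordinals. Operations
#' are applied left to right; the interval of a later operation refers to
#' the genome as already rearranged by the earlier ones. A deletion removes
#' at least one bin; an inversion must cover at least two.
#'
#' @param kind character vector, each `"deletion"` or `"inversion"`.
#' @param first,last 1-based inclusive bin ordinals of each interval.
#' @return an object of class `rearrangement` (a data.frame).
#' @export
rearrangement <- function(kind = character(0), first = integer(0),
                          last = integer(0)) {
  kind <- as.character(kind)
  if (!all(kind %in% c("deletion", "inversion")))
    stop("'kind' must be \"deletion\" or \"inversion\"")
  stopifnot(length(kind) == length(first), length(first) == length(last))
  first <- as.integer(first); last <- as.integer(last)
  if (any(first < 1L) || any(last < first))
    stop("need 1 <= first <= last for every operation")
  len <- last - first + 1L
  if (any(kind == "deletion" & len < 1L))
    stop("a deletion must remove at least one bin")
  if (any(kind == "inversion" & len < 2L))
    stop("an inversion must cover at least two bins")
  structure(data.frame(kind = kind, first = first, last = last,
                       stringsAsFactors = FALSE),
            class = c("rearrangement", "data.frame"))
}

# New-bin -> original-bin map after applying all operations to 1:p.
rearrangement_perm <- function(rearr, p) {
  stopifnot(inherits(rearr, "rearrangement"))
  perm <- seq_len(p)
  for (t in seq_len(nrow(rearr))) {
    a <- rearr$first[t]; b <- rearr$last[t]
    if (b > length(perm))
      stop("operation ", t, " interval [", a, ", ", b,
           "] out of range (current genome has ", length(perm), " bins)")
    if (rearr$kind[t] == "deletion") {
      perm <- perm[-(a:b)]
      if (!length(perm)) stop("deletion removes the whole chromosome")
    } else {
      perm[a:b] <- perm[b:a]
    }
  }
  perm
}

#' Rearranged model variables for PIM prediction
#'
#' Applies deletions/inversions to the bin table and recomputes the distance
#' variable and insulation indicators on the rearranged genome. For a
#' deletion, the separation of any surviving pair shrinks by the deleted
#' length between them and the deleted bins' insulation columns vanish; for
#' an inversion, bins are flipped in place and both variables are recomputed
#' from the new ordering. The pair universe is all pairs within `max_gap` on
#' the new bin table. Insulation columns stay indexed by *original* bin
#' ordinals so trained coefficients follow their bins.
#'
#' @param rearr a [rearrangement()].
#' @param p number of bins of the original genome.
#' @param max_gap maximal pair separation.
#' @param resolution bin size in bp.
#' @return list with `pairs` (data.frame `i`, `j`, `gap`, `d` on new
#'   ordinals), `X` (sparse indicators, `p` columns on original ordinals),
#'   `perm` (new -> original map), `old2new` (original -> new, `NA` if
#'   deleted) and `p_new`.
#' @export
apply_rearrangement <- function(rearr, p, max_gap, resolution) {
  perm <- rearrangement_perm(rearr, p)
  p_new <- length(perm)
  gaps <- seq_len(min(max_gap, p_new - 1L))
  i <- unlist(lapply(gaps, function(g) seq_len(p_new - g)))
  g <- rep(gaps, times = p_new - gaps)
  j <- i + g
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; g <- g[ord]
  pairs <- data.frame(i = i, j = j, gap = g, d = log(g * resolution))
  span <- which(g >= 2L)
  reps <- g[span] - 1L
  row <- rep.int(span, reps)
  newbin <- rep.int(i[span], reps) + sequence(reps)
  X <- Matrix::sparseMatrix(i = row, j = perm[newbin], x = 1,
                            dims = c(nrow(pairs), p),
                            dimnames = list(NULL, paste0("bin", seq_len(p))))
  old2new <- rep(NA_integer_, p)
  old2new[perm] <- seq_len(p_new)
  list(pairs = pairs, X = X, perm = perm, old2new = old2new, p_new = p_new)
}

#' Predict a contact map from a trained PIM, optionally after rearrangement
#'
#' Evaluates `exp(b0 + b_d d' + X' beta)` over the (possibly rearranged)
#' pair universe and assembles the symmetric matrix of predicted means.
#' With no rearrangement this reproduces the training fitted means exactly.
#'
#' @param object a `pim_fit`.
#' @param rearr optional [rearrangement()]; `NULL` predicts the wild type.
#' @param ... unused.
#' @return an object of class `predicted_matrix`: a [contact_matrix()]-like
#'   list whose `counts` hold predicted means within `max_gap` (`NA`
#'   elsewhere), plus `mu_pairs` (long form), `perm` and `old2new`
#'   provenance maps.
#' @export
predict.pim_fit <- function(object, rearr = NULL, ...) {
  if (is.null(rearr)) rearr <- rearrangement()
  rv <- apply_rearrangement(rearr, p = object$p, max_gap = object$max_gap,
                            resolution = object$resolution)
  eta <- object$beta0 + object$beta_d * rv$pairs$d +
    as.numeric(rv$X %*% object$beta_x)
  mu <- exp(eta)
  counts <- matrix(NA_real_, rv$p_new, rv$p_new)
  counts[cbind(rv$pairs$i, rv$pairs$j)] <- mu
  counts[cbind(rv$pairs$j, rv$pairs$i)] <- mu
  pairs <- rv$pairs
  pairs$mu <- mu
  origin <- object$bins$start[rv$perm]
  structure(list(
    counts = counts,
    bins = data.frame(chrom = object$chrom,
                      start = (seq_len(rv$p_new) - 1L) * object$resolution,
                      end = seq_len(rv$p_new) * object$resolution,
                      index = seq_len(rv$p_new),
                      origin_start = origin),
    resolution = object$resolution, chrom = object$chrom,
    max_gap = object$max_gap, mu_pairs = pairs,
    perm = rv$perm, old2new = rv$old2new
  ), class = "predicted_matrix")
}

#' @export
print.predicted_matrix <- function(x, ...) {
  cat(sprintf("predicted_matrix: %s, %d bins @ %s bp, pairs within %d bins\n",
              x$chrom, nrow(x$counts),
              format(x$resolution, big.mark = ","), x$max_gap))
  invisible(x)
}

#' Compare a predicted map with an observed one
#'
#' Three agreement measures over the shared pair universe (separations 1 to
#' `max_gap`): Pearson correlation of log counts (`log(x + 1)` scale),
#' Spearman correlation of counts, and the stratum-adjusted correlation
#' (SCC): per-separation Pearson correlations combined with weights
#' proportional to stratum size times the geometric mean rank standard
#' deviation, so the distance decay itself contributes nothing. Strata in
#' which either map is constant are skipped; if fewer than 3 usable strata
#' remain the SCC is returned as `NA` with `scc_defined = FALSE`.
#'
#' @param pred a `predicted_matrix` (or `contact_matrix`).
#' @param obs a [contact_matrix()] (or plain matrix) on the same bin table.
#' @param max_gap maximal separation; defaults to the prediction's.
#' @param smooth_h half-width of an optional 2D mean filter applied to both
#'   matrices before computing the SCC (0 = off, the default).
#' @return list with `pearson_log`, `spearman`, `scc`, `n_strata`,
#'   `scc_defined`.
#' @export
evaluate_prediction <- function(pred, obs, max_gap = NULL, smooth_h = 0) {
  P <- if (is.list(pred)) pred$counts else as.matrix(pred)
  O <- if (is.list(obs)) obs$counts else as.matrix(obs)
  if (!all(dim(P) == dim(O)))
    stop("prediction and observation have different bin tables (",
         nrow(P), " vs ", nrow(O), " bins)")
  if (is.null(max_gap))
    max_gap <- if (is.list(pred) && !is.null(pred$max_gap)) pred$max_gap
               else 10L
  if (smooth_h > 0) {
    P <- mean_filter(P, smooth_h)
    O <- mean_filter(O, smooth_h)
  }
  p <- nrow(P)
  xs <- list(); ys <- list()
  for (g in seq_len(min(max_gap, p - 1L))) {
    i <- seq_len(p - g)
    xs[[g]] <- P[cbind(i, i + g)]
    ys[[g]] <- O[cbind(i, i + g)]
  }
  x <- unlist(xs); y <- unlist(ys)
  keep <- is.finite(x) & is.finite(y)
  pearson_log <- cor(log(x[keep] + 1), log(y[keep] + 1))
  spearman <- cor(x[keep], y[keep], method = "spearman")
  num <- 0; den <- 0; n_strata <- 0L
  for (g in seq_along(xs)) {
    xg <- xs[[g]]; yg <- ys[[g]]
    ok <- is.finite(xg) & is.finite(yg)
    xg <- xg[ok]; yg <- yg[ok]
    if (length(xg) < 3L || sd(xg) == 0 || sd(yg) == 0) next
    r <- cor(xg, yg)
    w <- length(xg) * sqrt(var(rank(xg)) * var(rank(yg)))
    num <- num + w * r
    den <- den + w
    n_strata <- n_strata + 1L
  }
  scc_defined <- n_strata >= 3L && den > 0
  list(pearson_log = pearson_log, spearman = spearman,
       scc = if (scc_defined) num / den else NA_real_,
       n_strata = n_strata, scc_defined = scc_defined)
}

mean_filter <- function(M, h) {
  p <- nrow(M)
  out <- M
  for (i in seq_len(p)) {
    ri <- max(1L, i - h):min(p, i + h)
    for (j in seq_len(p)) {
      rj <- max(1L, j - h):min(p, j + h)
      block <- M[ri, rj]
      out[i, j] <- mean(block[is.finite(block)])
    }
  }
  out
}
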