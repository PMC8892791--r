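#' Lasso prefilter for the insulation design
#'
#' Best-subset search is only tractable up to a few thousand variables, so
#' when the candidate set is larger than `trigger` a cross-validated lasso is
#' fitted first and only bins whose lasso coefficient magnitude exceeds
#' `threshold` are retained. Below the trigger the candidate set is returned
#' unchanged.
#'
#' @param z residual vector (response).
#' @param X sparse insulation design over the candidate bins.
#' @param threshold coefficient-magnitude cutoff (default 0.2).
#' @param trigger prefilter only when the number of candidates exceeds this
#'   (default 5000).
#' @param seed seed for the cross-validation fold assignment.
#' @param force apply the lasso filter regardless of `trigger`.
#' @return integer vector of retained candidate bin ordinals (possibly empty,
#'   with a warning).
#' @export
prefilter_lasso <- function(z, X, threshold = 0.2, trigger = 5000,
                            seed = 1789, force = FALSE) {
  if (threshold <= 0) stop("'threshold' must be > 0")
  cand <- design_candidates(X)
  k <- ncol(X)
  if ((k <= trigger && !force) || k < 2L) return(cand)
  foldid <- withr::with_seed(seed, sample(rep_len(1:10, length(z))))
  cvfit <- glmnet::cv.glmnet(X, z, alpha = 1, foldid = foldid)
  beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1L]
  keep <- abs(beta) > threshold
  if (!any(keep)) {
    warning("lasso prefilter retained no variables; no borders will be called")
    return(integer(0))
  }
  cand[keep]
}

design_candidates <- function(X) {
  cand <- attr(X, "candidates")
  if (is.null(cand)) cand <- as.integer(sub("^bin", "", colnames(X)))
  cand
}

# Centered Gram-scale summaries: G = Xc'Xc, b = Xc'zc, ztz = zc'zc.
gram_summaries <- function(z, X) {
  n <- length(z)
  zbar <- mean(z)
  cm <- Matrix::colMeans(X)
  G <- as.matrix(Matrix::crossprod(X)) - n * tcrossprod(cm)
  b <- as.numeric(Matrix::crossprod(X, z)) - n * cm * zbar
  list(G = G, b = b, ztz = sum((z - zbar)^2), n = n, cm = cm, zbar = zbar)
}

# Exact best-subset path by exhaustive enumeration (k <= 15). The per-subset
# RSS does not depend on lambda, so the whole path is read off one sweep over
# the 2^k subsets. Ties: fewer variables, then lexicographically first.
l0_exact_path <- function(G, b, ztz, N, lambdas) {
  k <- nrow(G)
  if (k > 15L) stop("exact enumeration limited to 15 variables, got ", k)
  nsub <- bitwShiftL(1L, k)
  rss <- rep(Inf, nsub)
  size <- integer(nsub)
  coefs <- vector("list", nsub)
  rss[1L] <- ztz
  for (s in seq_len(nsub - 1L)) {
    S <- which(bitwAnd(s, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    size[s + 1L] <- length(S)
    bs <- tryCatch(solve(G[S, S, drop = FALSE], b[S]),
                   error = function(e) NULL)
    if (is.null(bs)) next
    rss[s + 1L] <- ztz - sum(b[S] * bs)
    coefs[[s + 1L]] <- bs
  }
  betas <- matrix(0, k, length(lambdas))
  objs <- numeric(length(lambdas))
  for (t in seq_along(lambdas)) {
    obj <- rss / N + lambdas[t] * size
    best <- which(obj <= min(obj) + 1e-12)
    best <- best[order(size[best], best)][1L]
    if (best > 1L) {
      S <- which(bitwAnd(best - 1L, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
      betas[S, t] <- coefs[[best]]
    }
    objs[t] <- obj[best]
  }
  list(beta = betas, objective = objs)
}

l0_path <- function(G, b, ztz, N, lambdas, exact) {
  if (exact) l0_exact_path(G, b, ztz, N, lambdas)
  else .l0_cd_path(G, b, ztz, N, lambdas)
}

#' L0-penalized best-subset regression with cross-validated penalty
#'
#' Fits `z ~ intercept + X beta` minimizing
#' `(1/N) sum (z - b0 - X beta)^2 + lambda ||beta||_0` over a decreasing
#' lambda grid, choosing `lambda` by K-fold cross-validation of the mean
#' squared error. For 12 or fewer candidates the solution is computed by
#' exhaustive subset enumeration; above that, coordinate descent with a swap
#' local search and OLS polish, warm-started along the path. Unselected
#' coefficients are exact zeros.
#'
#' @param z residual vector.
#' @param X sparse insulation design over the candidate bins (columns named
#'   `bin<k>`).
#' @param p total number of bins of the chromosome (defaults to the largest
#'   candidate ordinal).
#' @param lambda optional lambda grid (sorted decreasing internally);
#'   otherwise `nlambda` log-spaced values from just above the smallest
#'   lambda giving the empty model down to 1e-4 of it.
#' @param nlambda grid size.
#' @param cv_folds number of CV folds (default 10); folds are assigned by
#'   position modulo `cv_folds` after a seeded shuffle of the pairs.
#' @param cv_rule how the penalty is read off the CV curve: `"1se"` (default)
#'   takes the sparsest model within one standard error of the minimum,
#'   `"min"` takes the exact minimizer. Minimizing a noisy CV curve over a
#'   fine grid selects spurious variables with appreciable probability even
#'   on pure noise; the one-standard-error rule is the standard remedy and
#'   matches the conservative behaviour expected of a border caller.
#' @param seed fold-assignment seed.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` uses it when there are at most 12 candidates.
#' @param strong,moderate border-strength tier thresholds passed to
#'   [classify_borders()].
#' @return an object of class `insulation_fit`: per-bin `beta` (length `p`,
#'   exact zeros off-support), `beta0`, the selected `lambda`, the CV curve
#'   (`cv` data.frame), the candidate set and the classification table.
#' @export
fit_best_subset <- function(z, X, p = NULL, lambda = NULL, nlambda = 50,
                            cv_folds = 10, cv_rule = c("1se", "min"),
                            seed = 1789, exact = NULL,
                            strong = -2.0, moderate = -1.2) {
  cv_rule <- match.arg(cv_rule)
  cand <- design_candidates(X)
  if (is.null(p)) p <- if (length(cand)) max(cand) else 0L
  k <- ncol(X)
  if (cv_folds < 2) stop("'cv_folds' must be >= 2")
  if (k == 0L) {
    fit <- empty_insulation_fit(p, strong, moderate)
    return(fit)
  }
  n <- length(z)
  gs <- gram_summaries(z, X)
  dg <- diag(gs$G)
  ok <- dg > 1e-10
  if (is.null(lambda)) {
    lmax <- max(gs$b[ok]^2 / (n * dg[ok]), .Machine$double.eps)
    lambda <- exp(seq(log(lmax * 1.05), log(lmax * 1e-4),
                      length.out = nlambda))
  }
  lambda <- sort(unique(lambda), decreasing = TRUE)
  if (is.null(exact)) exact <- k <= 12L
  fold <- integer(n)
  perm <- withr::with_seed(seed, sample.int(n))
  fold[perm] <- ((seq_len(n) - 1L) %% cv_folds) + 1L
  mse <- matrix(NA_real_, length(lambda), cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    gtr <- gram_summaries(z[tr], X[tr, , drop = FALSE])
    path <- l0_path(gtr$G, gtr$b, gtr$ztz, sum(tr), lambda, exact)
    b0 <- gtr$zbar - as.numeric(crossprod(path$beta, gtr$cm))
    pred <- sweep(as.matrix(X[!tr, , drop = FALSE] %*% path$beta), 2L, b0, "+")
    mse[, f] <- colMeans((z[!tr] - pred)^2)
  }
  cv_mean <- rowMeans(mse)
  cv_se <- apply(mse, 1L, sd) / sqrt(cv_folds)
  imin <- which.min(cv_mean)  # grid is decreasing: ties resolve to sparser fits
  sel <- if (cv_rule == "1se") {
    min(which(cv_mean <= cv_mean[imin] + cv_se[imin]))
  } else imin
  path <- l0_path(gs$G, gs$b, gs$ztz, n, lambda, exact)
  beta_cand <- path$beta[, sel]
  beta0 <- gs$zbar - sum(gs$cm * beta_cand)
  beta <- numeric(p)
  beta[cand] <- beta_cand
  fit <- structure(list(
    beta = beta, beta0 = beta0, candidates = cand,
    lambda = lambda[sel], objective = path$objective[sel],
    cv = data.frame(lambda = lambda, cv_mse = cv_mean, cv_se = cv_se),
    cv_rule = cv_rule,
    method = if (exact) "exact" else "cd",
    n = n, seed = seed
  ), class = "insulation_fit")
  fit$classification <- classify_borders(fit, strong = strong,
                                         moderate = moderate)
  fit
}

empty_insulation_fit <- function(p, strong = -2.0, moderate = -1.2) {
  fit <- structure(list(
    beta = numeric(p), beta0 = 0, candidates = integer(0),
    lambda = NA_real_, objective = NA_real_,
    cv = data.frame(lambda = numeric(0), cv_mse = numeric(0),
                    cv_se = numeric(0)),
    method = "empty", n = 0L, seed = NA_integer_
  ), class = "insulation_fit")
  fit$classification <- classify_borders(fit, strong = strong,
                                         moderate = moderate)
  fit
}

#' @export
print.insulation_fit <- function(x, ...) {
  nb <- sum(x$beta < 0); nf <- sum(x$beta > 0)
  cat(sprintf(
    "insulation_fit: %d bins, %d borders (beta < 0), %d facilitators (beta > 0)\n",
    length(x$beta), nb, nf))
  if (!is.na(x$lambda))
    cat(sprintf("  lambda (CV-selected): %.4g; solver: %s\n",
                x$lambda, x$method))
  invisible(x)
}

#' @export
coef.insulation_fit <- function(object, ...) {
  setNames(object$beta, paste0("bin", seq_along(object$beta)))
}

#' Classify bins by insulation coefficient
#'
#' Border bins (`beta < 0`) are tiered by strength: strong (`beta <= strong`),
#' moderate (`strong < beta <= moderate`) or weak; positive coefficients are
#' facilitators; exact zeros have no effect.
#'
#' @param fit an `insulation_fit` (or a bare numeric beta vector).
#' @param strong,moderate tier thresholds, `strong < moderate < 0`
#'   (defaults -2.0 and -1.2).
#' @return a data.frame with columns `bin`, `beta`, `class`
#'   (`border`/`facilitator`/`null`) and `tier`
#'   (`strong`/`moderate`/`weak`, `NA` for non-borders).
#' @export
classify_borders <- function(fit, strong = -2.0, moderate = -1.2) {
  if (!(strong < moderate && moderate < 0))
    stop("need strong < moderate < 0")
  beta <- if (inherits(fit, "insulation_fit")) fit$beta else as.numeric(fit)
  cls <- ifelse(beta < 0, "border", ifelse(beta > 0, "facilitator", "null"))
  tier <- rep(NA_character_, length(beta))
  tier[beta < 0] <- ifelse(beta[beta < 0] <= strong, "strong",
                           ifelse(beta[beta < 0] <= moderate, "moderate",
                                  "weak"))
  data.frame(bin = seq_along(beta), beta = beta, class = cls, tier = tier,
             stringsAsFactors = FALSE)
}
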