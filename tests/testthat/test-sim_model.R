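test_that("distance trend recovers a generating power-law decay", {
  spec <- hic_spec(p = 200, depth = 150, alpha = 1.2,
                   effects = numeric(200), seed = 21)
  m <- simulate_hic(spec)$matrix
  pt <- build_pair_table(m, max_gap = 10)
  tr <- fit_distance_trend(pt)
  d_interior <- log((2:9) * spec$resolution)
  truth <- spec$beta0 - spec$alpha * d_interior
  fitted <- predict(tr, d_interior)
  expect_lt(max(abs(fitted - truth) / abs(truth)), 0.05)
  # fitted mean decreasing in distance over the observed range
  expect_true(all(diff(predict(tr, sort(unique(pt$d)))) < 0))
})

test_that("constant counts give a flat trend and degenerate input survives", {
  m <- toy_matrix(p = 30, seed = 22)
  m$counts[m$counts > 0] <- 40
  m <- contact_matrix(m$counts, resolution = 1000)
  pt <- build_pair_table(m, max_gap = 10)
  tr <- fit_distance_trend(pt)
  eta <- predict(tr, sort(unique(pt$d)))
  expect_lt(max(abs(eta - mean(eta))), 0.05)

  # all-zero counts refuse to fit (every bin is masked, no usable pairs)
  z0 <- contact_matrix(matrix(0, 25, 25), resolution = 1000)
  expect_error(build_pair_table(z0, max_gap = 10) |> fit_distance_trend())
  cm <- matrix(0, 25, 25); cm[1, 8] <- cm[8, 1] <- 9
  m1 <- contact_matrix(cm, resolution = 1000)
  m1$masked[] <- FALSE   # keep all bins so enough pairs exist
  pt1 <- build_pair_table(m1, max_gap = 10)
  tr1 <- suppressWarnings(fit_distance_trend(pt1))
  expect_true(all(is.finite(predict(tr1, pt1))))
})

test_that("residuals behave as log-scale deviations from the trend", {
  m <- toy_matrix(p = 60, seed = 23)
  pt <- build_pair_table(m, max_gap = 10)
  tr <- fit_distance_trend(pt)
  # y exactly exp(eta) - c gives exactly zero residuals
  pt0 <- pt
  pt0$y <- exp(predict(tr, pt)) - 1
  z0 <- compute_residuals(pt0, tr, pseudocount = 1, center = FALSE)
  expect_equal(max(abs(z0)), 0, tolerance = 1e-12)
  # doubling the counts shifts every (uncentered) residual by log 2
  z1 <- compute_residuals(pt, tr, pseudocount = 0, center = FALSE)
  pt2 <- pt; pt2$y <- 2 * pt$y
  z2 <- compute_residuals(pt2, tr, pseudocount = 0, center = FALSE)
  expect_equal(as.numeric(z2 - z1), rep(log(2), nrow(pt)), tolerance = 1e-12)
  # training-set residual mean is near zero
  z <- compute_residuals(pt, tr)
  expect_lt(abs(mean(z)), 0.05)
})

test_that("a planted border shifts mean spanning residuals by its effect", {
  eff <- numeric(120); eff[60] <- -1.5
  spec <- hic_spec(p = 120, depth = 300, effects = eff, seed = 24)
  m <- simulate_hic(spec)$matrix
  pt <- build_pair_table(m, max_gap = 10)
  tr <- fit_distance_trend(pt)
  z <- compute_residuals(pt, tr)
  span <- pt$i < 60 & pt$j > 60
  expect_lt(abs((mean(z[span]) - mean(z[!span])) - (-1.5)), 0.25)
})

test_that("lasso prefilter is the identity below the trigger and selective above", {
  eff <- numeric(150); eff[c(40, 100)] <- c(-2, -1.5)
  m <- simulate_hic(hic_spec(p = 150, depth = 150, effects = eff,
                             seed = 25))$matrix
  pt <- build_pair_table(m, max_gap = 10)
  tr <- fit_distance_trend(pt)
  z <- compute_residuals(pt, tr)
  X <- build_insulation_design(pt)
  # below the trigger: untouched
  cand0 <- prefilter_lasso(z, X, trigger = 5000)
  expect_equal(cand0, seq_len(150))
  # forced: planted borders survive
  cand <- prefilter_lasso(z, X, force = TRUE)
  expect_true(all(c(40, 100) %in% cand))
  expect_lt(length(cand), 150)
  # pure noise passes under 5% of bins
  m0 <- simulate_hic(hic_spec(p = 150, depth = 150,
                              effects = numeric(150), seed = 26))$matrix
  pt0 <- build_pair_table(m0, max_gap = 10)
  z0 <- compute_residuals(pt0, fit_distance_trend(pt0))
  cand_null <- suppressWarnings(
    prefilter_lasso(z0, build_insulation_design(pt0), force = TRUE))
  expect_lt(length(cand_null), 0.05 * 150)
})

test_that("best-subset limits: infinite penalty empties, zero penalty is OLS", {
  set.seed(31)
  n <- 300
  x <- rbinom(n, 1, 0.4)
  z <- -1.2 * x + rnorm(n, 0, 0.3)
  X <- Matrix::Matrix(matrix(x, ncol = 1,
                             dimnames = list(NULL, "bin2")), sparse = TRUE)
  f_inf <- fit_best_subset(z, X, p = 3, lambda = c(1e6, 1e5), cv_folds = 3)
  expect_equal(f_inf$beta, numeric(3))
  f0 <- fit_best_subset(z, X, p = 3, lambda = 0, cv_folds = 3)
  ols <- coef(lm(z ~ x))[["x"]]
  expect_equal(f0$beta[2], ols, tolerance = 1e-10)
  # empty candidate set: all-zero fit
  f_e <- fit_best_subset(z, X[, 0, drop = FALSE], p = 3)
  expect_equal(f_e$beta, numeric(3))
})

test_that("best-subset equals the exhaustive oracle on small problems", {
  set.seed(32)
  for (r in 1:6) {
    n <- sample(80:400, 1)
    k <- sample(4:10, 1)
    X <- matrix(rbinom(n * k, 1, 0.35), n, k)
    beta <- numeric(k)
    beta[sample(k, 2)] <- rnorm(2, 0, 1)
    z <- as.numeric(X %*% beta + rnorm(n, 0, 0.4))
    colnames(X) <- paste0("bin", seq_len(k))
    lam <- exp(runif(1, log(1e-4), log(0.3)))
    gs <- gram_of(z, X)
    for (use_exact in c(TRUE, FALSE)) {
      fit <- if (use_exact)
        insulatr:::l0_exact_path(gs$G, gs$b, gs$ztz, gs$n, lam)
      else insulatr:::.l0_cd_path(gs$G, gs$b, gs$ztz, gs$n, lam)
      orc <- oracle_best_subset(z, X, lam)
      expect_equal(fit$objective[1], orc$objective, tolerance = 1e-8)
    }
  }
})

test_that("cross-validation folds are deterministic given the seed", {
  m <- simulate_hic(hic_spec(p = 60, effects = numeric(60), seed = 33))$matrix
  pt <- build_pair_table(m, max_gap = 8)
  z <- compute_residuals(pt, fit_distance_trend(pt))
  X <- build_insulation_design(pt)
  f1 <- fit_best_subset(z, X, p = 60, seed = 99)
  f2 <- fit_best_subset(z, X, p = 60, seed = 99)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$cv, f2$cv)
})

test_that("border classification tiers follow the beta thresholds", {
  beta <- c(-2.5, -1.5, -0.5, 0, 0.8)
  cl <- classify_borders(beta)
  expect_equal(cl$class,
               c("border", "border", "border", "null", "facilitator"))
  expect_equal(cl$tier, c("strong", "moderate", "weak", NA, NA))
  expect_error(classify_borders(beta, strong = -1, moderate = -2), "strong")
})

test_that("the SIM pipeline recovers planted effects with the right signs", {
  spec <- hic_spec(seed = 41)
  m <- simulate_hic(spec)$matrix
  fit <- fit_sim(m)
  sel <- which(fit$beta != 0)
  planted <- which(spec$effects != 0)
  for (b in planted) {
    near <- sel[abs(sel - b) <= 1]
    expect_true(length(near) > 0, label = paste("bin", b, "recovered"))
    expect_equal(unique(sign(fit$beta[near])), sign(spec$effects[b]),
                 label = paste("sign at bin", b))
  }
  fp <- sel[vapply(sel, function(k) min(abs(k - planted)) > 1, TRUE)]
  expect_lte(length(fp), 1)
  expect_s3_class(fit, "sim_fit")
  expect_gte(nrow(fit$regions), 8)
  expect_true(all(fit$regions$class %in% c("border", "facilitator")))
})

test_that("reversing the chromosome reverses the beta profile", {
  eff <- numeric(80); eff[c(25, 55)] <- c(-2, 1.2)
  m <- simulate_hic(hic_spec(p = 80, depth = 200, effects = eff,
                             seed = 42))$matrix
  mr <- contact_matrix(m$counts[80:1, 80:1], resolution = m$resolution)
  f1 <- fit_sim(m)
  f2 <- fit_sim(mr)
  expect_equal(which(f2$beta != 0), 81 - rev(which(f1$beta != 0)))
})

test_that("masked bins are never selected", {
  eff <- numeric(100); eff[50] <- -2
  sim <- simulate_hic(hic_spec(p = 100, depth = 150, effects = eff, seed = 43))
  cm <- sim$matrix$counts
  cm[70, ] <- 0; cm[, 70] <- 0
  m <- contact_matrix(cm, resolution = 25000)
  fit <- fit_sim(m)
  expect_equal(fit$beta[70], 0)
  expect_true(70 %in% which(m$masked))
  expect_true(any(abs(which(fit$beta < 0) - 50) <= 1))
})
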