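make_fit <- function(beta, p = 100) {
  f <- insulatr:::empty_insulation_fit(p)
  f$beta[as.integer(names(beta))] <- beta
  f
}

test_that("union of SIM supports deduplicates consecutive bins", {
  f1 <- make_fit(c(`10` = -1, `40` = -2))
  f2 <- make_fit(c(`40` = -1.5, `80` = 0.7))
  expect_equal(select_union_bins(f1, f2), c(10, 40, 80))

  # consecutive bins collapse to the one with larger max |beta|
  g1 <- make_fit(c(`40` = -1.0, `41` = -0.5))
  g2 <- make_fit(c(`41` = -0.8))
  expect_equal(select_union_bins(g1, g2), 40)
  # tie: lower ordinal wins
  h1 <- make_fit(c(`40` = -1.0, `41` = -1.0))
  expect_equal(select_union_bins(h1, h1), 40)
  # identical fits: the support after dedup
  expect_equal(select_union_bins(f1, f1), c(10, 40))
  # empty union is an error
  e <- make_fit(numeric(0))
  expect_error(select_union_bins(e, e), "no candidate bins")
})

test_that("DIM on identical inputs returns exactly null interactions", {
  eff <- numeric(80); eff[c(25, 55)] <- c(-1.6, -0.9)
  m <- simulate_hic(hic_spec(p = 80, depth = 200, effects = eff,
                             seed = 51))$matrix
  d <- fit_dim(m, m)
  expect_lt(max(abs(d$table$beta_inter)), 1e-10)
  expect_lt(abs(d$beta_e), 1e-10)
})

test_that("swapping experiment labels negates every interaction estimate", {
  eff1 <- numeric(80); eff1[c(25, 55)] <- c(-1.6, -0.9)
  eff2 <- eff1; eff2[25] <- -2.4
  m1 <- simulate_hic(hic_spec(p = 80, depth = 200, effects = eff1,
                              seed = 52))$matrix
  m2 <- simulate_hic(hic_spec(p = 80, depth = 200, effects = eff2,
                              seed = 53))$matrix
  d12 <- fit_dim(m1, m2)
  d21 <- fit_dim(m2, m1)
  expect_equal(d12$table$bin, d21$table$bin)
  expect_equal(d12$table$beta_inter, -d21$table$beta_inter,
               tolerance = 1e-8)
})

test_that("a strengthened border is detected with the right sign and size", {
  eff1 <- numeric(100); eff1[c(25, 50, 75)] <- c(-1.5, -0.75, -2)
  eff2 <- eff1; eff2[50] <- -2.25   # differential effect -1.5
  m1 <- simulate_hic(hic_spec(p = 100, depth = 400, effects = eff1,
                              seed = 54))$matrix
  m2 <- simulate_hic(hic_spec(p = 100, depth = 400, effects = eff2,
                              seed = 55))$matrix
  d <- fit_dim(m1, m2)
  calls <- call_differential_borders(d)
  hit <- calls[abs(calls$bin - 50) <= 1, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$call, "gained_in_2")
  expect_gt(hit$beta_inter, -1.9)
  expect_lt(hit$beta_inter, -1.1)
  expect_lt(hit$p_adj, 0.05)
})

test_that("adjusted p-values dominate raw ones and calls follow alpha", {
  eff <- numeric(80); eff[c(25, 55)] <- c(-1.6, -0.9)
  m1 <- simulate_hic(hic_spec(p = 80, depth = 200, effects = eff,
                              seed = 56))$matrix
  m2 <- simulate_hic(hic_spec(p = 80, depth = 200, effects = eff,
                              seed = 57))$matrix
  d <- fit_dim(m1, m2)
  expect_true(all(d$table$p_adj >= d$table$p - 1e-15))
  expect_true(all(d$table$p_adj <= 1))
  strict <- call_differential_borders(d, alpha = 1e-30)
  expect_equal(nrow(strict), 0L)
})

test_that("the low-level OLS surface matches a direct lm fit", {
  set.seed(58)
  m1 <- simulate_hic(hic_spec(p = 60, depth = 200,
                              effects = {e <- numeric(60); e[30] <- -1.5; e},
                              seed = 59))$matrix
  s1 <- fit_sim(m1)
  d <- dim_ols(s1$residuals, s1$pairs, s1$residuals, s1$pairs,
               S = 30, se_type = "classical")
  # with identical halves the main effect equals the pooled OLS coefficient
  X <- insulatr:::gap_center_design(
    build_insulation_design(s1$pairs, candidate_bins = 30), s1$pairs$gap)
  ref <- coef(lm(as.numeric(s1$residuals) ~ as.matrix(X)))[2]
  expect_equal(unname(d$table$beta_main), unname(ref), tolerance = 1e-8)
})
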