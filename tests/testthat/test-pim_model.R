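test_that("Poisson fit recovers generating parameters", {
  e <- numeric(100); e[c(20, 35, 60, 80)] <- c(-1.8, -0.8, 1.0, -2.4)
  spec <- hic_spec(p = 100, depth = 100, effects = e, seed = 61)
  tabs <- lapply(1:8, function(r) {
    s <- spec; s$seed <- 61 + r
    build_pair_table(simulate_hic(s)$matrix, max_gap = 10)
  })
  pf <- fit_pim(do.call(bind_pair_tables, tabs))
  expect_lt(abs(pf$beta_d - (-1)), 0.05)
  ok <- which(pf$identifiable)
  expect_lt(max(abs(pf$beta_x[ok] - e[ok])), 0.15)
})

test_that("null effects and constant counts give null coefficients", {
  spec <- hic_spec(p = 80, depth = 200, effects = numeric(80), seed = 62)
  tabs <- lapply(0:3, function(r) {
    s <- spec; s$seed <- 62 + r
    build_pair_table(simulate_hic(s)$matrix, max_gap = 10)
  })
  pf <- fit_pim(do.call(bind_pair_tables, tabs))
  expect_lt(max(abs(pf$beta_x)), 0.1)

  cm <- matrix(25, 40, 40); diag(cm) <- 0
  mc <- contact_matrix(cm, resolution = 1000)
  pfc <- fit_pim(mc)
  expect_lt(abs(pfc$beta_d), 1e-6)
  expect_lt(max(abs(pfc$beta_x)), 1e-6)
  expect_equal(pfc$beta0, log(25), tolerance = 1e-6)
})

test_that("non-integer counts are rounded with a warning", {
  m <- toy_matrix(p = 30, seed = 63)
  m$counts <- m$counts * 1.37
  m2 <- contact_matrix(m$counts, resolution = 1000)
  expect_warning(fit_pim(m2), "rounded")
})

test_that("rearrangement variable transforms follow deletion geometry", {
  # deleting 3 bins strictly between a pair 8 apart shrinks its gap to 5
  rv <- apply_rearrangement(rearrangement("deletion", 10, 12),
                            p = 40, max_gap = 10, resolution = 1000)
  # original pair (6, 14): survivors map to new ordinals 6 and 11
  expect_equal(rv$old2new[6], 6L)
  expect_equal(rv$old2new[14], 11L)
  expect_equal(rv$old2new[11], NA_integer_)
  # a pair not spanning the deletion keeps its distance
  expect_equal(rv$old2new[20] - rv$old2new[16], 4L)
  # deleted bins have all-zero indicator columns
  expect_equal(sum(rv$X[, 10:12]), 0)
  expect_equal(rv$p_new, 37L)
})

test_that("inversions are involutions and rearrangements validate", {
  twice <- apply_rearrangement(
    rearrangement(c("inversion", "inversion"), c(12, 12), c(20, 20)),
    p = 50, max_gap = 10, resolution = 1000)
  none <- apply_rearrangement(rearrangement(), p = 50, max_gap = 10,
                              resolution = 1000)
  expect_identical(twice$pairs, none$pairs)
  expect_identical(as.matrix(twice$X), as.matrix(none$X))
  expect_identical(twice$perm, none$perm)

  expect_error(rearrangement("deletion", 5, 4), "first")
  expect_error(rearrangement("inversion", 5, 5), "two bins")
  expect_error(rearrangement("duplication", 1, 3), "kind")
  expect_error(apply_rearrangement(rearrangement("deletion", 48, 60),
                                   p = 50, max_gap = 10, resolution = 1000),
               "out of range")
})

test_that("self-prediction reproduces the training fitted means exactly", {
  m <- simulate_hic(hic_spec(p = 80, depth = 150,
                             effects = {e <- numeric(80); e[40] <- -2; e},
                             seed = 64))$matrix
  pf <- fit_pim(m)
  pred <- predict(pf)
  expect_equal(pred$mu_pairs$mu, pf$fitted, tolerance = 1e-12)
  expect_true(all(pred$mu_pairs$mu > 0))
  # assembled matrix is symmetric where defined
  expect_equal(pred$counts, t(pred$counts))
})

test_that("deleting a null-effect bin matches refitting without it", {
  e <- numeric(60); e[40] <- -1.8
  spec <- hic_spec(p = 60, depth = 300, effects = e, seed = 65)
  sim <- simulate_hic(spec)
  pf <- fit_pim(sim$matrix)
  # bin 15 carries no effect: prediction after deleting it ...
  pred_del <- predict(pf, rearrangement("deletion", 15, 15))
  # ... matches a model refit on the matrix with that row/column removed
  cm <- sim$matrix$counts[-15, -15]
  pf2 <- fit_pim(contact_matrix(cm, resolution = spec$resolution))
  pred2 <- predict(pf2)
  keep <- is.finite(pred_del$counts) & is.finite(pred2$counts)
  expect_equal(pred_del$counts[keep], pred2$counts[keep], tolerance = 0.15)
})

test_that("inverting an effect-free interval leaves predictions unchanged", {
  m <- simulate_hic(hic_spec(p = 60, depth = 200, effects = numeric(60),
                             seed = 66))$matrix
  pf <- fit_pim(m)
  base <- predict(pf)
  inv <- predict(pf, rearrangement("inversion", 20, 30))
  # an inversion never changes gaps, only which original bin sits where;
  # with no planted effects the coefficient profile is near-flat, so
  # predictions agree up to the fitted bin-level noise
  expect_equal(inv$counts, base$counts, tolerance = 0.2)
  # and with an exactly flat coefficient profile they agree exactly
  pf0 <- pf; pf0$beta_x[] <- 0
  expect_equal(predict(pf0, rearrangement("inversion", 20, 30))$counts,
               predict(pf0)$counts, tolerance = 1e-12)
})

test_that("prediction of a simulated mutant map is accurate", {
  e <- numeric(100); e[c(30, 55, 70)] <- c(-2, -1.2, 1.0)
  spec <- hic_spec(p = 100, depth = 100, effects = e, seed = 67)
  pf <- fit_pim(simulate_hic(spec)$matrix)
  rr <- rearrangement("deletion", 53, 57)  # delete the middle border
  pair <- simulate_hic_pair(spec, rr)
  ev <- evaluate_prediction(predict(pf, rr), pair$mutant$matrix)
  expect_gt(ev$pearson_log, 0.95)
  expect_gt(ev$scc, 0.8)
})

test_that("map-agreement metrics are exact on self-comparison", {
  m <- toy_matrix(p = 40, seed = 68)
  ev <- evaluate_prediction(m, m)
  expect_equal(ev$pearson_log, 1, tolerance = 1e-12)
  expect_equal(ev$spearman, 1, tolerance = 1e-12)
  expect_equal(ev$scc, 1, tolerance = 1e-12)
})

test_that("metrics handle degenerate strata and disagree on independent maps", {
  # constant per-stratum prediction: every stratum skipped, SCC undefined
  p <- 30
  decay <- outer(seq_len(p), seq_len(p),
                 function(i, j) 100 / pmax(abs(i - j), 1))
  diag(decay) <- 0
  mp <- contact_matrix(decay, resolution = 1000)
  mo <- toy_matrix(p = 30, seed = 69)
  ev <- evaluate_prediction(mp, mo)
  expect_false(ev$scc_defined)
  expect_true(is.na(ev$scc))

  # independent matrices: SCC near zero on average
  sccs <- vapply(1:8, function(s) {
    a <- simulate_hic(hic_spec(p = 60, effects = numeric(60),
                               seed = 200 + s))$matrix
    b <- simulate_hic(hic_spec(p = 60, effects = numeric(60),
                               seed = 300 + s))$matrix
    evaluate_prediction(a, b)$scc
  }, numeric(1))
  expect_lt(mean(abs(sccs)), 0.15)

  # mismatched bin tables are rejected
  expect_error(evaluate_prediction(toy_matrix(p = 20), toy_matrix(p = 25)),
               "different bin tables")
})
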