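#' Union of SIM-selected bins across two experiments
#'
#' Retains every bin with a nonzero insulation coefficient in either fit.
#' Because a physical border can be assigned to either of two adjacent bins
#' in different experiments, runs of consecutive bins are collapsed to one
#' representative: the bin with the larger maximum |beta| across the two
#' fits, ties to the lower ordinal.
#'
#' @param fit1,fit2 `insulation_fit`/`sim_fit` objects on the same bin table.
#' @return sorted integer vector of retained bin ordinals.
#' @export
select_union_bins <- function(fit1, fit2) {
  if (length(fit1$beta) != length(fit2$beta))
    stop("fits are on different bin tables")
  u <- sort(union(which(fit1$beta != 0), which(fit2$beta != 0)))
  if (!length(u))
    stop("no candidate bins; run SIM with a lower lambda")
  score <- pmax(abs(fit1$beta[u]), abs(fit2$beta[u]))
  run <- cumsum(c(TRUE, diff(u) > 1))
  sel <- vapply(split(seq_along(u), run), function(ix) {
    ix[which.max(score[ix])]  # which.max ties -> first, i.e. lower ordinal
  }, integer(1))
  u[sort(sel)]
}

#' Differential insulation model (DIM): border changes between two maps
#'
#' Tests, per retained bin, whether its insulation strength differs between
#' two Hi-C experiments. Each experiment gets its own distance trend (so
#' depth and decay differences cannot masquerade as differential
#' insulation), the residuals are stacked with an experiment indicator `e`,
#' and an ordinary least-squares fit of
#' `z ~ S + e + S:e` is performed over the union `S` of SIM-selected bins
#' (see [select_union_bins()]). No sparsity penalty is needed — the bins were
#' already selected — which keeps the interaction estimates unbiased. A
#' negative interaction coefficient means stronger insulation in the second
#' experiment; p-values are Benjamini-Hochberg adjusted across the retained
#' bins.
#'
#' @param m1,m2 [contact_matrix()] objects on the same bin table (experiment
#'   1 and 2).
#' @param sim1,sim2 optional pre-computed [fit_sim()] results for `m1`/`m2`;
#'   fitted here if missing.
#' @param max_gap,spline_df,seed,... passed to [fit_sim()] when needed.
#' @param se_type standard-error type, see [dim_ols()].
#' @param alpha adjusted-p cutoff stored for [call_differential_borders()].
#' @return an object of class `dim_fit` with a per-bin `table` (bin, start,
#'   end, beta_main, beta_inter, se, p, p_adj, call), the experiment main
#'   effect `beta_e`, intercept `beta0`, the retained set `S` and both SIM
#'   fits.
#' @export
fit_dim <- function(m1, m2, sim1 = NULL, sim2 = NULL, max_gap = 10,
                    spline_df = 8, seed = 1789, alpha = 0.05,
                    se_type = c("hc3", "classical"), ...) {
  stopifnot(inherits(m1, "contact_matrix"), inherits(m2, "contact_matrix"))
  if (nrow(m1$counts) != nrow(m2$counts))
    stop("the two matrices must share a bin table")
  if (is.null(sim1)) sim1 <- fit_sim(m1, max_gap = max_gap,
                                     spline_df = spline_df, seed = seed, ...)
  if (is.null(sim2)) sim2 <- fit_sim(m2, max_gap = max_gap,
                                     spline_df = spline_df, seed = seed, ...)
  S <- select_union_bins(sim1, sim2)
  dfit <- dim_ols(z1 = sim1$residuals, pairs1 = sim1$pairs,
                  z2 = sim2$residuals, pairs2 = sim2$pairs, S = S,
                  se_type = se_type)
  dfit$bins <- m1$bins
  dfit$table$start <- m1$bins$start[dfit$table$bin]
  dfit$table$end <- m1$bins$end[dfit$table$bin]
  dfit$sim1 <- sim1
  dfit$sim2 <- sim2
  dfit$alpha <- alpha
  dfit$table$call <- call_label(dfit$table, alpha)
  dfit$call <- match.call()
  dfit
}

#' Low-level DIM ordinary least squares
#'
#' Stacks the residuals of the two experiments and fits
#' `z ~ S + e + S:e` by OLS with classical standard errors. Exposed for
#' programmatic use; most users want [fit_dim()].
#'
#' Log-scale Hi-C residuals are heteroskedastic (their variance grows as
#' counts shrink, i.e. exactly at strongly insulated pairs), so classical
#' OLS standard errors are too small at the border bins being tested and
#' inflate the type-I error severalfold. Standard errors are therefore
#' heteroskedasticity-consistent (HC3 sandwich) by default; `"classical"`
#' is available for comparison.
#'
#' @param z1,z2 residual vectors from each experiment's own distance trend.
#' @param pairs1,pairs2 the matching `pair_table`s.
#' @param S retained bin ordinals.
#' @param se_type `"hc3"` (default) or `"classical"`.
#' @return a `dim_fit` (without genomic coordinates).
#' @export
dim_ols <- function(z1, pairs1, z2, pairs2, S,
                    se_type = c("hc3", "classical")) {
  se_type <- match.arg(se_type)
  X1 <- gap_center_design(build_insulation_design(pairs1, candidate_bins = S),
                          pairs1$gap, candidates = S)
  X2 <- gap_center_design(build_insulation_design(pairs2, candidate_bins = S),
                          pairs2$gap, candidates = S)
  z <- c(as.numeric(z1), as.numeric(z2))
  e <- rep(c(0, 1), c(length(z1), length(z2)))
  XS <- rbind(X1, X2)
  XSe <- XS * e
  colnames(XSe) <- paste0(colnames(XS), ":e")
  mm <- cbind(XS, e = e, XSe)
  fit <- lm(z ~ mm)
  cf <- if (se_type == "hc3") {
    unclass(lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC3")))
  } else {
    summary(fit)$coefficients
  }
  nm <- rownames(cf)
  q <- length(S)
  inter_names <- paste0("mmbin", S, ":e")
  main_names <- paste0("mmbin", S)
  dropped <- setdiff(inter_names, nm)
  if (length(dropped))
    warning("rank-deficient design; dropped interaction(s): ",
            paste(sub("^mm", "", dropped), collapse = ", "))
  pick <- function(names, col) {
    out <- rep(NA_real_, q)
    hit <- match(names, nm)
    out[!is.na(hit)] <- cf[hit[!is.na(hit)], col]
    out
  }
  tab <- data.frame(
    bin = S,
    beta_main = pick(main_names, 1L),
    beta_inter = pick(inter_names, 1L),
    se = pick(inter_names, 2L),
    p = pick(inter_names, 4L)
  )
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  structure(list(
    table = tab, S = S,
    beta0 = unname(cf["(Intercept)", 1L]),
    beta_e = if ("mme" %in% nm) unname(cf["mme", 1L]) else NA_real_,
    lm = fit
  ), class = "dim_fit")
}

call_label <- function(tab, alpha) {
  ifelse(!is.na(tab$p_adj) & tab$p_adj < alpha,
         ifelse(tab$beta_inter < 0, "gained_in_2", "lost_in_2"),
         "ns")
}

#' Call differential borders from a DIM fit
#'
#' Bins whose interaction term is significant after BH adjustment. A
#' negative interaction (stronger insulation in experiment 2) is a border
#' gained in 2; a positive one is a border lost in 2.
#'
#' @param dfit a `dim_fit`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return the significant rows of the DIM table with a `call` column.
#' @export
call_differential_borders <- function(dfit, alpha = 0.05) {
  stopifnot(inherits(dfit, "dim_fit"))
  tab <- dfit$table
  tab$call <- call_label(tab, alpha)
  tab[tab$call != "ns", , drop = FALSE]
}

#' @export
print.dim_fit <- function(x, ...) {
  alpha <- if (!is.null(x$alpha)) x$alpha else 0.05
  tab <- x$table
  sig <- sum(!is.na(tab$p_adj) & tab$p_adj < alpha)
  cat(sprintf("dim_fit: %d retained bins, %d differential at BH-adjusted p < %g\n",
              nrow(tab), sig, alpha))
  cat(sprintf("  experiment effect beta_e = %.3f\n", x$beta_e))
  invisible(x)
}

#' @export
coef.dim_fit <- function(object, ...) {
  setNames(object$table$beta_inter, paste0("bin", object$table$bin))
}

#' @export
summary.dim_fit <- function(object, ...) {
  print(object)
  print(object$table, row.names = FALSE)
  invisible(object)
}

#' Write DIM results as TSV
#'
#' @param dfit a `dim_fit` from [fit_dim()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_dim_fit <- function(dfit, path) {
  cols <- intersect(c("chrom", "start", "end", "bin", "beta_main",
                      "beta_inter", "se", "p", "p_adj", "call"),
                    names(dfit$table))
  write.table(dfit$table[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
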