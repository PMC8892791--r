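#' Specification of a synthetic Hi-C generative model
#'
#' The generator draws counts around a power-law distance decay with
#' log-additive per-bin effects: for bins `i < j`,
#' `log mu_ij = beta0 - alpha * log(dist_ij) + sum_{i<k<j} effect_k`,
#' where `dist_ij` is the bp separation. Negative effects are planted TAD
#' borders (they deplete every contact spanning the bin), positive effects
#' are facilitators. Counts are Poisson or negative-binomial around `mu`.
#'
#' The defaults emulate a deep 25 kb resolution map of a ~5 Mb region:
#' 200 bins, about 100 counts at one-bin separation, decay exponent 1,
#' eight borders of varying strength and two facilitators.
#'
#' @param p number of bins (>= 20).
#' @param resolution bin size in bp.
#' @param alpha power-law decay exponent (> 0).
#' @param depth expected count at one-bin separation; sets
#'   `beta0 = log(depth) + alpha * log(resolution)`.
#' @param effects length-`p` numeric vector of per-bin log-scale effects;
#'   defaults to [planted_effects()] of the standard fixture.
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`);
#'   ignored for Poisson.
#' @param seed RNG seed.
#' @return an object of class `hic_spec`.
#' @export
hic_spec <- function(p = 200, resolution = 25000, alpha = 1, depth = 100,
                     effects = planted_effects(p),
                     noise = c("poisson", "negative_binomial"),
                     dispersion = 0.1, seed = 1) {
  noise <- match.arg(noise)
  if (p < 20) stop("'p' must be >= 20")
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (length(effects) != p) stop("'effects' must have length p")
  if (!all(is.finite(effects))) stop("'effects' must be finite")
  structure(list(
    p = as.integer(p), resolution = resolution, alpha = alpha,
    beta0 = log(depth) + alpha * log(resolution), depth = depth,
    effects = effects, noise = noise, dispersion = dispersion,
    seed = as.integer(seed)
  ), class = "hic_spec")
}

#' Standard planted-effect map
#'
#' Eight borders with strengths spanning weak to strong and two
#' facilitators, spaced so that no two planted bins fall within one
#' `max_gap` window of ten bins of each other.
#'
#' @param p number of bins.
#' @param borders named numeric vector `bin = beta` of border effects
#'   (negative).
#' @param facilitators named numeric vector of facilitator effects
#'   (positive).
#' @return length-`p` effect vector.
#' @export
planted_effects <- function(p = 200,
                            borders = setNames(
                              seq(-2.5, -1.0, length.out = 8),
                              round(seq(0.1, 0.9, length.out = 8) * p)),
                            facilitators = setNames(
                              c(1.0, 1.5), round(c(0.275, 0.725) * p))) {
  eff <- numeric(p)
  eff[as.integer(names(borders))] <- borders
  eff[as.integer(names(facilitators))] <- facilitators
  eff
}

#' Simulate a Hi-C contact matrix from a generative spec
#'
#' @param spec a [hic_spec()].
#' @return a list of class `hic_sim`: `matrix` (a [contact_matrix()]),
#'   `mu` (the symmetric matrix of true means, zero diagonal) and `spec`.
#'   Reproducible: the same spec (same seed) yields the same matrix.
#' @export
simulate_hic <- function(spec) {
  stopifnot(inherits(spec, "hic_spec"))
  p <- spec$p
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  Cs <- cumsum(spec$effects)
  logmu <- spec$beta0 - spec$alpha * log((j - i) * spec$resolution) +
    Cs[j - 1L] - Cs[i]
  if (max(logmu) > log(1e12))
    stop("mean counts overflow; use a smaller depth/beta0 or weaker effects")
  mu <- exp(logmu)
  y <- withr::with_seed(spec$seed, switch(
    spec$noise,
    poisson = rpois(length(mu), mu),
    negative_binomial = rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion)
  ))
  counts <- matrix(0, p, p)
  counts[ut] <- y
  counts <- counts + t(counts)
  mum <- matrix(0, p, p)
  mum[ut] <- mu
  mum <- mum + t(mum)
  structure(list(
    matrix = contact_matrix(counts, resolution = spec$resolution),
    mu = mum, spec = spec
  ), class = "hic_sim")
}

#' Simulate a wild-type / rearranged-mutant pair from one truth
#'
#' The mutant is drawn from the same generative model evaluated on the
#' rearranged coordinates: deleted bins leave the effect map, inverted bins
#' carry their effects along.
#'
#' @param spec a [hic_spec()] describing the wild type.
#' @param rearr a [rearrangement()] valid on `spec$p` bins.
#' @param mutant_seed seed for the mutant draw (default `spec$seed + 1`).
#' @return list with `wt` and `mutant` (both `hic_sim`), `perm` (new-bin ->
#'   original-bin map) and `mutant_spec`.
#' @export
simulate_hic_pair <- function(spec, rearr, mutant_seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "hic_spec"))
  perm <- rearrangement_perm(rearr, spec$p)
  mspec <- hic_spec(
    p = length(perm), resolution = spec$resolution, alpha = spec$alpha,
    depth = spec$depth, effects = spec$effects[perm], noise = spec$noise,
    dispersion = spec$dispersion, seed = mutant_seed
  )
  list(wt = simulate_hic(spec), mutant = simulate_hic(mspec),
       perm = perm, mutant_spec = mspec)
}
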