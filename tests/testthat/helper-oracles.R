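# Independent oracles and small fixture builders used across the suite.

# Exhaustive best-subset oracle on the centered Gram scale, written
# independently of the package solver: enumerates every subset, solves the
# OLS normal equations, and returns the minimal penalized objective.
oracle_best_subset <- function(z, X, lambda) {
  X <- as.matrix(X)
  n <- length(z)
  k <- ncol(X)
  cm <- colMeans(X)
  G <- crossprod(X) - n * tcrossprod(cm)
  b <- as.numeric(crossprod(X, z)) - n * cm * mean(z)
  ztz <- sum((z - mean(z))^2)
  best_obj <- ztz / n
  best_S <- integer(0)
  for (sz in seq_len(k)) {
    for (S in utils::combn(k, sz, simplify = FALSE)) {
      bs <- tryCatch(solve(G[S, S, drop = FALSE], b[S]),
                     error = function(e) NULL)
      if (is.null(bs)) next
      obj <- (ztz - sum(b[S] * bs)) / n + lambda * sz
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best_S <- S
      }
    }
  }
  list(objective = best_obj, support = best_S)
}

# Brute-force spanning count: M_i = sum of counts over pairs (a, b) with
# a < i < b and b - a <= max_gap, by direct triple loop.
oracle_spanning_counts <- function(counts, max_gap) {
  p <- nrow(counts)
  M <- numeric(p)
  for (i in seq_len(p))
    for (a in seq_len(p))
      for (b in seq_len(p))
        if (a < i && i < b && b - a <= max_gap)
          M[i] <- M[i] + counts[a, b]
  M
}

# Small deterministic symmetric count matrix with decay.
toy_matrix <- function(p = 20, resolution = 1000, depth = 50, seed = 1) {
  spec <- hic_spec(p = max(p, 20), resolution = resolution, depth = depth,
                   effects = numeric(max(p, 20)), seed = seed)
  m <- simulate_hic(spec)$matrix
  if (p < 20) {
    cm <- m$counts[seq_len(p), seq_len(p)]
    m <- contact_matrix(cm, resolution = resolution)
  }
  m
}

# Solver front-end used by several tests: centered Gram pieces for a design.
gram_of <- function(z, X) {
  X <- as.matrix(X)
  n <- length(z)
  cm <- colMeans(X)
  list(G = crossprod(X) - n * tcrossprod(cm),
       b = as.numeric(crossprod(X, z)) - n * cm * mean(z),
       ztz = sum((z - mean(z))^2),
       n = n)
}
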