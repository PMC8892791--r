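#' Classical insulation score
#'
#' For each bin `i`, `M_i` is the total count over pairs `(a, b)` that
#' strictly span the bin (`a < i < b`) with separation at most `max_gap`;
#' the score is `IS_i = log2(M_i / mean(M))`, the mean taken over unmasked
#' bins with positive `M`. Low scores mark TAD borders, high scores mark
#' regions facilitating long-range contacts. Bins with `M_i = 0` (including
#' masked bins) get `NA`.
#'
#' @param m a [contact_matrix()].
#' @param max_gap maximal pair separation in bins (default 10, matching the
#'   sparse insulation model so profiles are comparable).
#' @return an object of class `is_profile`: data.frame with `bin`, `start`,
#'   `end`, `M`, `IS`; attribute `max_gap`.
#' @export
compute_insulation_score <- function(m, max_gap = 10) {
  stopifnot(inherits(m, "contact_matrix"))
  if (max_gap < 2) stop("'max_gap' must be >= 2")
  p <- nrow(m$counts)
  M <- numeric(p)
  for (g in 2:min(max_gap, p - 1L)) {
    a <- seq_len(p - g)
    cnt <- m$counts[cbind(a, a + g)]
    for (o in seq_len(g - 1L)) M[a + o] <- M[a + o] + cnt
  }
  usable <- !m$masked & M > 0
  IS <- rep(NA_real_, p)
  IS[usable] <- log2(M[usable] / mean(M[usable]))
  out <- data.frame(bin = seq_len(p), start = m$bins$start,
                    end = m$bins$end, M = M, IS = IS)
  attr(out, "max_gap") <- max_gap
  attr(out, "chrom") <- m$chrom
  class(out) <- c("is_profile", "data.frame")
  out
}

#' Write an insulation-score profile as bedGraph
#'
#' @param profile an `is_profile` from [compute_insulation_score()].
#' @param path output bedGraph file (bins with undefined score are omitted).
#' @return `path`, invisibly.
#' @export
write_insulation_score <- function(profile, path) {
  keep <- is.finite(profile$IS)
  df <- data.frame(chrom = attr(profile, "chrom"),
                   start = profile$start[keep], end = profile$end[keep],
                   score = profile$IS[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
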