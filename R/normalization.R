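# Step 3: rank-preserving Gaussianisation of the z triangle and quantile
# thresholding.

#' Rank-preserving Gaussian normalisation of z values
#'
#' Maps the stored voxel-pair values onto exact standard-normal scores: the
#' element of ascending rank `r` (ties get average ranks) among all `N` pairs
#' becomes `qnorm((r - 0.5) / N)`. The map is deterministic, exactly
#' rank-preserving, idempotent up to tie structure, and independent of input
#' order. It wipes out any marginal distortion of the raw theta differences
#' (global confounds, heavy tails) while keeping the spatial arrangement of
#' high-ranking pairs, which is what the local edge density exploits.
#'
#' @param z A `diff_sync` with at least two distinct finite values.
#' @return A `diff_sync` with `normalised = TRUE`.
#' @export
gaussianize <- function(z) {
  stopifnot(inherits(z, "diff_sync"))
  v <- z$z
  N <- length(v)
  if (N < 2L || max(v) == min(v)) {
    stop("gaussianize: need at least 2 distinct values")
  }
  r <- data.table::frank(v, ties.method = "average")
  # ranks are integers or (tie-averaged) half-integers: look the normal
  # scores up in a cached table instead of re-evaluating qnorm each call
  new_diff_sync(z$space, norm_scores(N)[round(2 * r)], normalised = TRUE)
}

#' Threshold retaining the top fraction of normalised z values
#'
#' Because [gaussianize()] forces an exact standard-normal marginal, the
#' upper-tail quantile of the normalised triangle is the normal quantile:
#' the threshold keeping the top fraction `q` of edges is `qnorm(1 - q)`,
#' reported rounded to two decimals (top 1 percent gives `z_t = 2.33`).
#'
#' @param z A normalised `diff_sync` (only its flag is consulted; the
#'   threshold is a property of the normalisation, not of the data).
#' @param top_fraction Fraction of edges to retain, in (0, 1). Default 0.01.
#' @return The threshold `z_t`, a single number.
#' @export
quantile_threshold <- function(z, top_fraction = 0.01) {
  stopifnot(inherits(z, "diff_sync"))
  if (!z$normalised) stop("quantile_threshold: z must be normalised first")
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction >= 1) {
    stop("quantile_threshold: top_fraction must be in (0, 1)")
  }
  round(qnorm(1 - top_fraction), 2)
}
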