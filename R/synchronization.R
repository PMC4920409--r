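# Step 2: per-condition effect-size time courses, synchronisation matrices
# Theta_A / Theta_B, the differential-synchronisation triangle z, and the
# across-run conjunction.

#' Effect-size time courses across trials
#'
#' For each voxel `i` and within-trial time point `t`, computes the across-trial
#' mean `mu_i(t)`, the across-trial sample standard deviation `sigma_i(t)`
#' (divisor `K - 1`), and the effect size `s_i(t) = mu_i(t) / sigma_i(t)`.
#' Cells with `sigma = 0` (zero inter-trial variance) get `s = 0` and are
#' flagged degenerate, so such voxels contribute no synchronisation.
#'
#' The effect-size series is what makes the synchronisation statistic penalise
#' inter-trial inconsistency: responses that flip or jitter across trials
#' inflate `sigma` and shrink `s`, even when single-trial correlations are
#' strong.
#'
#' @param trials A `trial_array` (needs `K >= 2`).
#' @return An object of class `effect_series` with matrices `mu`, `sigma`, `s`
#'   (voxel x time) and a logical `degenerate` matrix.
#' @export
effect_series <- function(trials) {
  stopifnot(inherits(trials, "trial_array"))
  v <- trials$values
  d <- dim(v)
  n <- d[1]; K <- d[2]; T <- d[3]
  if (K < 2L) stop("effect_series: need at least K = 2 trials")
  mu <- matrix(0, n, T)
  sigma <- matrix(0, n, T)
  for (t in seq_len(T)) {
    m <- array(v[, , t], c(n, K))
    mu_t <- rowMeans(m)
    mu[, t] <- mu_t
    sigma[, t] <- sqrt(rowSums((m - mu_t)^2) / (K - 1))
  }
  degenerate <- sigma == 0
  s <- mu / sigma
  s[degenerate] <- 0
  structure(list(space = trials$space, condition = trials$condition,
                 mu = mu, sigma = sigma, s = s, degenerate = degenerate,
                 K = K, T = T),
            class = "effect_series")
}

new_sync_matrix <- function(space, condition, theta) {
  structure(list(space = space, condition = condition, theta = theta),
            class = "sync_matrix")
}

# Fisher z-transform of positive correlations; r clamped below 1 - eps.
fisher_theta <- function(r, eps = 1e-7) {
  th <- numeric(length(r))
  pos <- which(r > 0)            # NA (undefined correlation) maps to theta = 0
  rp <- pmin(r[pos], 1 - eps)
  th[pos] <- atanh(rp)           # = 0.5 log((1+r)/(1-r))
  th
}

#' Pairwise synchronisation matrix
#'
#' For every voxel pair `i < j`, the synchronisation `theta_{i,j}` is the
#' Fisher z-transform of the Pearson correlation `r` between the effect-size
#' series `s_i(.)` and `s_j(.)` over within-trial time, for positive `r`;
#' non-positive (and undefined) correlations give `theta = 0`. `r` is clamped
#' to at most `1 - 1e-7` before the transform. Computed in column blocks so
#' peak memory is O(n * block) beyond the output triangle.
#'
#' @param effects An `effect_series` (needs `T >= 3`).
#' @param block Number of voxels per correlation block.
#' @return A `sync_matrix` whose `theta` field is the upper triangle stored as
#'   a vector in `upper.tri` (column-major) order.
#' @export
sync_matrix <- function(effects, block = 2048L) {
  stopifnot(inherits(effects, "effect_series"))
  s <- effects$s
  n <- nrow(s)
  T <- ncol(s)
  if (T < 3L) stop("sync_matrix: need at least T = 3 time points")
  x <- t(s)                                  # T x n
  theta <- numeric(n_pairs(n))
  if (n <= block) {
    # Pearson correlation via a scaled symmetric crossproduct (one BLAS
    # dsyrk); constant columns yield NaN, which fisher_theta maps to 0.
    cx <- x - rep(colMeans(x), each = T)
    cx <- cx / rep(sqrt(colSums(cx * cx)), each = T)
    r <- crossprod(cx)
    theta <- fisher_theta(r[ut_indices(n)])
  } else {
    for (j0 in seq(2L, n, by = block)) {
      cols <- j0:min(j0 + block - 1L, n)
      r <- suppressWarnings(cor(x, x[, cols, drop = FALSE]))
      for (j in cols) {
        off <- (j - 1) * (j - 2) / 2
        theta[off + seq_len(j - 1L)] <- fisher_theta(r[seq_len(j - 1L), j - j0 + 1L])
      }
    }
  }
  new_sync_matrix(effects$space, effects$condition, theta)
}

new_diff_sync <- function(space, z, normalised = FALSE) {
  structure(list(space = space, z = z, normalised = normalised),
            class = "diff_sync")
}

#' Construct a differential-synchronisation triangle from raw values
#'
#' Low-level constructor, mainly for tests and worked examples: wraps a vector
#' of voxel-pair values (in `upper.tri` column-major order over ids `i < j`)
#' as a `diff_sync` object.
#'
#' @param z Numeric vector of length `n(n-1)/2`.
#' @param space The `voxel_space` the pairs refer to.
#' @param normalised Whether the values are already rank-Gaussianised.
#' @return A `diff_sync` object.
#' @export
as_diff_sync_matrix <- function(z, space, normalised = FALSE) {
  stopifnot(inherits(space, "voxel_space"))
  if (length(z) != n_pairs(space$n)) {
    stop(sprintf("as_diff_sync_matrix: expected %d pair values, got %d",
                 n_pairs(space$n), length(z)))
  }
  if (!all(is.finite(z))) stop("as_diff_sync_matrix: non-finite values")
  new_diff_sync(space, as.numeric(z), isTRUE(normalised))
}

#' @export
print.diff_sync <- function(x, ...) {
  cat(sprintf("<diff_sync> %d voxel pairs (%d voxels), %s\n",
              length(x$z), x$space$n,
              if (x$normalised) "rank-Gaussianised" else "raw theta differences"))
  invisible(x)
}

#' Differential synchronisation between two conditions
#'
#' Element-wise subtraction `z = theta_A - theta_B`; large positive values mean
#' stronger task-locked coupling in condition A.
#'
#' @param theta_a,theta_b `sync_matrix` objects on the same `voxel_space`.
#' @return A `diff_sync` with `normalised = FALSE`.
#' @export
diff_sync <- function(theta_a, theta_b) {
  stopifnot(inherits(theta_a, "sync_matrix"), inherits(theta_b, "sync_matrix"))
  if (!same_space(theta_a$space, theta_b$space)) {
    stop("diff_sync: voxel spaces differ")
  }
  new_diff_sync(theta_a$space, theta_a$theta - theta_b$theta, normalised = FALSE)
}

#' Conjunction of two runs' normalised z triangles
#'
#' Element-wise minimum of two rank-Gaussianised differential-synchronisation
#' triangles, combining independent runs of the same task: an edge survives
#' only if it scores high in both runs.
#'
#' @param z1,z2 Normalised `diff_sync` objects on the same `voxel_space`.
#' @return A `diff_sync` (flagged normalised; note the marginal distribution
#'   of a minimum is no longer standard normal).
#' @export
conjunction <- function(z1, z2) {
  stopifnot(inherits(z1, "diff_sync"), inherits(z2, "diff_sync"))
  if (!same_space(z1$space, z2$space)) stop("conjunction: voxel spaces differ")
  if (!z1$normalised || !z2$normalised) {
    stop("conjunction: both inputs must be normalised (see gaussianize())")
  }
  new_diff_sync(z1$space, pmin(z1$z, z2$z), normalised = TRUE)
}
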