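# Step 5: permutation null via task-label swaps, empirical cdfs of D_e, the
# two-component empirical Fdr, and the significance cutoff.

#' Draw a binary task-label permutation vector
#'
#' `K` independent Bernoulli(0.5) indicators; entry `k = 1` means the labels of
#' trial `k` are swapped between conditions. Reproducible given the seed. The
#' identity vector (all zeros) is a valid draw.
#'
#' @param K Number of trials per condition (>= 2).
#' @param seed Integer seed.
#' @return A `perm_vector`: list with integer `rho` (0/1, length `K`) and `seed`.
#' @export
draw_permutation <- function(K, seed) {
  if (K < 2L) stop("draw_permutation: need K >= 2")
  rho <- local_seed(seed, rbinom(K, 1L, 0.5))
  structure(list(rho = as.integer(rho), seed = as.integer(seed)),
            class = "perm_vector")
}

#' Effect series under a task-label permutation
#'
#' Rebuilds the per-condition effect-size series after swapping trial labels
#' according to `rho`: the permuted condition A uses trial `k` from A when
#' `rho[k] = 0` and from B when `rho[k] = 1`, and conversely for B. The same
#' `rho` is applied to every voxel, so the spatial correlation structure of the
#' data is preserved under the null. Moments use the same `K - 1` divisor as
#' [effect_series()].
#'
#' @param trials_a,trials_b `trial_array` objects with identical shape/space.
#' @param rho A `perm_vector` (or 0/1 vector) of length `K`.
#' @return List with permuted `effect_series` elements `A` and `B`.
#' @export
permuted_effect_series <- function(trials_a, trials_b, rho) {
  stopifnot(inherits(trials_a, "trial_array"), inherits(trials_b, "trial_array"))
  if (inherits(rho, "perm_vector")) rho <- rho$rho
  if (!same_space(trials_a$space, trials_b$space) ||
      !identical(dim(trials_a$values), dim(trials_b$values))) {
    stop("permuted_effect_series: trial arrays have mismatched shapes")
  }
  K <- trials_a$K
  if (length(rho) != K || !all(rho %in% c(0L, 1L))) {
    stop("permuted_effect_series: rho must be a 0/1 vector of length K")
  }
  sw <- rho == 1L
  va <- trials_a$values
  vb <- trials_b$values
  if (any(sw)) {
    tmp <- va[, sw, , drop = FALSE]
    va[, sw, ] <- vb[, sw, , drop = FALSE]
    vb[, sw, ] <- tmp
  }
  list(A = effect_series(new_trial_array(trials_a$space, trials_a$condition, va)),
       B = effect_series(new_trial_array(trials_b$space, trials_b$condition, vb)))
}

# Normalise the runs argument: either list(A=..., B=...) for one run, or a
# list of such per-run pairs.
as_run_list <- function(runs) {
  if (!is.null(runs$A) && !is.null(runs$B)) runs <- list(runs)
  if (!length(runs)) stop("no runs supplied")
  for (r in runs) {
    if (!inherits(r$A, "trial_array") || !inherits(r$B, "trial_array")) {
      stop("each run must be a list with trial_array elements A and B")
    }
  }
  runs
}

# Shared core of the observed and permuted pipelines: per-run effect-series
# pairs -> z -> gaussianize -> (conjunction) -> threshold -> candidate edges
# -> local edge densities.
ted_densities_from_effects <- function(effs, top_fraction, min_distance_mm,
                                       adjacency, geom) {
  zn_runs <- lapply(effs, function(e) {
    gaussianize(diff_sync(sync_matrix(e$A), sync_matrix(e$B)))
  })
  zn <- Reduce(conjunction, zn_runs)
  z_t <- quantile_threshold(zn, top_fraction)
  edges <- candidate_edges(zn, z_t, min_distance_mm)
  dmap <- density_map(edges, zn, adjacency, geom = geom)
  list(zn = zn, z_t = z_t, edges = edges, dmap = dmap)
}

# Observed (unpermuted) pipeline for one or two runs of trial arrays.
ted_observed <- function(runs, top_fraction = 0.01, min_distance_mm = 15,
                         adjacency = 26L, geom = NULL) {
  runs <- as_run_list(runs)
  space <- runs[[1]]$A$space
  if (is.null(geom)) geom <- lattice_geometry(space, adjacency)
  effs <- lapply(runs, function(r) list(A = effect_series(r$A), B = effect_series(r$B)))
  ted_densities_from_effects(effs, top_fraction, min_distance_mm, adjacency, geom)
}

#' Pooled null local edge densities from task-label permutations
#'
#' For each of `P` replicates, draws one permutation vector per run, rebuilds
#' the full statistic pipeline (effect series, synchronisation, differential
#' z, Gaussianisation, conjunction across runs, thresholding, candidate edges,
#' local edge densities) and pools the resulting `D_e` values. Because the
#' rank normalisation is reapplied inside every replicate, null and observed
#' triangles have identical marginal distributions and differences in `D_e`
#' reflect spatial arrangement only.
#'
#' @param runs One run (`list(A=, B=)` of `trial_array`s) or a list of runs.
#' @param P Number of permutation replicates (>= 1).
#' @param seed Integer seed; per-replicate, per-run seeds are derived from it
#'   and recorded.
#' @param top_fraction,min_distance_mm,adjacency Pipeline parameters, as in
#'   [quantile_threshold()] and [candidate_edges()].
#' @param geom Optional precomputed `lattice_geometry()`.
#' @return A `null_ensemble`: list with pooled `samples`,
#'   `per_replicate_counts`, `P`, `seed` and the `seeds` matrix (P x runs).
#' @export
null_density_samples <- function(runs, P, seed, top_fraction = 0.01,
                                 min_distance_mm = 15, adjacency = 26L,
                                 geom = NULL) {
  if (P < 1L) stop("null_density_samples: need P >= 1")
  runs <- as_run_list(runs)
  space <- runs[[1]]$A$space
  if (is.null(geom)) geom <- lattice_geometry(space, adjacency)
  R <- length(runs)
  seeds <- local_seed(seed, matrix(sample.int(2147483646L, P * R), nrow = P))
  samples <- vector("list", P)
  counts <- integer(P)
  for (p in seq_len(P)) {
    effs <- lapply(seq_len(R), function(r) {
      rho <- draw_permutation(runs[[r]]$A$K, seeds[p, r])
      permuted_effect_series(runs[[r]]$A, runs[[r]]$B, rho)
    })
    res <- ted_densities_from_effects(effs, top_fraction, min_distance_mm,
                                      adjacency, geom)
    samples[[p]] <- res$dmap$de
    counts[p] <- nrow(res$dmap)
  }
  structure(list(samples = unlist(samples), per_replicate_counts = counts,
                 P = as.integer(P), seed = as.integer(seed), seeds = seeds,
                 top_fraction = top_fraction, min_distance_mm = min_distance_mm,
                 adjacency = as.integer(adjacency)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d permutation replicates, %d pooled D_e values (mean %d/replicate)\n",
              x$P, length(x$samples), as.integer(round(mean(x$per_replicate_counts)))))
  invisible(x)
}

#' Default D_e histogram grid
#'
#' Right edges of 1,000 equal-width bins on [0, 1]; bin width 0.001 resolves
#' all attainable densities (denominators are at most 729).
#' @return Ascending numeric vector of length 1000.
#' @export
de_grid <- function() seq_len(1000L) / 1000

#' Empirical cdf from cumulative histogram counts
#'
#' Right-continuous empirical cdf on the shared grid: `F(g) = #\{x <= g\} / n`,
#' i.e. cumulative summation of histogram counts with bin edges at `grid`.
#'
#' @param samples Non-empty numeric vector.
#' @param grid Ascending bin edges (default [de_grid()]).
#' @return Numeric vector of cdf values, one per grid edge.
#' @export
estimate_cdf <- function(samples, grid = de_grid()) {
  if (!length(samples)) stop("estimate_cdf: samples are empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("estimate_cdf: grid must be ascending")
  ecdf(samples)(grid)
}

#' Empirical Fdr curve from null and observed cdfs
#'
#' Two-component empirical false discovery rate over the `D_e` grid:
#' `Fdr(c) = pi0 (1 - F0(c)) / (1 - Fz(c))`, the probability that an edge with
#' `D_e` as large or larger than `c` is a null edge. Values are clamped to
#' [0, 1]; where the observed tail `1 - Fz` is zero the last finite value is
#' carried forward. `pi0 = 1` is the conservative default.
#'
#' @param F0 Null cdf on `grid` (from permutations, see
#'   [null_density_samples()]).
#' @param Fz Observed cdf on `grid`.
#' @param grid Shared grid of `D_e` bin edges.
#' @param pi0 Prior null probability in (0, 1].
#' @return An `fdr_curve`: list with `grid`, `F0`, `Fz`, `fdr`, `pi0`.
#' @export
fdr_curve <- function(F0, Fz, grid = de_grid(), pi0 = 1) {
  if (length(F0) != length(grid) || length(Fz) != length(grid)) {
    stop("fdr_curve: F0, Fz and grid must have equal length")
  }
  if (pi0 <= 0 || pi0 > 1) stop("fdr_curve: pi0 must be in (0, 1]")
  den <- 1 - Fz
  fdr <- pi0 * (1 - F0) / den
  fdr[den <= 0] <- NA_real_
  # carry the last finite value forward into the exhausted tail
  if (anyNA(fdr)) {
    last <- 1
    for (g in seq_along(fdr)) {
      if (is.na(fdr[g])) fdr[g] <- last else last <- fdr[g]
    }
  }
  fdr <- pmin(pmax(fdr, 0), 1)
  structure(list(grid = grid, F0 = F0, Fz = Fz, fdr = fdr, pi0 = pi0),
            class = "fdr_curve")
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat(sprintf("<fdr_curve> %d grid points, pi0 = %g, min Fdr = %.4g\n",
              length(x$grid), x$pi0, min(x$fdr)))
  invisible(x)
}

#' Significance cutoff from an Fdr curve
#'
#' The smallest grid value `c` with `Fdr(c) < alpha`; edges with `D_e > c` are
#' declared significant. Returns `NA` if no grid point qualifies. A
#' non-monotone curve past the cutoff is reported via `message()` but the scan
#' semantics (first qualifying point) are kept.
#'
#' @param curve An [fdr_curve()].
#' @param alpha Fdr level in (0, 1).
#' @return The cutoff `D_e` value, or `NA_real_`.
#' @export
significance_cutoff <- function(curve, alpha = 0.05) {
  stopifnot(inherits(curve, "fdr_curve"))
  if (alpha <= 0 || alpha >= 1) stop("significance_cutoff: alpha must be in (0, 1)")
  hit <- which(curve$fdr < alpha)
  if (!length(hit)) return(NA_real_)
  first <- hit[1]
  if (any(curve$fdr[first:length(curve$fdr)] >= alpha)) {
    message("significance_cutoff: Fdr curve is non-monotone past the cutoff")
  }
  curve$grid[first]
}
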