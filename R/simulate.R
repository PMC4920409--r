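# Synthetic two-condition block-design data with known ground truth: planted
# synchronised voxel clusters, controllable inter-trial consistency, and
# Gaussian noise. Exchangeable null data are obtained with amplitude = 0.

# Canonical double-gamma haemodynamic response, sampled at `dt` seconds.
double_gamma_hrf <- function(t) {
  t^5 * exp(-t) / gamma(6) - (1 / 6) * t^15 * exp(-t) / gamma(16)
}

# Default response waveform: boxcar covering the trial convolved with the
# double-gamma shape, truncated to T volumes and scaled to peak 1. The
# pipeline itself is model-free; this is purely a data-generating choice.
default_waveform <- function(T, tr_seconds) {
  dt <- tr_seconds
  tmax <- T * dt + 32
  tt <- seq(0, tmax, by = dt)
  h <- double_gamma_hrf(tt)
  box <- as.numeric(tt < T * dt)
  w <- stats::convolve(box, rev(h), type = "open")[seq_len(T)]
  w / max(abs(w))
}

default_clusters <- function(amplitude, consistency) {
  list(
    list(origin = c(1L, 4L, 4L), size = c(3L, 3L, 3L), condition = "A",
         amplitude = amplitude, consistency = consistency),
    list(origin = c(8L, 4L, 4L), size = c(3L, 3L, 3L), condition = "A",
         amplitude = amplitude, consistency = consistency)
  )
}

#' Specification of a synthetic two-condition dataset
#'
#' Describes a block-design experiment on a full-mask lattice with planted
#' synchronised clusters. Each cluster is a voxel block that responds with a
#' common waveform in its condition's trials; the per-trial response sign
#' `g_k` is +1 with probability `(1 + c)/2` and -1 otherwise, so consistency
#' `c = 1` gives fully trial-locked responses while `c = 0` gives sign-flipping
#' responses with unchanged per-trial correlation magnitude (the inter-trial
#' consistency scenario the synchronisation statistic is built to detect).
#' Sign flips are shared by all clusters of the same condition, keeping
#' cross-cluster per-trial correlations matched across consistency levels.
#'
#' @param dims Lattice dimensions (default `c(10, 10, 10)`).
#' @param voxel_size_mm Voxel size (default 3 mm isotropic, the scale at which
#'   the 15 mm short-edge rule guarantees three voxels of separation).
#' @param K Trials per condition (default 20).
#' @param T Volumes per trial (default 16).
#' @param tr_seconds TR (default 0.72 s).
#' @param amplitude Response amplitude `a`; with `noise_sd = 1` this is the
#'   per-sample effect size `a/sd`. `amplitude = 0` gives exchangeable null
#'   data. Default 2.
#' @param consistency Inter-trial consistency `c` in [0, 1]; default 1.
#' @param noise_sd Gaussian noise standard deviation; default 1.
#' @param clusters Optional list of cluster definitions (`origin` 1-based
#'   lattice corner, `size`, `condition`, `amplitude`, `consistency`, optional
#'   `waveform`). Default: two 3x3x3 condition-A blocks 15 mm apart.
#' @param seed Integer seed for all randomness.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(dims = c(10L, 10L, 10L), voxel_size_mm = c(3, 3, 3),
                            K = 20L, T = 16L, tr_seconds = 0.72,
                            amplitude = 2, consistency = 1, noise_sd = 1,
                            clusters = NULL, seed = 1L) {
  if (K < 2L || T < 3L) stop("simulation_spec: need K >= 2 and T >= 3")
  if (noise_sd <= 0) stop("simulation_spec: noise_sd must be positive")
  # amplitude 0 means an exchangeable null dataset: nothing is planted
  clusters <- clusters %||%
    (if (amplitude == 0) list() else default_clusters(amplitude, consistency))
  for (cl in clusters) {
    if (!all(cl$origin >= 1L) || !all(cl$origin + cl$size - 1L <= dims)) {
      stop("simulation_spec: cluster outside the lattice")
    }
    if (!cl$condition %in% c("A", "B")) {
      stop("simulation_spec: cluster condition must be 'A' or 'B'")
    }
    cc <- cl$consistency %||% consistency
    if (cc < 0 || cc > 1) stop("simulation_spec: consistency must be in [0, 1]")
  }
  structure(list(dims = as.integer(dims), voxel_size_mm = voxel_size_mm,
                 K = as.integer(K), T = as.integer(T), tr_seconds = tr_seconds,
                 amplitude = amplitude, consistency = consistency,
                 noise_sd = noise_sd, clusters = clusters,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

cluster_voxel_ids <- function(cl, space) {
  rng <- lapply(1:3, function(d) (cl$origin[d] - 1L):(cl$origin[d] + cl$size[d] - 2L))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  ids <- space$id_of[cbind(g[, 1] + 1L, g[, 2] + 1L, g[, 3] + 1L)]
  sort(ids)
}

#' Generate synthetic trial arrays with ground truth
#'
#' Draws Gaussian noise for both conditions and adds `g_k * a * w(t)` to every
#' planted cluster voxel in the cluster's condition, where `w` is the response
#' waveform and `g_k` the per-trial sign (see [simulation_spec()]). The ground
#' truth lists every cross-cluster voxel pair (between distinct clusters of
#' the same condition) as a task-positive edge.
#'
#' @param spec A [simulation_spec()].
#' @return List with `trials_a`, `trials_b` (`trial_array`s), `truth` (data
#'   frame of ground-truth edges `i < j` with distances), `space`, and `spec`.
#' @export
simulate_trials <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  space <- voxel_space(array(TRUE, spec$dims), spec$voxel_size_mm)
  n <- space$n
  K <- spec$K
  T <- spec$T
  out <- local_seed(spec$seed, {
    va <- array(rnorm(n * K * T, 0, spec$noise_sd), c(n, K, T))
    vb <- array(rnorm(n * K * T, 0, spec$noise_sd), c(n, K, T))
    u <- list(A = runif(K), B = runif(K))   # shared flip draws per condition
    for (cl in spec$clusters) {
      a <- cl$amplitude %||% spec$amplitude
      if (a == 0) next
      cc <- cl$consistency %||% spec$consistency
      w <- cl$waveform %||% default_waveform(T, spec$tr_seconds)
      if (length(w) != T) stop("simulate_trials: waveform length must be T")
      g <- ifelse(u[[cl$condition]] < (1 + cc) / 2, 1, -1)
      ids <- cluster_voxel_ids(cl, space)
      sig <- aperm(array(outer(g, a * w), c(K, T, length(ids))), c(3, 1, 2))
      if (cl$condition == "A") {
        va[ids, , ] <- va[ids, , ] + sig
      } else {
        vb[ids, , ] <- vb[ids, , ] + sig
      }
    }
    list(va = va, vb = vb)
  })
  truth <- data.frame(i = integer(0), j = integer(0))
  cls <- spec$clusters
  if (length(cls) >= 2L) {
    for (aidx in seq_along(cls)) {
      for (bidx in seq_along(cls)) {
        if (bidx <= aidx || cls[[aidx]]$condition != cls[[bidx]]$condition) next
        ids1 <- cluster_voxel_ids(cls[[aidx]], space)
        ids2 <- cluster_voxel_ids(cls[[bidx]], space)
        gg <- expand.grid(p = ids1, q = ids2)
        truth <- rbind(truth, data.frame(i = pmin(gg$p, gg$q),
                                         j = pmax(gg$p, gg$q),
                                         condition = cls[[aidx]]$condition))
      }
    }
    truth$distance_mm <- voxel_distance_mm(space, truth$i, truth$j)
  }
  list(trials_a = new_trial_array(space, "A", out$va),
       trials_b = new_trial_array(space, "B", out$vb),
       truth = truth, space = space, spec = spec)
}

#' Write a synthetic dataset as NIfTI/TSV/JSON fixtures
#'
#' Materialises a simulated experiment as files so the full file-based pipeline
#' can be exercised end to end: a 4D BOLD run (trials concatenated
#' back-to-back, conditions interleaved A, B, A, B, ...), a mask volume, a
#' trial-onset TSV, and a ground-truth JSON recording the spec, seed and
#' planted edges. Fixed seeds give byte-identical files.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of paths (`bold`, `mask`, `onsets`, `truth`),
#'   invisibly.
#' @export
write_nifti_fixture <- function(spec, out_dir) {
  sim <- simulate_trials(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- sim$space
  K <- spec$K; T <- spec$T
  L <- 2L * K * T
  series <- matrix(0, space$n, L)
  onset <- integer(0); condition <- character(0)
  for (k in seq_len(K)) {
    oA <- (2L * k - 2L) * T
    oB <- (2L * k - 1L) * T
    series[, oA + seq_len(T)] <- sim$trials_a$values[, k, ]
    series[, oB + seq_len(T)] <- sim$trials_b$values[, k, ]
    onset <- c(onset, oA, oB)
    condition <- c(condition, "A", "B")
  }
  vol <- array(0, c(space$dims, L))
  volmat <- matrix(vol, prod(space$dims), L)
  volmat[space$lin, ] <- series
  paths <- c(bold = file.path(out_dir, "bold.nii"),
             mask = file.path(out_dir, "mask.nii"),
             onsets = file.path(out_dir, "onsets.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_nifti(array(volmat, c(space$dims, L)), paths[["bold"]],
              voxel_size_mm = space$voxel_size_mm, tr_seconds = spec$tr_seconds,
              datatype = 64L)
  write_nifti(array(1, space$dims), paths[["mask"]],
              voxel_size_mm = space$voxel_size_mm, datatype = 2L)
  write.table(data.frame(condition = condition, onset_volume = onset,
                         length_volumes = T),
              paths[["onsets"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_json(list(
    dims = spec$dims, voxel_size_mm = spec$voxel_size_mm, K = K, T = T,
    tr_seconds = spec$tr_seconds, amplitude = spec$amplitude,
    consistency = spec$consistency, noise_sd = spec$noise_sd,
    seed = spec$seed,
    clusters = lapply(spec$clusters, function(cl) {
      cl[c("origin", "size", "condition")]
    }),
    truth_edges = sim$truth[, c("i", "j")]
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
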