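# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive (double/triple loops) and never share code with the
# package's vectorised paths.

full_space <- function(dims, voxel_mm = 3) {
  voxel_space(array(TRUE, dims), rep(voxel_mm, 3))
}

# Triangle vector (upper.tri order) from a symmetric matrix.
tri_of <- function(m) m[upper.tri(m)]

# Naive Pearson + Fisher oracle for sync_matrix: double loop over pairs.
oracle_sync_theta <- function(s, eps = 1e-7) {
  n <- nrow(s)
  th <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      k <- k + 1L
      si <- s[i, ]; sj <- s[j, ]
      if (stats::sd(si) == 0 || stats::sd(sj) == 0) next
      r <- stats::cor(si, sj)
      r <- min(r, 1 - eps)
      if (r > 0) th[k] <- 0.5 * log((1 + r) / (1 - r))
    }
  }
  th
}

# Naive neighbourhood enumeration straight from coordinates (no id_of table).
oracle_neighbourhood <- function(id, space, adjacency) {
  co <- space$coords[id, ]
  out <- integer(0)
  for (v in seq_len(space$n)) {
    d <- abs(space$coords[v, ] - co)
    cheb <- max(d); taxi <- sum(d)
    inc <- if (v == id) TRUE else switch(as.character(adjacency),
      "6"  = taxi == 1,
      "18" = cheb == 1 && taxi <= 2,
      "26" = cheb == 1)
    if (inc) out <- c(out, v)
  }
  out
}

# Brute-force local edge density: triple loop over edges and neighbourhoods.
oracle_density <- function(edges_ij, ztri, z_t, space, adjacency) {
  n <- space$n
  vapply(seq_len(nrow(edges_ij)), function(e) {
    Ni <- oracle_neighbourhood(edges_ij[e, 1], space, adjacency)
    Nj <- oracle_neighbourhood(edges_ij[e, 2], space, adjacency)
    cnt <- 0L
    for (p in Ni) for (q in Nj) {
      k <- if (p < q) (q - 1) * (q - 2) / 2 + p else (p - 1) * (p - 2) / 2 + q
      if (ztri[k] > z_t) cnt <- cnt + 1L
    }
    cnt / (length(Ni) * length(Nj))
  }, numeric(1))
}

# Random normalised triangle over a space.
random_zn <- function(space, seed) {
  N <- space$n * (space$n - 1) / 2
  z <- local({ set.seed(seed); stats::rnorm(N) })
  gaussianize(as_diff_sync_matrix(z, space, normalised = FALSE))
}

# A normalised triangle where exactly the pairs in `hot` (2-col id matrix)
# are suprathreshold at z_t = 2.33 and everything else is far below.
planted_zn <- function(space, hot) {
  N <- space$n * (space$n - 1) / 2
  z <- seq(-6, 0, length.out = N)      # distinct, all below threshold
  idx <- tedfmri:::pair_index(hot[, 1], hot[, 2], space$n)
  z[idx] <- seq(3, 4, length.out = nrow(hot))
  as_diff_sync_matrix(z, space, normalised = TRUE)
}

# Small simulated dataset helper.
quick_sim <- function(seed, dims = c(10L, 10L, 10L), K = 8L, T = 12L,
                      amplitude = 2, consistency = 1, ...) {
  simulate_trials(simulation_spec(dims = dims, K = K, T = T,
                                  amplitude = amplitude,
                                  consistency = consistency, seed = seed, ...))
}

# Sensitivity / false-discovery proportion of a pipeline result against the
# planted ground truth.
recovery_stats <- function(result, truth) {
  n <- result$space$n
  truth_idx <- tedfmri:::pair_index(truth$i, truth$j, n)
  sig <- result$significant
  sig_idx <- if (nrow(sig)) tedfmri:::pair_index(sig$i, sig$j, n) else integer(0)
  list(sensitivity = mean(truth_idx %in% sig_idx),
       fdp = if (length(sig_idx)) mean(!sig_idx %in% truth_idx) else 0,
       n_significant = length(sig_idx))
}
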