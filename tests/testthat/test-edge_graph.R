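test_that("closed neighbourhoods have the textbook sizes", {
  sp <- full_space(c(5L, 5L, 5L))
  centre <- sp$id_of[3, 3, 3]
  corner <- sp$id_of[1, 1, 1]
  expect_length(closed_neighbourhood(centre, sp, 26L), 27L)
  expect_length(closed_neighbourhood(centre, sp, 18L), 19L)
  expect_length(closed_neighbourhood(centre, sp, 6L), 7L)
  expect_length(closed_neighbourhood(corner, sp, 26L), 8L)
  expect_error(closed_neighbourhood(0L, sp), "voxel_id")
})

test_that("closed neighbourhoods respect the mask and match the oracle", {
  set.seed(5)
  mask <- array(runif(4 * 4 * 4) > 0.3, c(4, 4, 4))
  mask[2, 2, 2] <- TRUE
  sp <- voxel_space(mask, c(3, 3, 3))
  for (adj in c(6L, 18L, 26L)) {
    for (id in c(1L, sp$id_of[2, 2, 2], sp$n)) {
      expect_setequal(closed_neighbourhood(id, sp, adj),
                      oracle_neighbourhood(id, sp, adj))
    }
  }
})

test_that("candidate_edges applies strict z and the 15 mm short-edge rule", {
  sp <- full_space(c(7L, 1L, 1L), voxel_mm = 3)   # collinear voxels, 3 mm apart
  N <- 21L
  z <- rep(-3, N)
  idx <- function(i, j) tedfmri:::pair_index(i, j, 7L)
  z[idx(1, 5)] <- 3.0        # 4 steps = 12 mm -> short, excluded
  z[idx(1, 6)] <- 3.0        # 5 steps = 15 mm -> boundary kept
  z[idx(1, 7)] <- 2.33       # 18 mm but z == z_t -> excluded (strict >)
  z[idx(2, 7)] <- 2.3300001  # just above threshold -> kept
  zn <- as_diff_sync_matrix(z, sp, normalised = TRUE)
  es <- candidate_edges(zn, 2.33, 15, sp)
  expect_equal(nrow(es), 2L)
  expect_setequal(paste(es$i, es$j), c("1 6", "2 7"))
  expect_equal(sort(es$distance_mm), c(15, 15))
  expect_error(candidate_edges(zn, 2.33, 0, sp), "positive")
})

test_that("local_edge_density reproduces the worked 11/729 and 5/729 cases", {
  sp <- full_space(c(11L, 5L, 5L), voxel_mm = 3)
  i <- sp$id_of[3, 3, 3]               # interior, full 27-neighbourhood
  j <- sp$id_of[9, 3, 3]               # 18 mm away along x
  Ni <- closed_neighbourhood(i, sp, 26L)
  Nj <- closed_neighbourhood(j, sp, 26L)
  expect_length(Ni, 27L)
  expect_length(Nj, 27L)
  set.seed(8)
  cross <- as.matrix(expand.grid(Ni, Nj))
  for (m in c(11L, 5L)) {
    hot <- rbind(c(i, j), cross[sample(which(cross[, 1] != i | cross[, 2] != j),
                                       m - 1L), ])
    zn <- planted_zn(sp, hot)
    expect_equal(local_edge_density(c(i, j), zn, 2.33, 26L, sp), m / 729)
  }
  # every crossing pair suprathreshold -> density 1
  expect_equal(local_edge_density(c(i, j), planted_zn(sp, cross), 2.33, 26L, sp), 1)
  # a single suprathreshold pair: the edge itself counts
  expect_equal(local_edge_density(c(i, j), planted_zn(sp, rbind(c(i, j))),
                                  2.33, 26L, sp), 1 / 729)
  # overlapping neighbourhoods are a contract violation
  k <- sp$id_of[4, 3, 3]
  zn2 <- planted_zn(sp, rbind(c(i, k)))
  expect_error(local_edge_density(c(i, k), zn2, 2.33, 26L, sp), "overlap")
})

test_that("density_map matches the brute-force oracle on irregular lattices", {
  cases <- list(list(dims = c(6L, 6L, 6L), adj = 26L, seed = 1),
                list(dims = c(5L, 7L, 6L), adj = 18L, seed = 2),
                list(dims = c(6L, 6L, 6L), adj = 6L, seed = 3))
  for (cs in cases) {
    sp <- full_space(cs$dims)
    zn <- random_zn(sp, cs$seed)
    z_t <- quantile_threshold(zn, 0.02)
    es <- candidate_edges(zn, z_t, 15, sp)
    expect_gt(nrow(es), 0L)
    dm <- density_map(es, zn, cs$adj)
    expect_true(all(dm$de >= 0 & dm$de <= 1))
    pick <- seq_len(min(25L, nrow(dm)))   # oracle is O(n^2) per edge
    ora <- oracle_density(cbind(dm$i, dm$j)[pick, , drop = FALSE], zn$z, z_t,
                          sp, cs$adj)
    expect_equal(dm$de[pick], ora)
  }
})

test_that("boundary edges use mask-truncated denominators", {
  sp <- full_space(c(9L, 3L, 3L), voxel_mm = 3)
  i <- sp$id_of[1, 1, 1]               # corner: |N[i]| = 8
  j <- sp$id_of[9, 2, 2]               # far-end face voxel: |N[j]| = 2*3*3 = 18
  expect_length(closed_neighbourhood(i, sp, 26L), 8L)
  expect_length(closed_neighbourhood(j, sp, 26L), 18L)
  zn <- planted_zn(sp, rbind(c(i, j)))
  expect_equal(local_edge_density(c(i, j), zn, 2.33, 26L, sp), 1 / (8 * 18))
  es <- candidate_edges(zn, 2.33, 15, sp)
  dm <- density_map(es, zn, 26L)
  expect_equal(dm$de, 1 / 144)
})

test_that("adding a suprathreshold crossing pair never lowers any density", {
  sp <- full_space(c(8L, 4L, 4L))
  zn <- random_zn(sp, 9)
  z_t <- quantile_threshold(zn, 0.02)
  es <- candidate_edges(zn, z_t, 15, sp)
  dm1 <- density_map(es, zn, 26L)
  # push one previously sub-threshold pair above threshold
  cold <- which(zn$z <= z_t)
  zn2 <- zn
  zn2$z[cold[100]] <- max(zn$z) + 1
  es2 <- candidate_edges(zn2, z_t, 15, sp)
  dm2 <- density_map(es2, zn2, 26L)
  shared <- merge(as.data.frame(dm1), as.data.frame(dm2), by = c("i", "j"))
  expect_true(all(shared$de.y >= shared$de.x))
})
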