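# Step 4: voxel-lattice adjacency, candidate-edge selection, and the local
# edge density D_e.

adjacency_offsets <- function(kind = 26L) {
  kind <- as.integer(kind)
  if (!kind %in% c(6L, 18L, 26L)) stop("adjacency must be one of 6, 18, 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- rowSums(abs(g))
  keep <- switch(as.character(kind),
                 "6"  = o == 1,
                 "18" = o >= 1 & o <= 2,
                 "26" = o >= 1)
  g[keep, , drop = FALSE]
}

#' Closed lattice neighbourhood of a voxel
#'
#' The voxel itself plus its 26-, 18- or 6-adjacent lattice neighbours that lie
#' inside the mask. An interior voxel under 26-adjacency has a closed
#' neighbourhood of 27 voxels, so two full neighbourhoods admit 27 x 27 = 729
#' crossing pairs.
#'
#' @param voxel_id In-mask voxel id (1-based).
#' @param space A `voxel_space`.
#' @param adjacency 6, 18 or 26 (default).
#' @return Integer vector of voxel ids (includes `voxel_id`).
#' @export
closed_neighbourhood <- function(voxel_id, space, adjacency = 26L) {
  stopifnot(inherits(space, "voxel_space"))
  if (length(voxel_id) != 1L || is.na(voxel_id) ||
      voxel_id < 1L || voxel_id > space$n) {
    stop("closed_neighbourhood: voxel_id is not an in-mask voxel id")
  }
  off <- adjacency_offsets(adjacency)
  co <- space$coords[voxel_id, ]
  nb <- sweep(off, 2L, co, `+`)
  ok <- nb[, 1] >= 0 & nb[, 1] < space$dims[1] &
        nb[, 2] >= 0 & nb[, 2] < space$dims[2] &
        nb[, 3] >= 0 & nb[, 3] < space$dims[3]
  nb <- nb[ok, , drop = FALSE]
  ids <- space$id_of[cbind(nb[, 1] + 1L, nb[, 2] + 1L, nb[, 3] + 1L)]
  c(voxel_id, ids[!is.na(ids)])
}

# Precomputed geometry for fast bulk density computation: the sparse n x n
# closed-neighbourhood indicator NB (with diagonal) and the in-mask closed
# neighbourhood size of every voxel. Built once per (space, adjacency).
lattice_geometry <- function(space, adjacency = 26L) {
  off <- adjacency_offsets(adjacency)
  n <- space$n
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(space$coords, 2L, off[r, ], `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < space$dims[1] &
          nb[, 2] >= 0 & nb[, 2] < space$dims[2] &
          nb[, 3] >= 0 & nb[, 3] < space$dims[3]
    ids <- rep(NA_integer_, n)
    ids[ok] <- space$id_of[cbind(nb[ok, 1] + 1L, nb[ok, 2] + 1L, nb[ok, 3] + 1L)]
    hit <- which(!is.na(ids))
    from <- c(from, hit)
    to <- c(to, ids[hit])
  }
  NB <- sparseMatrix(i = c(from, seq_len(n)), j = c(to, seq_len(n)),
                     x = 1, dims = c(n, n))
  list(NB = NB, sizes = as.integer(Matrix::rowSums(NB)), adjacency = as.integer(adjacency))
}

new_edge_set <- function(df, space, z_t, min_distance_mm, adjacency = NULL) {
  structure(df, class = c("edge_set", "data.frame"),
            space = space, z_t = z_t, min_distance_mm = min_distance_mm,
            adjacency = adjacency)
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set> %d edges (z_t = %.3g, min distance %.3g mm)\n",
              nrow(x), attr(x, "z_t"), attr(x, "min_distance_mm")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Suprathreshold, non-short candidate edges
#'
#' Selects all voxel pairs whose normalised z exceeds `z_t` (strictly) and
#' whose endpoints are at least `min_distance_mm` apart (Euclidean distance of
#' voxel centres; "shorter than" is excluded, the boundary is kept). The
#' distance rule keeps the endpoint neighbourhoods disjoint and well separated,
#' so the local edge density is a genuine long-range statistic.
#'
#' @param zn A normalised `diff_sync`.
#' @param z_t Threshold on normalised z (strict `>`).
#' @param min_distance_mm Minimum endpoint distance in mm (default 15).
#' @param space The `voxel_space` (defaults to the triangle's own space).
#' @return An `edge_set`: data frame with columns `i`, `j`, `z`,
#'   `distance_mm`, plus `space`/`z_t`/`min_distance_mm` attributes.
#' @export
candidate_edges <- function(zn, z_t, min_distance_mm = 15, space = zn$space) {
  stopifnot(inherits(zn, "diff_sync"))
  if (!zn$normalised) stop("candidate_edges: z must be normalised first")
  if (!is.numeric(min_distance_mm) || min_distance_mm <= 0) {
    stop("candidate_edges: min_distance_mm must be positive")
  }
  k <- which(zn$z > z_t)
  ij <- index_pairs(k, space$n)
  d <- voxel_distance_mm(space, ij[, 1], ij[, 2])
  keep <- d >= min_distance_mm
  df <- data.frame(i = ij[keep, 1], j = ij[keep, 2],
                   z = zn$z[k][keep], distance_mm = d[keep])
  out <- new_edge_set(df, space, z_t, min_distance_mm)
  attr(out, "supra_idx") <- k   # all suprathreshold pairs, incl. short ones
  out
}

#' Local edge density of one edge
#'
#' For an edge (i, j), the fraction of suprathreshold pairs among all pairs
#' crossing between the in-mask closed neighbourhoods `N[i]` and `N[j]`:
#' `D_e = #\{(p, q): p in N[i], q in N[j], z_{p,q} > z_t\} / (|N[i]| |N[j]|)`.
#' Only cross-neighbourhood pairs are counted; the edge itself (p = i, q = j)
#' is one of them. With full 27-voxel neighbourhoods the denominator is 729.
#' The two neighbourhoods must be disjoint (guaranteed by the 15 mm rule on
#' 3 mm voxels); overlap is an error.
#'
#' @param edge Length-2 vector of voxel ids `c(i, j)`.
#' @param zn A normalised `diff_sync`.
#' @param z_t Threshold on normalised z (strict `>`).
#' @param adjacency 6, 18 or 26 (default).
#' @param space The `voxel_space` (defaults to the triangle's own space).
#' @return `D_e`, a number in [0, 1].
#' @export
local_edge_density <- function(edge, zn, z_t, adjacency = 26L, space = zn$space) {
  stopifnot(inherits(zn, "diff_sync"), length(edge) == 2L)
  i <- as.integer(edge[1]); j <- as.integer(edge[2])
  if (zn$z[pair_index(i, j, space$n)] <= z_t) {
    stop("local_edge_density: edge is not suprathreshold (z <= z_t)")
  }
  Ni <- closed_neighbourhood(i, space, adjacency)
  Nj <- closed_neighbourhood(j, space, adjacency)
  if (length(intersect(Ni, Nj))) {
    stop("local_edge_density: endpoint neighbourhoods overlap (edge too short)")
  }
  pairs <- expand.grid(p = Ni, q = Nj)
  idx <- pair_index(pairs$p, pairs$q, space$n)
  sum(zn$z[idx] > z_t) / (length(Ni) * length(Nj))
}

new_edge_density_map <- function(edges, de, adjacency) {
  df <- as.data.frame(edges)
  df$de <- de
  structure(df, class = c("edge_density_map", "edge_set", "data.frame"),
            space = attr(edges, "space"), z_t = attr(edges, "z_t"),
            min_distance_mm = attr(edges, "min_distance_mm"),
            adjacency = as.integer(adjacency))
}

#' Local edge density for every candidate edge
#'
#' Vectorised equivalent of calling [local_edge_density()] on each edge of an
#' [candidate_edges()] set, via the sparse product `NB %*% S %*% NB` where `NB`
#' is the closed-neighbourhood indicator and `S` the suprathreshold-pair
#' indicator. Edges absent from the candidate set have `D_e` defined as 0 and
#' are not stored.
#'
#' @param edges An `edge_set` from [candidate_edges()].
#' @param zn The normalised `diff_sync` the edges were selected from.
#' @param adjacency 6, 18 or 26 (default).
#' @param geom Optional precomputed `lattice_geometry()` (reused across
#'   permutation replicates).
#' @return An `edge_density_map`: the edge table with an added `de` column.
#' @export
density_map <- function(edges, zn, adjacency = 26L, geom = NULL) {
  stopifnot(inherits(edges, "edge_set"), inherits(zn, "diff_sync"))
  space <- attr(edges, "space")
  z_t <- attr(edges, "z_t")
  if (is.null(geom)) geom <- lattice_geometry(space, adjacency)
  if (geom$adjacency != as.integer(adjacency)) {
    stop("density_map: geom was built for a different adjacency")
  }
  if (nrow(edges) == 0L) {
    return(new_edge_density_map(edges, numeric(0), adjacency))
  }
  # Disjointness: closed radius-1 neighbourhoods are disjoint iff the
  # endpoints' Chebyshev lattice distance is >= 3.
  cheb <- pmax(abs(space$coords[edges$i, 1] - space$coords[edges$j, 1]),
               abs(space$coords[edges$i, 2] - space$coords[edges$j, 2]),
               abs(space$coords[edges$i, 3] - space$coords[edges$j, 3]))
  if (any(cheb < 3L)) {
    stop("density_map: endpoint neighbourhoods overlap for some edges; min_distance_mm too small for this voxel size")
  }
  supra <- attr(edges, "supra_idx") %||% which(zn$z > z_t)
  sup <- index_pairs(supra, space$n)
  S <- sparseMatrix(i = c(sup[, 1], sup[, 2]), j = c(sup[, 2], sup[, 1]),
                    x = 1, dims = c(space$n, space$n))
  C <- geom$NB %*% S %*% geom$NB
  num <- C[cbind(edges$i, edges$j)]
  de <- as.numeric(num) / (geom$sizes[edges$i] * geom$sizes[edges$j])
  new_edge_density_map(edges, de, adjacency)
}
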