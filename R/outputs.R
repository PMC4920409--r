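# Step 6: hubness maps, seed-restricted edge sets, and file exports.

#' Hubness map of an edge set
#'
#' Counts, for every in-mask voxel, the number of edges having it as an
#' endpoint. The sum over all voxels is twice the number of edges (handshake
#' identity). Voxels with high counts are hubs of the task-specific network.
#'
#' @param edges An `edge_set` (typically the significant edges).
#' @param space The `voxel_space` (defaults to the edge set's own).
#' @return A `hubness_map`: list with integer `counts` (length n) and `space`.
#' @export
hubness <- function(edges, space = attr(edges, "space")) {
  stopifnot(inherits(edges, "edge_set"), inherits(space, "voxel_space"))
  if (nrow(edges) && (max(edges$i, edges$j) > space$n || min(edges$i, edges$j) < 1L)) {
    stop("hubness: edge endpoints outside the voxel space")
  }
  counts <- tabulate(c(edges$i, edges$j), nbins = space$n)
  structure(list(counts = as.integer(counts), space = space,
                 n_edges = nrow(edges)),
            class = "hubness_map")
}

#' @export
print.hubness_map <- function(x, ...) {
  cat(sprintf("<hubness_map> %d edges over %d voxels; max hubness %d\n",
              x$n_edges, x$space$n, if (length(x$counts)) max(x$counts) else 0L))
  invisible(x)
}

#' Restrict an edge set to a seed region
#'
#' Keeps the edges with at least one endpoint in the region of interest,
#' mirroring a seed-based view of the significant network.
#'
#' @param edges An `edge_set`.
#' @param roi Non-empty integer vector of in-mask voxel ids.
#' @return The filtered `edge_set` (attributes preserved).
#' @export
seed_restricted_edges <- function(edges, roi) {
  stopifnot(inherits(edges, "edge_set"))
  space <- attr(edges, "space")
  roi <- as.integer(roi)
  if (!length(roi)) stop("seed_restricted_edges: roi is empty")
  if (any(roi < 1L | roi > space$n)) {
    stop("seed_restricted_edges: roi contains ids outside the mask")
  }
  keep <- edges$i %in% roi | edges$j %in% roi
  out <- edges[keep, , drop = FALSE]
  attributes(out)[c("space", "z_t", "min_distance_mm", "adjacency")] <-
    attributes(edges)[c("space", "z_t", "min_distance_mm", "adjacency")]
  class(out) <- class(edges)
  out
}

# Edge table with lattice and mm coordinates of both endpoints.
edge_table <- function(edges, space, fdr_fun = NULL) {
  df <- as.data.frame(edges)
  ci <- space$coords[df$i, , drop = FALSE]
  cj <- space$coords[df$j, , drop = FALSE]
  out <- data.frame(
    i = df$i, j = df$j,
    xi = ci[, 1], yi = ci[, 2], zi = ci[, 3],
    xj = cj[, 1], yj = cj[, 2], zj = cj[, 3],
    xi_mm = ci[, 1] * space$voxel_size_mm[1],
    yi_mm = ci[, 2] * space$voxel_size_mm[2],
    zi_mm = ci[, 3] * space$voxel_size_mm[3],
    xj_mm = cj[, 1] * space$voxel_size_mm[1],
    yj_mm = cj[, 2] * space$voxel_size_mm[2],
    zj_mm = cj[, 3] * space$voxel_size_mm[3],
    z = df$z)
  if (!is.null(df$de)) out$de <- df$de
  if (!is.null(fdr_fun) && !is.null(df$de)) out$fdr <- fdr_fun(df$de)
  out
}

# Step function giving Fdr(D_e) from a curve (right-continuous lookup).
fdr_lookup <- function(curve) {
  G <- length(curve$grid)
  function(de) {
    idx <- findInterval(de, curve$grid, left.open = TRUE) + 1L
    curve$fdr[pmin(pmax(idx, 1L), G)]
  }
}

#' Export hubness map, edge table, Fdr curve and run manifest
#'
#' Writes four files into `out_dir`: `hubness.nii` (counts on the original
#' grid, zeros off-mask), `edges.tsv` (both endpoints' voxel ids, 0-based
#' lattice and mm coordinates, z, D_e, Fdr), `fdr_curve.tsv` (grid, F0, Fz,
#' fdr) and `manifest.json` (all parameters, seeds and stage counts). Exports
#' are byte-stable for identical inputs.
#'
#' @param map A [hubness()] map.
#' @param edges The significant `edge_density_map`.
#' @param curve The [fdr_curve()].
#' @param manifest Named list of parameters/seeds/counts to record.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_results <- function(map, edges, curve, manifest, out_dir) {
  stopifnot(inherits(map, "hubness_map"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- map$space
  vol <- array(0, space$dims)
  vol[space$lin] <- map$counts
  paths <- c(
    hubness = file.path(out_dir, "hubness.nii"),
    edges = file.path(out_dir, "edges.tsv"),
    fdr = file.path(out_dir, "fdr_curve.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_nifti(vol, paths[["hubness"]], voxel_size_mm = space$voxel_size_mm,
              datatype = 16L)
  tab <- edge_table(edges, space, fdr_fun = if (!is.null(curve)) fdr_lookup(curve))
  write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
              paths[["edges"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(curve)) {
    ctab <- data.frame(de = curve$grid, F0 = curve$F0, Fz = curve$Fz,
                       fdr = curve$fdr)
    write.table(format(ctab, digits = 10, trim = TRUE, scientific = FALSE),
                paths[["fdr"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  invisible(paths)
}
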