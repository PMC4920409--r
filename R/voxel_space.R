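#' Voxel space: masked lattice geometry
#'
#' Builds the shared geometry object used throughout the pipeline: a 3D brain
#' mask, voxel sizes, and a bijection between in-mask lattice coordinates and
#' contiguous voxel ids `1..n`. Ids are assigned in ascending `(x, y, z)`
#' lexicographic order of the 0-based lattice coordinates (x most significant),
#' and every pairwise matrix in the package uses this order.
#'
#' @param mask 3D logical (or 0/1 numeric) array; `TRUE` marks in-mask voxels.
#' @param voxel_size_mm Length-3 positive voxel edge lengths in mm.
#' @return An object of class `voxel_space` with fields `mask`, `dims`,
#'   `voxel_size_mm`, `n`, `coords` (n x 3 integer, 0-based), `coords_mm`
#'   (n x 3 voxel-centre coordinates in mm) and `lin` (linear index of each
#'   voxel id into the 3D array).
#' @export
voxel_space <- function(mask, voxel_size_mm = c(3, 3, 3)) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("voxel_space: mask must be a 3D array")
  }
  if (anyNA(mask)) stop("voxel_space: mask contains NA")
  storage.mode(mask) <- "logical"
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("voxel_space: voxel_size_mm must be three positive numbers")
  }
  n <- sum(mask)
  if (n < 2L) stop("voxel_space: mask must contain at least 2 voxels")
  idx <- which(mask, arr.ind = TRUE)
  coords <- idx - 1L
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[ord, , drop = FALSE]
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  dims <- dim(mask)
  lin <- coords[, 3] * (dims[1] * dims[2]) + coords[, 2] * dims[1] + coords[, 1] + 1L
  id_of <- array(NA_integer_, dims)
  id_of[lin] <- seq_len(n)
  structure(list(
    mask = mask, dims = dims, voxel_size_mm = voxel_size_mm, n = n,
    coords = coords,
    coords_mm = sweep(coords, 2L, voxel_size_mm, `*`),
    lin = as.integer(lin), id_of = id_of
  ), class = "voxel_space")
}

#' @export
print.voxel_space <- function(x, ...) {
  cat(sprintf("<voxel_space> %d x %d x %d lattice, %d in-mask voxels, voxel %s mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$n,
              paste(format(x$voxel_size_mm), collapse = " x ")))
  invisible(x)
}

same_space <- function(a, b) {
  identical(a$dims, b$dims) && identical(a$voxel_size_mm, b$voxel_size_mm) &&
    identical(a$lin, b$lin)
}

# Euclidean distance in mm between voxel ids i and j (vectorised).
voxel_distance_mm <- function(space, i, j) {
  d <- space$coords_mm[i, , drop = FALSE] - space$coords_mm[j, , drop = FALSE]
  sqrt(rowSums(d * d))
}
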