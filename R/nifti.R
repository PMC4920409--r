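# Minimal NIfTI-1 I/O (single-file .nii / .nii.gz).
#
# Supports the datatypes used in fMRI practice (uint8, int16, int32, float32,
# float64), scl_slope/scl_inter rescaling and both endiannesses on read;
# writes little-endian float64/float32/uint8 volumes with an axis-aligned
# sform. Deliberately not a general NIfTI library: no extensions, no .hdr/.img
# pairs, no qform quaternions.

.nifti_dt <- function(code) {
  switch(as.character(code),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "numeric", size = 4L, signed = TRUE),
    "64" = list(what = "numeric", size = 8L, signed = TRUE),
    stop(sprintf("unsupported NIfTI datatype code %s", code))
  )
}

.nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an R array.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array with the image
#'   dimensions), `voxel_size_mm` (length-3 numeric, from `pixdim[1:3]`),
#'   `tr_seconds` (the fourth `pixdim` entry, `NA` for 3D images) and `dims`.
#' @seealso [write_nifti()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- .nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop(sprintf("%s: truncated NIfTI header", path))
  endian <- "little"
  if (readBin(hdr[1:4], "integer", 1L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", 1L, 4L, endian = endian) != 348L) {
      stop(sprintf("%s: not a NIfTI-1 file (sizeof_hdr != 348)", path))
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop(sprintf("%s: unsupported NIfTI magic '%s'", path, magic))
  dim0 <- readBin(hdr[41:56], "integer", 8L, 2L, endian = endian)
  ndim <- dim0[1]
  if (ndim < 3L || ndim > 4L) stop(sprintf("%s: only 3D/4D images supported", path))
  dims <- dim0[2:(1 + ndim)]
  datatype <- readBin(hdr[71:72], "integer", 1L, 2L, endian = endian)
  pixdim <- readBin(hdr[77:108], "numeric", 8L, 4L, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", 1L, 4L, endian = endian)
  scl_slope <- readBin(hdr[113:116], "numeric", 1L, 4L, endian = endian)
  scl_inter <- readBin(hdr[117:120], "numeric", 1L, 4L, endian = endian)
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  dt <- .nifti_dt(datatype)
  nvox <- prod(dims)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < nvox) stop(sprintf("%s: truncated NIfTI data", path))
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = dims),
       voxel_size_mm = abs(pixdim[2:4]),
       tr_seconds = if (ndim >= 4L) pixdim[5] else NA_real_,
       dims = dims)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D array as a little-endian single-file NIfTI-1 image with
#' an axis-aligned sform built from the voxel size.
#'
#' @param data 3D or 4D numeric/logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Length-3 voxel edge lengths in mm.
#' @param tr_seconds Repetition time stored in `pixdim[4]` (4D images).
#' @param datatype NIfTI datatype code: 64 (float64, default), 16 (float32)
#'   or 2 (uint8).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(1, 1, 1), tr_seconds = 1,
                        datatype = 64L) {
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("write_nifti: data must be a 3D or 4D array")
  }
  if (!datatype %in% c(2L, 16L, 64L)) {
    stop("write_nifti: datatype must be one of 2 (uint8), 16 (float32), 64 (float64)")
  }
  hdr <- raw(348L)
  poke <- function(x, size, at) {
    r <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(at + 1):(at + length(r))] <<- r
    invisible(NULL)
  }
  dimv <- rep(1L, 8L)
  dimv[1] <- length(d)
  dimv[seq_along(d) + 1L] <- as.integer(d)
  bitpix <- c("2" = 8L, "16" = 32L, "64" = 64L)[[as.character(datatype)]]
  poke(348L, 4L, 0L)
  poke(dimv, 2L, 40L)
  poke(as.integer(datatype), 2L, 70L)
  poke(bitpix, 2L, 72L)
  poke(as.numeric(c(1, voxel_size_mm, tr_seconds, 0, 0, 0)), 4L, 76L)
  poke(352, 4L, 108L)                 # vox_offset
  poke(c(1, 0), 4L, 112L)             # scl_slope, scl_inter
  hdr[124L] <- as.raw(10L)            # xyzt_units: mm | sec
  poke(c(0L, 1L), 2L, 252L)           # qform_code = 0, sform_code = 1
  srow <- rbind(c(voxel_size_mm[1], 0, 0, 0),
                c(0, voxel_size_mm[2], 0, 0),
                c(0, 0, voxel_size_mm[3], 0))
  poke(as.numeric(t(srow)), 4L, 280L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)              # extension indicator
  if (datatype == 2L) {
    writeBin(as.integer(round(as.numeric(data))), con, size = 1L)
  } else {
    writeBin(as.numeric(data), con, size = if (datatype == 64L) 8L else 4L)
  }
  invisible(path)
}
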