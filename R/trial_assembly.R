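# Step 1 of the pipeline: load runs, remove slow drifts, cut the series into
# fixed-length per-condition trials, and normalise each trial.

new_bold_run <- function(space, series, tr_seconds) {
  structure(list(space = space, series = series, tr_seconds = tr_seconds),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d voxels x %d volumes, TR %.3f s\n",
              nrow(x$series), ncol(x$series), x$tr_seconds))
  invisible(x)
}

#' Load a 4D BOLD run restricted to a brain mask
#'
#' Reads a 4D NIfTI series and a 3D mask on the same grid and returns the
#' in-mask time series in voxel-id order (see [voxel_space()]). Voxel size and
#' TR are taken from the volume header unless overridden.
#'
#' @param volume_path Path to a 4D NIfTI file.
#' @param mask_path Path to a 3D NIfTI mask (nonzero = in mask).
#' @param tr_seconds Optional TR override (seconds per volume).
#' @param voxel_size_mm Optional voxel-size override (length 3, mm).
#' @return A `bold_run`: list with `space` (a `voxel_space`), `series`
#'   (n voxels x L volumes matrix) and `tr_seconds`.
#' @export
load_bold_run <- function(volume_path, mask_path, tr_seconds = NULL,
                          voxel_size_mm = NULL) {
  vol <- read_nifti(volume_path)
  msk <- read_nifti(mask_path)
  if (length(msk$dims) != 3L) stop("load_bold_run: mask must be a 3D volume")
  if (length(vol$dims) != 4L) stop("load_bold_run: series must be a 4D volume")
  if (!identical(as.integer(vol$dims[1:3]), as.integer(msk$dims))) {
    stop(sprintf("load_bold_run: grid mismatch between volume (%s) and mask (%s)",
                 paste(vol$dims[1:3], collapse = "x"),
                 paste(msk$dims, collapse = "x")))
  }
  mask <- msk$data != 0
  if (!any(mask)) stop("load_bold_run: mask is empty")
  vs <- voxel_size_mm %||% vol$voxel_size_mm
  tr <- tr_seconds %||% vol$tr_seconds
  if (is.na(tr) || tr <= 0) stop("load_bold_run: TR missing from header; pass tr_seconds")
  space <- voxel_space(mask, vs)
  L <- vol$dims[4]
  if (L < 2L) stop("load_bold_run: series must have at least 2 volumes")
  series <- matrix(vol$data, prod(vol$dims[1:3]), L)[space$lin, , drop = FALSE]
  if (!all(is.finite(series))) {
    stop("load_bold_run: non-finite values inside the mask")
  }
  new_bold_run(space, series, tr)
}

# Drift basis: constant + linear trend + DCT-II cosines with frequency below
# the cutoff. Frequency of the k-th cosine over L volumes is k / (2 L TR).
drift_basis <- function(L, tr_seconds, cutoff_hz) {
  t0 <- seq_len(L) - 1
  kmax <- max(0L, ceiling(2 * L * tr_seconds * cutoff_hz) - 1L)
  X <- cbind(1, t0 - mean(t0))
  if (kmax >= 1L) {
    for (k in seq_len(kmax)) X <- cbind(X, cos(pi * k * (t0 + 0.5) / L))
  }
  X
}

#' Remove baseline drifts with a highpass projection
#'
#' Regresses a drift basis (constant, linear trend, and all discrete-cosine
#' basis functions with frequency below `cutoff_hz`) out of every voxel's time
#' series. The operation is an exact linear projection, so applying it twice
#' equals applying it once; the output has zero mean per voxel.
#'
#' @param run A `bold_run`.
#' @param cutoff_hz Highpass cutoff in Hz; must be below the Nyquist frequency
#'   `1/(2 TR)`. The default 1/90 Hz suits block designs of ~15-30 s trials.
#' @return A `bold_run` with detrended series.
#' @export
highpass_detrend <- function(run, cutoff_hz = 1 / 90) {
  stopifnot(inherits(run, "bold_run"))
  nyquist <- 1 / (2 * run$tr_seconds)
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0) {
    stop("highpass_detrend: cutoff_hz must be positive")
  }
  if (cutoff_hz >= nyquist) {
    stop(sprintf("highpass_detrend: cutoff %.4g Hz is at or above Nyquist (%.4g Hz)",
                 cutoff_hz, nyquist))
  }
  L <- ncol(run$series)
  X <- drift_basis(L, run$tr_seconds, cutoff_hz)
  Q <- qr.Q(qr(X))
  Y <- t(run$series)                       # L x n
  resid <- Y - Q %*% crossprod(Q, Y)
  new_bold_run(run$space, t(resid), run$tr_seconds)
}

#' Trial-onset table
#'
#' Validates a table of trial onsets for a two-condition block design: labels
#' in `{A, B}`, 0-based onset volumes, a common trial length `T`, the same
#' number of trials `K` in each condition, non-overlapping trials, and all
#' trials inside the run.
#'
#' @param condition Character vector of condition labels (`"A"`/`"B"`).
#' @param onset_volume Integer vector of 0-based onset volumes.
#' @param length_volumes Integer vector of trial lengths in volumes.
#' @param n_volumes Run length `L`, used to check `onset + T <= L`.
#' @return A data frame of class `onset_table`, sorted by onset.
#' @export
onset_table <- function(condition, onset_volume, length_volumes, n_volumes) {
  condition <- as.character(condition)
  onset_volume <- as.integer(onset_volume)
  length_volumes <- as.integer(length_volumes)
  if (!all(condition %in% c("A", "B"))) {
    stop("onset_table: condition labels must be 'A' or 'B'")
  }
  if (any(onset_volume < 0L)) stop("onset_table: onset volumes must be >= 0")
  if (any(length_volumes < 1L)) stop("onset_table: trial lengths must be positive")
  if (length(unique(length_volumes)) != 1L) {
    stop("onset_table: all trials must have the same length T")
  }
  if (any(onset_volume + length_volumes > n_volumes)) {
    stop("onset_table: trial extends beyond the run (onset + T > L)")
  }
  kA <- sum(condition == "A")
  kB <- sum(condition == "B")
  if (kA != kB) {
    stop(sprintf("onset_table: conditions must have equal trial counts (A: %d, B: %d)",
                 kA, kB))
  }
  if (kA < 1L) stop("onset_table: both conditions must be present")
  ord <- order(onset_volume)
  df <- data.frame(condition = condition[ord], onset_volume = onset_volume[ord],
                   length_volumes = length_volumes[ord])
  if (nrow(df) > 1L) {
    gap <- df$onset_volume[-1L] - (df$onset_volume[-nrow(df)] + df$length_volumes[-nrow(df)])
    if (any(gap < 0L)) stop("onset_table: trials overlap")
  }
  attr(df, "n_volumes") <- as.integer(n_volumes)
  class(df) <- c("onset_table", "data.frame")
  df
}

#' Read a trial-onset TSV
#'
#' Expects a tab-separated file with header
#' `condition<TAB>onset_volume<TAB>length_volumes` and 0-based onsets.
#'
#' @param path Path to the TSV.
#' @param n_volumes Run length `L` for validation.
#' @return An [onset_table()].
#' @export
read_onsets <- function(path, n_volumes) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "onset_volume", "length_volumes")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_onsets: expected columns %s", paste(need, collapse = ", ")))
  }
  onset_table(df$condition, df$onset_volume, df$length_volumes, n_volumes)
}

new_trial_array <- function(space, condition, values) {
  d <- dim(values)
  if (length(d) != 3L) stop("trial_array: values must be voxel x trial x time")
  if (d[2] < 2L) stop("trial_array: need at least K = 2 trials")
  if (d[3] < 3L) stop("trial_array: need at least T = 3 time points")
  if (!all(is.finite(values))) stop("trial_array: non-finite values")
  structure(list(space = space, condition = condition, values = values,
                 K = d[2], T = d[3]),
            class = "trial_array")
}

#' @export
print.trial_array <- function(x, ...) {
  cat(sprintf("<trial_array> condition %s: %d voxels x %d trials x %d time points\n",
              x$condition, dim(x$values)[1], x$K, x$T))
  invisible(x)
}

#' Cut a run into per-condition trials
#'
#' @param run A `bold_run`.
#' @param onsets An [onset_table()].
#' @param condition Which condition to extract (`"A"` or `"B"`).
#' @return A `trial_array` with values indexed voxel x trial x within-trial
#'   time, trials in onset order.
#' @export
extract_trials <- function(run, onsets, condition) {
  stopifnot(inherits(run, "bold_run"), inherits(onsets, "onset_table"))
  rows <- onsets[onsets$condition == condition, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("extract_trials: condition '%s' absent from onset table", condition))
  }
  L <- ncol(run$series)
  if (any(rows$onset_volume + rows$length_volumes > L)) {
    stop("extract_trials: onsets exceed run length")
  }
  K <- nrow(rows)
  T <- rows$length_volumes[1]
  n <- nrow(run$series)
  values <- array(0, c(n, K, T))
  for (k in seq_len(K)) {
    values[, k, ] <- run$series[, rows$onset_volume[k] + seq_len(T), drop = FALSE]
  }
  new_trial_array(run$space, condition, values)
}

#' Normalise each trial's time series to mean 0, sd 1
#'
#' Every (voxel, trial) series is centred and scaled to unit sample standard
#' deviation (divisor `T - 1`). Constant series are an error because the
#' downstream effect-size statistic is undefined for them.
#'
#' @param trials A `trial_array`.
#' @return A `trial_array` of the same shape.
#' @export
normalize_trials <- function(trials) {
  stopifnot(inherits(trials, "trial_array"))
  d <- dim(trials$values)
  n <- d[1]; K <- d[2]; T <- d[3]
  M <- matrix(trials$values, n * K, T)
  m <- rowMeans(M)
  M <- M - m
  s <- sqrt(rowSums(M * M) / (T - 1))
  bad <- which(s == 0)
  if (length(bad)) {
    vox <- (bad - 1L) %% n + 1L
    tri <- (bad - 1L) %/% n + 1L
    stop(sprintf("normalize_trials: zero-variance trial series (voxel %s, trial %s%s)",
                 paste(head(vox, 5L), collapse = ","),
                 paste(head(tri, 5L), collapse = ","),
                 if (length(bad) > 5L) ", ..." else ""))
  }
  out <- trials
  out$values <- array(M / s, d)
  out
}
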