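test_that("NIfTI round trips preserve data, voxel size and TR", {
  td <- withr_like_tempdir <- tempfile("nifti")
  dir.create(td)
  set.seed(1)
  for (ext in c(".nii", ".nii.gz")) {
    arr <- array(rnorm(4 * 5 * 6 * 3), c(4, 5, 6, 3))
    p <- file.path(td, paste0("vol", ext))
    write_nifti(arr, p, voxel_size_mm = c(3, 3, 3.5), tr_seconds = 0.72)
    r <- read_nifti(p)
    expect_identical(r$data, arr)
    expect_equal(r$voxel_size_mm, c(3, 3, 3.5), tolerance = 1e-6)
    expect_equal(r$tr_seconds, 0.72, tolerance = 1e-6)
  }
  msk <- array(runif(4 * 5 * 6) > 0.5, c(4, 5, 6))
  p <- file.path(td, "mask.nii")
  write_nifti(msk, p, voxel_size_mm = c(3, 3, 3), datatype = 2L)
  expect_identical(read_nifti(p)$data != 0, msk)
  unlink(td, recursive = TRUE)
})

make_run_files <- function(dims, L, mask = array(TRUE, dims), seed = 1,
                           tr = 0.72) {
  td <- tempfile("run")
  dir.create(td)
  set.seed(seed)
  vol <- array(rnorm(prod(dims) * L), c(dims, L))
  write_nifti(vol, file.path(td, "bold.nii"), voxel_size_mm = c(3, 3, 3),
              tr_seconds = tr)
  write_nifti(mask, file.path(td, "mask.nii"), voxel_size_mm = c(3, 3, 3),
              datatype = 2L)
  list(dir = td, vol = vol, bold = file.path(td, "bold.nii"),
       mask = file.path(td, "mask.nii"))
}

test_that("load_bold_run does the shape bookkeeping and rejects bad input", {
  dims <- c(4L, 4L, 4L)
  mask <- array(FALSE, dims)
  mask[sample(1:64, 10)] <- TRUE
  f <- make_run_files(dims, L = 20L, mask = mask)
  run <- load_bold_run(f$bold, f$mask)
  expect_s3_class(run, "bold_run")
  expect_equal(dim(run$series), c(10L, 20L))
  expect_equal(run$tr_seconds, 0.72, tolerance = 1e-6)
  # series are in ascending (x, y, z) id order and match the raw volume
  sp <- run$space
  v1 <- f$vol[sp$coords[3, 1] + 1, sp$coords[3, 2] + 1, sp$coords[3, 3] + 1, ]
  expect_equal(run$series[3, ], v1)

  f2 <- make_run_files(c(5L, 4L, 4L), L = 20L)
  expect_error(load_bold_run(f2$bold, f$mask), "grid mismatch")
  empty <- array(FALSE, dims)
  pe <- file.path(f$dir, "empty.nii")
  write_nifti(empty, pe, datatype = 2L)
  expect_error(load_bold_run(f$bold, pe), "mask is empty")
  unlink(c(f$dir, f2$dir), recursive = TRUE)
})

test_that("voxel ids are ascending (x, y, z) lexicographic", {
  sp <- full_space(c(2L, 2L, 2L))
  expect_equal(sp$coords[, "x"], c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
               ignore_attr = TRUE)
  expect_equal(sp$coords[, "z"], rep(c(0L, 1L), 4L), ignore_attr = TRUE)
})

test_that("highpass_detrend removes drifts and passes task-band signal", {
  L <- 200L
  tr <- 0.72
  sp <- full_space(c(2L, 2L, 1L))
  ramp <- seq(0, 10, length.out = L)
  t_sec <- (seq_len(L) - 1) * tr
  sine <- sin(2 * pi * 0.2 * t_sec)
  series <- rbind(ramp, sine, rep(5, L), ramp + sine)
  run <- tedfmri:::new_bold_run(sp, series, tr)
  out <- highpass_detrend(run, 1 / 90)
  # a linear ramp lies in the drift span
  expect_lt(max(abs(out$series[1, ])), 1e-6 * diff(range(ramp)))
  # a 0.2 Hz sinusoid is far above the cutoff and survives
  expect_gt(cor(out$series[2, ], sine), 0.99)
  # constants vanish; output is centred
  expect_equal(out$series[3, ], rep(0, L), ignore_attr = TRUE)
  expect_equal(rowMeans(out$series), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  # idempotent linear projection
  twice <- highpass_detrend(out, 1 / 90)
  expect_equal(twice$series, out$series, tolerance = 1e-10)
  expect_error(highpass_detrend(run, 1 / (2 * tr)), "Nyquist")
})

test_that("onset tables enforce the block-design invariants", {
  ot <- onset_table(c("A", "B", "A", "B"), c(0, 16, 32, 48), rep(16, 4), 64)
  expect_s3_class(ot, "onset_table")
  expect_error(onset_table(c("A", "B"), c(0, 8), c(16, 16), 64), "overlap")
  expect_error(onset_table(c("A", "B"), c(0, 20), c(16, 16), 32), "beyond the run")
  expect_error(onset_table(c("A", "B"), c(0, 16), c(16, 8), 64), "same length")
  expect_error(onset_table(c("A", "A"), c(0, 16), c(16, 16), 64), "equal trial counts")
  expect_error(onset_table(c("A", "C"), c(0, 16), c(16, 16), 64), "'A' or 'B'")

  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(condition = c("A", "B"), onset_volume = c(0, 16),
                         length_volumes = 16),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_onsets(p, 32)$onset_volume, c(0L, 16L))
  unlink(p)
})

test_that("extract_trials slices the run exactly and uses no volume twice", {
  sp <- full_space(c(2L, 2L, 2L))
  series <- matrix(seq_len(8L * 32L), 8L, 32L)
  run <- tedfmri:::new_bold_run(sp, series, 0.72)
  ot <- onset_table(c("A", "B", "A", "B"), c(0, 8, 16, 24), rep(8, 4), 32)
  ta <- extract_trials(run, ot, "A")
  tb <- extract_trials(run, ot, "B")
  expect_equal(dim(ta$values), c(8L, 2L, 8L))
  expect_equal(ta$values[, 1, ], series[, 1:8])
  expect_equal(ta$values[, 2, ], series[, 17:24])
  expect_equal(tb$values[, 1, ], series[, 9:16])
  # no volume shared between any two trials
  used <- c(outer(seq_len(8), ot$onset_volume, `+`))
  expect_equal(anyDuplicated(used), 0L)
  ot_a_only <- onset_table(c("A", "B"), c(0, 8), c(8, 8), 32)
  expect_error(extract_trials(run, ot_a_only, "C"), "absent")
})

test_that("normalize_trials matches the closed form and its invariances", {
  sp <- full_space(c(2L, 1L, 1L))
  v <- array(0, c(2, 2, 3))
  v[1, 1, ] <- c(1, 2, 3)
  v[1, 2, ] <- c(4, 8, 12)
  v[2, 1, ] <- c(0, 1, 5)
  v[2, 2, ] <- c(-1, 0, 2)
  tr <- tedfmri:::new_trial_array(sp, "A", v)
  nt <- normalize_trials(tr)
  expect_equal(nt$values[1, 1, ], c(-1, 0, 1))
  for (i in 1:2) for (k in 1:2) {
    expect_equal(mean(nt$values[i, k, ]), 0, tolerance = 1e-12)
    expect_equal(sd(nt$values[i, k, ]), 1, tolerance = 1e-12)
  }
  # idempotence and affine invariance: normalising a*x + b equals normalising x
  expect_equal(normalize_trials(nt)$values, nt$values, tolerance = 1e-12)
  tr2 <- tr
  tr2$values <- 3.7 * tr$values + 11
  expect_equal(normalize_trials(tr2)$values, nt$values, tolerance = 1e-12)

  v[2, 2, ] <- 5
  trc <- tedfmri:::new_trial_array(sp, "A", v)
  expect_error(normalize_trials(trc), "zero-variance.*voxel 2, trial 2")
})
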