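test_that("time-averaged tangent angle equals the static offset over integer cycles", {
  # 20 Hz sampled at 200 fps for 400 frames = 40 full cycles
  for (off in c(0, 0.2)) {
    p <- waveform_params(beat_freq_hz = 20, frame_rate_hz = 200,
                         n_frames = 400, asym_offset = off)
    tr <- generate_waveform(p)
    expect_equal(rowMeans(tr$psi), rep(off, nrow(tr$psi)), tolerance = 1e-12)
  }
})

test_that("the waveform is periodic with the beat period", {
  p <- waveform_params(beat_freq_hz = 20, frame_rate_hz = 200, n_frames = 30)
  tr <- generate_waveform(p)
  # period = 200/20 = 10 frames; psi(s, t + 0.05 s) = psi(s, t)
  expect_equal(tr$psi[, 1:20], tr$psi[, 11:30], tolerance = 1e-12)
  expect_equal(tr$x_um[, 3], tr$x_um[, 13], tolerance = 1e-12)
})

test_that("invalid waveform parameters are rejected", {
  expect_error(waveform_params(beat_freq_hz = 120, frame_rate_hz = 200),
               "Nyquist")
  expect_error(waveform_params(length_um = -5), "positive")
  expect_error(waveform_params(n_frames = 1), "at least 2")
  expect_error(waveform_params(pixel_size_um = 0), "positive")
})

test_that("midline geometry is consistent: spacing bounded, arc length monotone", {
  tr <- generate_waveform(tiny_params())
  for (k in c(1, 20, 40)) {
    seg <- sqrt(diff(tr$x_um[, k])^2 + diff(tr$y_um[, k])^2)
    expect_true(all(seg <= 1.5))
    expect_true(all(seg > 0))
  }
  expect_true(all(diff(tr$s_um) > 0))
})

test_that("a constant curvature offset biases the nominal curvature field uniformly", {
  p <- waveform_params(beat_freq_hz = 20, n_frames = 400,
                       asym_offset = curvature_offset(0.2))
  tr <- generate_waveform(p)
  interior <- tr$s_um >= 10 & tr$s_um <= 70
  expect_equal(tr$asym_nominal_rad[interior],
               rep(0.2, sum(interior)), tolerance = 1e-3)
})

test_that("ground-truth CSV export has one row per point and frame", {
  tr <- generate_waveform(tiny_params())
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(tr, path)
  df <- read.csv(path)
  expect_equal(nrow(df), nrow(tr$psi) * ncol(tr$psi))
  expect_equal(df$tangent_angle_rad[df$frame == 2], tr$psi[, 2])
})
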