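test_that("column-wise intensity maxima of a noiseless straight flagellum track the midline", {
  p <- tiny_params(amp_envelope = 0, noise_sd = 0, n_frames = 2)
  tr <- generate_waveform(p)
  m <- render_movie(tr, render_head = FALSE)
  truth_y <- tr$y_um[, 1] / p$pixel_size_um + m$origin_px[2]
  truth_x <- tr$x_um[, 1] / p$pixel_size_um + m$origin_px[1]
  frame <- m$frames[, , 1]
  cols <- round(seq(min(truth_x) + 2, max(truth_x) - 2, by = 3))
  for (j in cols) {
    i_max <- which.max(frame[, j])
    y_true <- truth_y[which.min(abs(truth_x - j))]
    expect_lt(abs(i_max - y_true), 0.5 + 1e-9)
  }
})

test_that("rendering is deterministic in the seed", {
  p1 <- tiny_params(seed = 7, n_frames = 5)
  m1 <- render_movie(generate_waveform(p1))
  m2 <- render_movie(generate_waveform(p1))
  expect_identical(m1$frames, m2$frames)
  p3 <- tiny_params(seed = 8, n_frames = 5)
  m3 <- render_movie(generate_waveform(p3))
  expect_false(identical(m1$frames, m3$frames))
})

test_that("additive noise in empty margins has the configured statistics", {
  p <- tiny_params(noise_sd = 0.05, seed = 11, n_frames = 4)
  m <- render_movie(generate_waveform(p), clamp = FALSE)
  # top-left margin corner is far from the flagellum
  patch <- m$frames[1:8, 1:8, ]
  n <- length(patch)
  expect_lt(abs(mean(patch)), 3 * p$noise_sd / sqrt(n))
  expect_equal(sd(patch), p$noise_sd, tolerance = 0.15)
  # clamped rendering stays within [0, max]
  m2 <- render_movie(generate_waveform(p))
  expect_gte(min(m2$frames), 0)
})

test_that("midlines that do not fit the requested frame fail naming the frame", {
  tr <- generate_waveform(tiny_params(n_frames = 3))
  expect_error(render_movie(tr, frame_dim = c(20, 20)), "frame 1")
})

test_that("movies round-trip through 16-bit TIFF plus sidecar", {
  m <- tiny_movie(tiny_params(n_frames = 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(m, path)
  m2 <- read_movie(path)
  expect_equal(m2$frame_rate_hz, m$frame_rate_hz)
  expect_equal(m2$pixel_size_um, m$pixel_size_um)
  expect_equal(dim(m2$frames), dim(m$frames))
  # 16-bit quantisation: worst-case error is scale / 2^16
  expect_lt(max(abs(m2$frames - m$frames)), max(m$frames) / 65535)
  expect_equal(unname(m2$origin_px), unname(m$origin_px))
})
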