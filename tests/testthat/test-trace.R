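test_that("a noiseless straight flagellum is traced to sub-pixel accuracy", {
  p <- tiny_params(amp_envelope = 0, noise_sd = 0, n_frames = 2)
  tr <- generate_waveform(p)
  m <- render_movie(tr)
  t <- trace_movie(m)
  err <- trace_error_px(t, tr, m)
  expect_lt(err$rms_px, 0.5)
})

test_that("the traced arc length of a quarter-circle matches R*pi/2 within 2%", {
  R <- 50
  p <- waveform_params(length_um = R * pi / 2, amp_envelope = 0,
                       asym_offset = function(s) s / R, beat_freq_hz = 5,
                       n_frames = 2, noise_sd = 0)
  tr <- generate_waveform(p)
  m <- render_movie(tr)
  t <- trace_movie(m)
  L <- max(t$frames[[1]]$arclen_um)
  expect_lt(abs(L - R * pi / 2) / (R * pi / 2), 0.02)
})

test_that("blank and multi-object frames fail with a trace error", {
  s <- trace_settings()
  expect_error(trace_midline(matrix(0, 50, 50), s), "trace failure")
  # two separated bright blobs of similar size
  two <- flagbeat:::cpp_render_ridge(c(10, 20), c(10, 10), 60, 60, 1.5, 1) +
    flagbeat:::cpp_render_ridge(c(40, 50), c(45, 45), 60, 60, 1.5, 1)
  expect_error(trace_midline(two, s), "multiple large components")
})

test_that("Gaussian normal refinement recovers a known sub-pixel ridge offset", {
  # ridge rendered at y = 30.8; initial points sit on y = 30 (0.8 px off)
  img <- flagbeat:::cpp_render_ridge(c(3, 58), c(30.8, 30.8), 60, 60, 1.3, 1)
  pts <- data.frame(x_px = seq(10, 50, by = 0.5), y_px = 30)
  s <- trace_settings(exclude_head_points = 1)
  out <- refine_normals(pts, img, s, pixel_size_um = 0.65)
  interior <- seq(10, nrow(out) - 10)
  expect_lt(max(abs(out$y_px[interior] - 30.8)), 0.1)
})

test_that("refinement leaves an already-centred point in place", {
  img <- flagbeat:::cpp_render_ridge(c(3, 58), c(30, 30), 60, 60, 1.3, 1)
  pts <- data.frame(x_px = seq(10, 50, by = 0.5), y_px = 30)
  out <- refine_normals(pts, img, trace_settings(exclude_head_points = 1),
                        pixel_size_um = 0.65)
  expect_lt(max(abs(out$y_px - 30)), 1e-6)
})

test_that("fit-width smoothing reduces width variance along the flagellum", {
  p <- tiny_params(noise_sd = 0.08, seed = 5, n_frames = 2)
  tr <- generate_waveform(p)
  m <- render_movie(tr)
  pre <- preprocess_frame(m$frames[, , 1], trace_settings())
  img <- gaussian_blur(pre, 1.0)
  pts <- trace_midline(pre, trace_settings(), head_hint_px = m$head_px)
  raw <- refine_normals(pts, img, trace_settings(smoothing_window_points = 1e-9),
                        0.65)
  smo <- refine_normals(pts, img, trace_settings(), 0.65)
  v_raw <- var(raw$fit_width_um, na.rm = TRUE)
  v_smo <- var(smo$fit_width_um, na.rm = TRUE)
  expect_lt(v_smo, v_raw)
})

test_that("tracing a beating noisy movie is accurate and length-stable", {
  p <- tiny_params(noise_sd = 0.1, seed = 3)
  tr <- generate_waveform(p)
  m <- render_movie(tr)
  t <- suppressWarnings(trace_movie(m))
  expect_length(t$failed, 0)
  err <- trace_error_px(t, tr, m)
  expect_lt(err$rms_px, 1)
  L <- vapply(t$frames, function(f) max(f$arclen_um), numeric(1))
  expect_lt(sd(L) / mean(L), 0.03)
})

test_that("re-tracing a rendered trace reproduces it (idempotence)", {
  p <- tiny_params(noise_sd = 0.05, seed = 9, n_frames = 2)
  tr <- generate_waveform(p)
  m <- render_movie(tr)
  t1 <- trace_movie(m)
  f1 <- t1$frames[[1]]
  # re-render the traced midline as a clean ridge and trace it again
  H <- dim(m$frames)[1]
  W <- dim(m$frames)[2]
  img <- flagbeat:::cpp_render_ridge(f1$x_px, f1$y_px, H, W, 1.3, 1)
  blob <- flagbeat:::cpp_render_ridge(rep(f1$x_px[1], 2), rep(f1$y_px[1], 2),
                                      H, W, 2, 1.5)
  m2 <- sperm_movie(array(pmax(img, blob), dim = c(H, W, 1)),
                    m$frame_rate_hz, m$pixel_size_um)
  f2 <- trace_frame(m2$frames[, , 1], trace_settings(), m$pixel_size_um,
                    head_hint_px = c(f1$x_px[1], f1$y_px[1]))
  L <- max(f1$arclen_um)
  sel <- f2$arclen_um >= 0.05 * L & f2$arclen_um <= 0.9 * L
  d <- flagbeat:::cpp_dist_to_polyline(f2$x_px[sel], f2$y_px[sel],
                                       f1$x_px, f1$y_px)
  expect_lt(sqrt(mean(d^2)), 0.2)
})

test_that("traces round-trip exactly through CSV", {
  p <- tiny_params(noise_sd = 0.05, seed = 13, n_frames = 3)
  m <- render_movie(generate_waveform(p))
  t1 <- trace_movie(m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(t1, path)
  t2 <- read_trace(path, pixel_size_um = m$pixel_size_um,
                   frame_rate_hz = m$frame_rate_hz)
  for (k in seq_along(t1$frames)) {
    expect_identical(t2$frames[[k]]$x_um, t1$frames[[k]]$x_um)
    expect_identical(t2$frames[[k]]$arclen_um, t1$frames[[k]]$arclen_um)
  }
})
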