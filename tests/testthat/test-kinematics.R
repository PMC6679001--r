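test_that("arc-length resampling reproduces lines and circles", {
  cfg <- kinematics_config()
  # straight line at 30 degrees, irregular input spacing
  set.seed(4)
  s_in <- c(0, cumsum(runif(80, 0.4, 1.4)))
  line <- data.frame(x_um = s_in * cos(pi / 6), y_um = s_in * sin(pi / 6),
                     arclen_um = s_in)
  out <- resample_arclength(line, cfg)
  expect_equal(diff(out$arclen_um), rep(1, nrow(out) - 1))
  expect_equal(out$y_um[-1] / out$x_um[-1], rep(tan(pi / 6), nrow(out) - 1),
               tolerance = 1e-9)
  # circle of radius 40: resampled points lie on the circle within 0.01 um
  R <- 40
  s_in <- seq(0, 75, by = 0.8)
  circ <- data.frame(x_um = R * sin(s_in / R), y_um = R * (1 - cos(s_in / R)),
                     arclen_um = s_in)
  out <- resample_arclength(circ, cfg)
  r_err <- abs(sqrt(out$x_um^2 + (out$y_um - R)^2) - R)
  expect_lt(max(r_err), 0.01)
  # grid never exceeds the trace length; remainder dropped
  expect_lte(max(out$arclen_um), max(s_in))
  expect_error(resample_arclength(circ[1, , drop = FALSE], cfg),
               "fewer than 2")
})

test_that("curvature angle obeys the circle identity theta = d_ref / R", {
  cfg <- kinematics_config()
  for (R in c(50, 100, 200)) {
    f <- arc_frame(R)
    ca <- curvature_angle(f, cfg)
    interior <- ca$s_um >= 10 & ca$s_um <= 70
    expect_equal(ca$theta_rad[interior], rep(10 / R, sum(interior)),
                 tolerance = 0.01 * 10 / R)
  }
})

test_that("a straight trace has zero curvature angle everywhere", {
  s <- seq(0, 80, by = 1)
  f <- data.frame(x_um = s * 0.8, y_um = s * 0.6, arclen_um = s)
  ca <- curvature_angle(f, kinematics_config())
  expect_equal(ca$theta_rad[ca$valid], rep(0, sum(ca$valid)),
               tolerance = 1e-12)
})

test_that("mirroring flips the curvature-angle sign; rigid motions leave it unchanged", {
  f <- arc_frame(60)
  cfg <- kinematics_config()
  base <- curvature_angle(f, cfg)
  mirrored <- transform(f, y_um = -y_um)
  flip <- curvature_angle(mirrored, cfg)
  expect_equal(flip$theta_rad[flip$valid], -base$theta_rad[base$valid],
               tolerance = 1e-12)
  phi <- 0.7
  rot <- data.frame(
    x_um = cos(phi) * f$x_um - sin(phi) * f$y_um + 12.3,
    y_um = sin(phi) * f$x_um + cos(phi) * f$y_um - 4.5,
    arclen_um = f$arclen_um)
  same <- curvature_angle(rot, cfg)
  expect_equal(same$theta_rad[same$valid], base$theta_rad[base$valid],
               tolerance = 1e-9)
})

test_that("frames shorter than the reference distance are fully masked", {
  f <- arc_frame(50, length_um = 6)
  expect_warning(ca <- curvature_angle(f, kinematics_config()), "masked")
  expect_false(any(ca$valid))
})

test_that("the assembled field matches ground-truth curvature angles", {
  p <- tiny_params(noise_sd = 0.05, seed = 21)
  tr <- generate_waveform(p)
  m <- render_movie(tr)
  t <- suppressWarnings(trace_movie(m))
  fld <- build_field(t, kinematics_config())
  # align grids: truth is on a 0.5 um grid, field on 1 um
  idx_truth <- match(fld$s_um, tr$s_um)
  ok <- !is.na(idx_truth)
  est <- fld$theta[ok, ]
  nom <- tr$theta_nom[idx_truth[ok], ]
  use <- fld$valid[ok, ] & tr$theta_valid[idx_truth[ok], ]
  expect_gt(cor(est[use], nom[use]), 0.99)
})

test_that("identical frames give identical field columns; failed frames are masked", {
  f <- arc_frame(60)
  t <- as_trace(list(f, f, f))
  fld <- build_field(t)
  expect_equal(fld$theta[, 1], fld$theta[, 2])
  expect_equal(fld$theta[, 1], fld$theta[, 3])
  t2 <- as_trace(list(f, NULL, f))
  fld2 <- build_field(t2)
  expect_false(any(fld2$valid[, 2]))
  a <- asymmetry_profile(fld2)
  b <- asymmetry_profile(build_field(as_trace(list(f, f))))
  expect_equal(a$asym_deg, b$asym_deg, tolerance = 1e-12)
})

test_that("field export converts to degrees exactly and preserves the mask", {
  theta <- matrix(c(pi / 6, -pi / 3, 0, pi), 2, 2)
  fld <- field_from_matrix(theta)
  df <- as.data.frame(fld)
  expect_equal(df$theta, c(30, -60, 0, 180))
  fld$angle_unit <- "radians"
  expect_equal(as.data.frame(fld)$theta, as.vector(theta))
  path <- withr::local_tempfile(fileext = ".csv")
  write_field(fld, path)
  expect_true("theta_rad" %in% names(read.csv(path)))
})
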