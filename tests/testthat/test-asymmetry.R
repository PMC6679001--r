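test_that("a symmetric beat has zero asymmetry on ground truth with integer cycles", {
  p <- waveform_params(beat_freq_hz = 20, frame_rate_hz = 200, n_frames = 400,
                       noise_sd = 0)
  a <- asymmetry_profile(as_curvature_field(generate_waveform(p)))
  expect_lt(max(a$asym_deg, na.rm = TRUE), 1e-6)
})

test_that("a constant curvature offset is recovered as a flat asymmetry profile", {
  p <- waveform_params(beat_freq_hz = 20, n_frames = 400, noise_sd = 0,
                       asym_offset = curvature_offset(0.2))
  a <- asymmetry_profile(as_curvature_field(generate_waveform(p)))
  interior <- a$s_um >= 10 & a$s_um <= 70
  expect_equal(a$asym_deg[interior],
               rep(0.2 * 180 / pi, sum(interior)), tolerance = 0.01)
})

test_that("asymmetry is invariant to sign flips and time reversal", {
  p <- tiny_params(asym_offset = curvature_offset(0.1), noise_sd = 0)
  fld <- as_curvature_field(generate_waveform(p))
  a <- asymmetry_profile(fld)
  neg <- fld
  neg$theta <- -neg$theta
  expect_equal(asymmetry_profile(neg)$asym_deg, a$asym_deg)
  rev_f <- fld
  rev_f$theta <- fld$theta[, rev(seq_len(ncol(fld$theta)))]
  rev_f$valid <- fld$valid[, rev(seq_len(ncol(fld$valid)))]
  expect_equal(asymmetry_profile(rev_f)$asym_deg, a$asym_deg)
})

test_that("positions with under half the frames valid are masked", {
  theta <- matrix(0.1, 3, 10)
  valid <- matrix(TRUE, 3, 10)
  valid[2, 1:6] <- FALSE
  a <- asymmetry_profile(field_from_matrix(theta, valid = valid))
  expect_true(is.na(a$asym_deg[2]))
  expect_false(anyNA(a$asym_deg[c(1, 3)]))
  expect_error(asymmetry_profile(field_from_matrix(theta,
                                                   valid = !valid & FALSE)),
               "empty")
})

test_that("difference curves match hand-computed means and SDs", {
  s <- 0:50
  mk <- function(vals, id, cond) {
    out <- data.frame(s_um = s, asym_deg = vals, n_frames = 400)
    attr(out, "sperm_id") <- id
    attr(out, "condition") <- cond
    class(out) <- c("asymmetry_profile", "data.frame")
    out
  }
  a1 <- mk(rep(1, 51), "s1", "pre")
  a2 <- mk(rep(2, 51), "s2", "pre")
  b1 <- mk(rep(3, 51), "s1", "post")   # +2 for sperm 1
  b2 <- mk(rep(6, 51), "s2", "post")   # +4 for sperm 2
  d <- difference_curve(list(a1, a2), list(b1, b2), paired = TRUE)
  expect_equal(d$delta_mean_deg, rep(3, 51))   # mean of +2, +4
  expect_equal(d$delta_sd_deg, rep(sqrt(2), 51))  # sd of (2, 4)
  # self-difference is exactly zero
  d0 <- difference_curve(list(a1, a2), list(a1, a2), paired = TRUE)
  expect_equal(d0$delta_mean_deg, rep(0, 51))
  expect_equal(d0$delta_sd_deg, rep(0, 51))
  # swapping the groups negates the difference
  dr <- difference_curve(list(b1, b2), list(a1, a2), paired = TRUE)
  expect_equal(dr$delta_mean_deg, -d$delta_mean_deg)
  # unmatched ids fall back to unpaired with a warning
  b3 <- mk(rep(3, 51), "other", "post")
  expect_warning(difference_curve(list(a1, a2), list(b1, b3), paired = TRUE),
                 "unpaired")
})

test_that("pointwise ANOVA rejects degenerate designs", {
  gA <- simulate_asymmetry_profiles(2, condition = "A", seed = 1)
  gB <- simulate_asymmetry_profiles(2, condition = "B", seed = 2)
  expect_error(pointwise_anova(gA[1], gB), "at least 2")
  # identical constant observations: zero within-cell variance
  s <- 0:30
  mk <- function(id, cond) {
    out <- data.frame(s_um = s, asym_deg = 5, n_frames = 400)
    attr(out, "sperm_id") <- id
    attr(out, "condition") <- cond
    class(out) <- c("asymmetry_profile", "data.frame")
    out
  }
  expect_error(
    pointwise_anova(list(mk("1", "A"), mk("2", "A")),
                    list(mk("3", "B"), mk("4", "B"))),
    "zero within-cell variance")
})

test_that("significant regions are maximal runs carrying their minimum p", {
  s <- 1:20
  p <- rep(0.5, 20)
  p[4:7] <- c(0.04, 0.001, 0.03, 0.049)
  p[12] <- 0.01
  p[15] <- NA
  reg <- significant_regions(s, p, alpha = 0.05)
  expect_equal(reg$start_um, c(4, 12))
  expect_equal(reg$end_um, c(7, 12))
  expect_equal(reg$min_p, c(0.001, 0.01))
  # exhaustive property: every region's min_p equals min over members,
  # and positions adjacent to regions are non-significant
  for (i in seq_len(nrow(reg))) {
    members <- s >= reg$start_um[i] & s <= reg$end_um[i]
    expect_equal(reg$min_p[i], min(p[members]))
    expect_true(all(p[members] < 0.05))
  }
  expect_equal(nrow(significant_regions(s, rep(0.9, 20))), 0)
})

test_that("an injected group difference is recovered within 2 SEM", {
  n <- 10
  gA <- simulate_asymmetry_profiles(n, base_offset = 0.1, condition = "A",
                                    seed = 31)
  gB <- simulate_asymmetry_profiles(n, base_offset = 0.15, condition = "B",
                                    seed = 32)
  d <- difference_curve(gA, gB, paired = FALSE)
  interior <- d$s_um >= 10 & d$s_um <= 70
  inj <- (0.15 - 0.1) * 180 / pi
  sem <- mean(d$delta_sd_deg[interior]) / sqrt(n)
  expect_lt(abs(mean(d$delta_mean_deg[interior]) - inj), 2 * sem)
})

test_that("condition comparison combines curve, p-values and regions coherently", {
  eff <- function(s) 0.08 + 0.2 * (s < 25)
  gA <- simulate_asymmetry_profiles(6, condition = "pre", seed = 41)
  gB <- simulate_asymmetry_profiles(6, base_offset = eff, condition = "post",
                                    seed = 42)
  cmp <- compare_conditions(gA, gB, paired = FALSE,
                            labels = c("pre", "post"))
  expect_s3_class(cmp, "condition_comparison")
  expect_true(all(cmp$curve$significant[cmp$curve$p < 0.05], na.rm = TRUE))
  expect_gt(nrow(cmp$regions), 0)
  expect_lt(cmp$regions$start_um[1], 25)
})
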