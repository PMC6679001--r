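test_that("frequency bins are multiples of frame_rate / window", {
  sp <- power_spectrum(rnorm(400), 200, window = 400)
  expect_equal(sp$freq, seq(0, 100, by = 0.5))
})

test_that("a bin-centred sine concentrates all power in its bin", {
  t <- (0:399) / 200
  sp <- power_spectrum(sin(2 * pi * 20 * t), 200)
  peak <- which(sp$freq == 20)
  expect_equal(sp$freq[which.max(sp$power)], 20)
  expect_lt(sum(sp$power[-peak]) / sp$power[peak], 1e-6)
})

test_that("a constant series has an all-zero spectrum after mean subtraction", {
  sp <- power_spectrum(rep(3.7, 400), 200)
  expect_equal(sp$power, rep(0, 201), tolerance = 1e-20)
  expect_true(is.na(local_frequency(sp)$f1_hz))
})

test_that("short series fail unless explicitly allowed", {
  expect_error(power_spectrum(rnorm(100), 200), "window")
  sp <- power_spectrum(sin(2 * pi * 20 * (0:99) / 200), 200,
                       allow_short = TRUE)
  expect_equal(sp$freq[which.max(sp$power)], 20)
})

test_that("two tones merge to the mean of f1 and f2 by the (f1+f2)/2 rule", {
  t <- (0:399) / 200
  two <- function(a1, a2) sin(2 * pi * 20 * t) * a1 + sin(2 * pi * 24 * t) * a2
  lf <- local_frequency(power_spectrum(two(1, 0.5), 200))
  expect_equal(lf$f1_hz, 20)
  expect_equal(lf$f2_hz, 24)
  expect_equal(lf$f_local_hz, 22)
  # swapping amplitudes swaps f1/f2 but not the merged value
  lf2 <- local_frequency(power_spectrum(two(0.5, 1), 200))
  expect_equal(lf2$f1_hz, 24)
  expect_equal(lf2$f2_hz, 20)
  expect_equal(lf2$f_local_hz, 22)
})

test_that("without a second peak f2 falls back to f1", {
  t <- (0:399) / 200
  lf <- local_frequency(power_spectrum(sin(2 * pi * 20 * t), 200))
  expect_equal(lf$f2_hz, lf$f1_hz)
  expect_equal(lf$f_local_hz, 20)
})

test_that("harmonic exclusion removes f2 = 2 f1 when requested", {
  t <- (0:399) / 200
  sig <- sin(2 * pi * 15 * t) + 0.4 * sin(2 * pi * 30 * t) +
    0.3 * sin(2 * pi * 17 * t)
  sp <- power_spectrum(sig, 200)
  expect_equal(local_frequency(sp)$f2_hz, 30)
  expect_equal(local_frequency(sp, exclude_harmonics = TRUE)$f2_hz, 17)
})

test_that("mean subtraction prevents the DC bin from winning", {
  t <- (0:399) / 200
  sig <- 50 + 0.01 * sin(2 * pi * 10 * t)
  lf <- local_frequency(power_spectrum(sig, 200))
  expect_equal(lf$f1_hz, 10)
})

test_that("f_local is invariant to amplitude scaling of the angle series", {
  p <- tiny_params(n_frames = 400, noise_sd = 0)
  fld <- as_curvature_field(generate_waveform(p))
  fp1 <- frequency_profile(fld)
  fld$theta <- fld$theta * 7.3
  fp2 <- frequency_profile(fld)
  expect_equal(fp1$f_local_hz, fp2$f_local_hz)
})

test_that("masked samples are imputed below the 5% threshold and skipped above", {
  t <- (0:399) / 200
  series <- sin(2 * pi * 20 * t)
  series[sample.int(400, 10)] <- NA  # 2.5% masked
  sp <- power_spectrum(series, 200)
  expect_equal(sp$freq[which.max(sp$power)], 20)
  series[sample.int(400, 40)] <- NA  # > 5% masked
  expect_null(power_spectrum(series, 200))
})

test_that("sperm frequency averages local frequencies over 15-60 um only", {
  s <- 0:80
  f_local <- ifelse(s < 40, 18, 22)
  prof <- data.frame(s_um = s, f_local_hz = f_local)
  # independent brute-force mean over the closed window
  expected <- mean(f_local[s >= 15 & s <= 60])
  expect_equal(sperm_frequency(prof), expected)
  # constant profile gives the constant
  expect_equal(sperm_frequency(data.frame(s_um = s, f_local_hz = 20)), 20)
  # values outside the window are irrelevant
  prof2 <- prof
  prof2$f_local_hz[s < 15 | s > 60] <- NA
  expect_equal(sperm_frequency(prof2), expected)
  prof3 <- prof
  prof3$f_local_hz[] <- NA
  expect_error(sperm_frequency(prof3), "no valid positions")
})
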