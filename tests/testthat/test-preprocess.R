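test_that("preprocessing removes a constant background completely", {
  img <- matrix(0.4, 40, 50)
  out <- preprocess_frame(img, trace_settings())
  expect_equal(out, matrix(0, 40, 50), tolerance = 1e-12)
})

test_that("a narrow ridge on constant background survives background removal", {
  img <- matrix(0.3, 60, 60)
  ridge <- flagbeat:::cpp_render_ridge(c(5, 55), c(30, 30), 60, 60, 1.0, 1.0)
  out <- preprocess_frame(img + ridge, trace_settings())
  blurred_ridge <- gaussian_blur(ridge, 0.5)
  peak <- max(blurred_ridge)
  # ridge peak preserved within 10%
  expect_gt(max(out[, 20:40]), 0.9 * peak)
  # background (rows far from the ridge) removed to < 1% of the ridge peak
  expect_lt(max(out[c(1:15, 45:60), ]), 0.01 * peak)
})

test_that("blurring a delta impulse reproduces the closed-form Gaussian kernel", {
  img <- matrix(0, 21, 21)
  img[11, 11] <- 1
  out <- gaussian_blur(img, 0.5)
  r <- max(1, ceiling(3 * 0.5))
  k <- exp(-((-r):r)^2 / (2 * 0.5^2))
  k <- k / sum(k)
  expected <- matrix(0, 21, 21)
  expected[11 + (-r:r), 11 + (-r:r)] <- outer(k, k)
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("non-2-D input to preprocessing is rejected", {
  expect_error(preprocess_frame(array(0, c(4, 4, 2))), "2-D")
  expect_error(preprocess_frame(1:10), "2-D")
})

test_that("triangle threshold maximises the point-to-line distance (exhaustive oracle)", {
  # background peak at bin 10, convex decay to zero at bin 100
  counts <- numeric(120)
  counts[1:9] <- round(seq(2, 60, length.out = 9))
  counts[10:100] <- round(1000 * ((100 - (10:100)) / 90)^2)
  counts[10] <- 1000
  tt <- triangle_threshold(counts)
  # independent brute-force oracle: distance of each (bin, count) point to
  # the line from the peak to the farthest non-empty bin, axes normalised
  peak <- which.max(counts)
  nz <- which(counts > 0)
  far <- max(nz)
  p1 <- c(0, 1)
  p2 <- c(1, counts[far] / counts[peak])
  best <- NA
  best_d <- -1
  for (i in (peak + 1):(far - 1)) {
    pt <- c((i - peak) / (far - peak), counts[i] / counts[peak])
    v <- p2 - p1
    w <- pt - p1
    d <- sqrt(sum(w^2) - (sum(w * v))^2 / sum(v^2))
    if (d > best_d) {
      best_d <- d
      best <- i
    }
  }
  expect_equal(tt$bin, best)
  expect_false(tt$degenerate)
})

test_that("degenerate and invalid histograms are handled explicitly", {
  expect_error(triangle_threshold(numeric(0)), "empty")
  expect_error(triangle_threshold(c(0, 0, 0)), "empty")
  expect_error(triangle_threshold(rep(5, 10)), "flat")
  two <- triangle_threshold(c(10, 3))
  expect_true(two$degenerate)
  expect_equal(two$bin, 1)
})

test_that("trailing empty bins do not change the threshold", {
  counts <- c(rep(0, 4), 500, round(500 * exp(-(1:50) / 6)))
  a <- triangle_threshold(counts)
  b <- triangle_threshold(c(counts, rep(0, 200)))
  expect_equal(a$bin, b$bin)
})
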