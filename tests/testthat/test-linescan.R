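# Bright-fringe preprocessing and per-image moment extraction.

test_that("time-averaged profile equals the brute-force per-row mean", {
  img <- linescan_image(matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE),
                        pixel_um = 0.2, line_ms = 2)
  expect_equal(time_average_profile(img), c(2, 5))

  set.seed(4)
  m <- matrix(rpois(40 * 25, 8), 40, 25)
  img <- linescan_image(m, 0.2, 2)
  brute <- apply(m, 1, function(r) sum(r) / length(r))
  expect_equal(time_average_profile(img), brute, tolerance = 1e-12)

  one_col <- linescan_image(matrix(1, 3, 1), 0.2, 2)
  expect_error(time_average_profile(one_col), "2 time columns")
})

test_that("bright-fringe threshold separates a bimodal profile at k = 0", {
  prof <- c(rep(100, 70), rep(10, 30))
  mask <- detect_bright_fringes(prof, k = 0)
  expect_equal(mask$mu, 73)
  expect_identical(mask$bright, prof >= 73)
  expect_equal(sum(mask$bright), 70)
  expect_false(mask$failed)

  uni <- detect_bright_fringes(rep(5, 10), k = 0)
  expect_true(all(uni$bright))

  expect_warning(hi <- detect_bright_fringes(prof, k = 1e6), "no bright")
  expect_true(hi$failed)
  expect_false(any(hi$bright))
})

test_that("pooled bright-fringe moments match enumeration", {
  m <- rbind(c(0, 2), c(100, 100), c(4, 6))
  img <- linescan_image(m, 0.2, 2, annotations = list(image_id = "t"))
  mask <- structure(list(bright = c(TRUE, FALSE, TRUE), k = 0, mu = 0,
                         sigma = 0, failed = FALSE), class = "fringe_mask")
  ms <- bright_moments(img, mask)
  expect_equal(ms$mean_F, 3)
  expect_equal(ms$var_F, 20 / 3)           # sample convention
  expect_equal(bright_moments(img, mask, "population")$var_F, 5)
  expect_equal(ms$n_pixels, 4L)

  const <- linescan_image(matrix(7, 4, 4), 0.2, 2)
  cmask <- detect_bright_fringes(time_average_profile(const))
  expect_equal(bright_moments(const, cmask)$var_F, 0)

  empty <- structure(list(bright = rep(FALSE, 3), k = 0, mu = 0, sigma = 0,
                          failed = TRUE), class = "fringe_mask")
  expect_error(bright_moments(img, empty), "no bright rows")
})

test_that("moments of a model-drawn image agree with the closed forms", {
  p <- ref_params()
  lam <- matrix(p$occupancy, 50, 400)
  img <- synthesize_image(lam, p, seed = 21)
  ms <- extract_moments(img)
  n <- ms$n_pixels
  expect_equal(n, 50L * 400L)  # stationary image: no masking triggered
  se_mean <- sqrt(variance_fluorescence(p) / n)
  expect_lt(abs(ms$mean_F - mean_fluorescence(p)), 3 * se_mean)
  se_var <- variance_fluorescence(p) * sqrt(2 / n) * 2  # conservative
  expect_lt(abs(ms$var_F - variance_fluorescence(p)), 3 * se_var)
})

test_that("baseline normalization is unity when stationary and tracks scaling", {
  p <- ref_params()
  lam <- matrix(p$occupancy, 30, 300)
  img <- synthesize_image(lam, p, seed = 31)
  rat <- f_over_f0(img, baseline = 1:300)
  rm <- rowMeans(rat)
  se <- sqrt(variance_fluorescence(p) / 300) / mean_fluorescence(p)
  expect_true(all(abs(rm - 1) < 4 * se))

  # deterministic doubling after the baseline window
  m <- cbind(matrix(5, 4, 10), matrix(10, 4, 10))
  img2 <- linescan_image(m, 0.2, 2)
  rat2 <- f_over_f0(img2, baseline = 1:10)
  expect_equal(unname(rat2[, 11]), rep(2, 4))

  m[2, ] <- 0
  img3 <- linescan_image(m, 0.2, 2)
  expect_warning(rat3 <- f_over_f0(img3, baseline = 1:10), "zero baseline")
  expect_equal(attr(rat3, "zero_baseline_rows"), 2L)
  expect_true(all(is.na(rat3[2, ])))
})
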