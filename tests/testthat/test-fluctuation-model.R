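# Generative pixel model: closed-form moments, sampler, and the three
# variance-versus-mean curve reductions.

test_that("closed-form moments match their definitions and limits", {
  p <- ref_params()
  expect_equal(mean_fluorescence(p), 6.5)
  expect_equal(variance_fluorescence(p), 14.03)

  # equal brightnesses: occupancy drops out of the mean by symmetry
  for (lam in c(0, 0.3, 1)) {
    pe <- fluct_params(1.5, 0.2, 0.2, lam, 50)
    expect_equal(mean_fluorescence(pe), 1.5 * 50 * 0.2)
  }
  # dark limit
  expect_equal(mean_fluorescence(fluct_params(2, 0.1, 0, 0, 100)), 0)
  # zero-brightness limit of the variance is handled by eps_bound > 0
  # validation; instead check the photon-shot lower bound everywhere
  for (p in random_params(25)) {
    slack <- variance_fluorescence(p) - p$gain * mean_fluorescence(p)
    expect_gte(slack, 0)
  }
})

test_that("sampled pixels converge to the closed-form moments", {
  p <- ref_params()
  n <- 2e5
  x <- sample_pixel(p, n, seed = 7)
  se_mean <- stats::sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 6.5), 3 * se_mean)
  se_var <- sqrt((mean((x - mean(x))^4) - stats::var(x)^2) / n)
  expect_lt(abs(stats::var(x) - 14.03), 3 * se_var)
})

test_that("sampler is deterministic under a seed and respects the gain grid", {
  p <- ref_params()
  expect_identical(sample_pixel(p, 100, seed = 3), sample_pixel(p, 100, seed = 3))
  x <- sample_pixel(p, 500, seed = 5)
  expect_true(all(x >= 0))
  expect_true(all(abs(x / p$gain - round(x / p$gain)) < 1e-12))
  dark <- fluct_params(2, 0.1, 0, 0, 100)
  expect_true(all(sample_pixel(dark, 200, seed = 1) == 0))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(fluct_params(0, 0.1, 0.01, 0.5, 10), "gain")
  expect_error(fluct_params(1, 0.1, 0.2, 0.5, 10), "eps_free")
  expect_error(fluct_params(1, 0.1, 0.01, 1.5, 10), "occupancy")
  expect_error(fluct_params(1, 0.1, 0.01, 0.5, -1), "mean_molecules")
  expect_error(fluct_params(1, NA, 0.01, 0.5, 10), "finite")
})

test_that("the three curve forms reproduce the exact variance under their substitutions", {
  for (p in random_params(30, seed = 11)) {
    f <- mean_fluorescence(p)
    v <- variance_fluorescence(p)
    r <- brightness_ratio(p)

    s1 <- type1_slope(p$gain, p$eps_bound, r, p$occupancy)
    expect_lt(abs(s1 * f - v) / v, 1e-12)

    co <- type2_coefficients(p$gain, p$mean_molecules, p$occupancy, r)
    expect_lt(abs(co$a1 * f + co$a2 * f^2 - v) / v, 1e-12)

    l3 <- type3_line(p$gain, p$eps_bound, p$eps_free, p$mean_molecules)
    expect_lt(abs(l3$slope * f + l3$intercept - v) / v, 1e-12)
  }
})

test_that("curve-form reductions and degenerate inputs behave as derived", {
  # region-sweep slope tends to the gain as the brightness vanishes,
  # monotonically
  eps <- 10^seq(-1, -6, by = -1)
  slopes <- vapply(eps, function(e) type1_slope(2, e, 0.1, 0.3), numeric(1))
  expect_true(all(diff(slopes) < 0))
  expect_equal(slopes[length(slopes)], 2, tolerance = 1e-6)
  expect_gte(min(slopes), 2)
  # r = 1 collapses the bracket
  expect_equal(type1_slope(2, 0.3, 1, 0.7), 2 * (1 + 0.3))
  expect_error(type1_slope(2, 0.3, 0, 0), "degenerate")

  co <- type2_coefficients(2, 80, 0.4, 1)
  expect_equal(co$a2, 1 / 80)
  co0 <- type2_coefficients(2, 80, 0.4, 0)
  expect_equal(co0$a2, 1 / (80 * 0.4))
  expect_equal(co$fstar, co$a1 / co$a2)
  expect_error(type2_coefficients(2, 80, 0, 0), "degenerate")

  l3 <- type3_line(2, 0.3, 0, 100)
  expect_equal(l3$slope, 2 * 1.3)
  expect_equal(l3$intercept, 0)
  expect_lte(type3_line(2, 0.3, 0.02, 100)$intercept, 0)
})

test_that("parameter sets round-trip through flat key-value files", {
  p <- ref_params()
  f <- tempfile(fileext = ".json")
  write_fluct_params(p, f)
  expect_equal(read_fluct_params(f), p)
  fy <- tempfile(fileext = ".yaml")
  write_fluct_params(p, fy)
  expect_equal(read_fluct_params(fy), p)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(gain = 1), bad, auto_unbox = TRUE)
  expect_error(read_fluct_params(bad), "misses")
})
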