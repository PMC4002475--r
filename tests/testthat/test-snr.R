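# Signal-to-noise computation, parameter scans, dye translation and
# equivalence classification.

test_that("image SN is zero for a constant image and rejects zero noise", {
  p <- ref_params()
  img <- linescan_image(matrix(5, 10, 10), 0.2, 2)
  expect_equal(snr_image(img, p, lambda_basal = 0.1)$sn, 0)
})

test_that("image SN is invariant to the detector gain in expectation", {
  lam <- matrix(0.1, 30, 200)
  lam[15, 90:110] <- 0.35
  sn_at_gain <- function(g) {
    p <- fluct_params(g, 0.2, 0.01, 0.1, 150)
    mean(vapply(1:8, function(sd)
      snr_image(synthesize_image(lam, p, lambda_basal = 0.1, seed = sd),
                p, lambda_basal = 0.1)$sn, numeric(1)))
  }
  s1 <- sn_at_gain(1)
  s4 <- sn_at_gain(4)
  expect_lt(abs(s1 - s4) / s1, 0.1)
})

test_that("analytic SN has the exact structural properties", {
  p <- fluct_params(2, 0.2, 0.01, 0.05, 100)
  expect_equal(snr_analytic(p, lambda_peak = 0.05), 0)
  # exact gain invariance
  p5 <- update_fluct_params(p, gain = 5)
  expect_equal(snr_analytic(p, 0.2), snr_analytic(p5, 0.2), tolerance = 1e-14)
  # sqrt(N) scaling
  p2 <- update_fluct_params(p, mean_molecules = 250)
  expect_equal(snr_analytic(p2, 0.2) / snr_analytic(p, 0.2), sqrt(2.5),
               tolerance = 1e-12)
  # increasing in the peak occupancy
  sn <- vapply(seq(0.06, 0.9, length.out = 20),
               function(lp) snr_analytic(p, lp), numeric(1))
  expect_true(all(diff(sn) > 0))
  expect_warning(snr_analytic(p, 0.01), "below basal")
})

test_that("the small-brightness form converges to the exact SN", {
  for (eb in c(0.02, 0.05, 0.1, 0.2)) {
    p <- fluct_params(1, eb, 0.05 * eb, 0.1, 100)
    full <- snr_analytic(p, 0.3)
    simp <- snr_analytic(p, 0.3, simplified = TRUE)
    expect_lt(abs(simp - full) / full, eb / 2 + 1e-12)
  }
})

test_that("the SN surface reduces to the analytic value and is monotone", {
  p <- fluct_params(1.5, 0.1, 0.007, 0.1, 100)
  one <- snr_surface(p, lambda_peak = 0.2)
  expect_equal(one$sn, snr_analytic(p, 0.2))

  surf <- snr_surface(p, n_grid = c(50, 100, 200, 400),
                      intensity_grid = c(0.5, 1, 2, 4),
                      lambda_basal_grid = c(0.05, 0.1, 0.2, 0.4),
                      lambda_peak = 0.5)
  # increasing in N at fixed (I, lambda_b)
  for (i in unique(surf$intensity_rel)) for (l in unique(surf$lambda_basal)) {
    s <- surf$sn[surf$intensity_rel == i & surf$lambda_basal == l]
    expect_true(all(diff(s) > 0))
  }
  # increasing in intensity, decreasing in basal occupancy
  for (n in unique(surf$mean_molecules)) {
    s_i <- surf$sn[surf$mean_molecules == n & surf$lambda_basal == 0.05]
    expect_true(all(diff(s_i) > 0))
    s_l <- surf$sn[surf$mean_molecules == n & surf$intensity_rel == 1]
    expect_true(all(diff(s_l) < 0))
  }
  # SN / sqrt(N) constant along the N axis
  s <- surf[surf$intensity_rel == 1 & surf$lambda_basal == 0.1, ]
  expect_equal(stats::sd(s$sn / sqrt(s$mean_molecules)), 0, tolerance = 1e-12)
})

test_that("occupancy translates between dyes through the free-Ca peak", {
  expect_equal(translate_occupancy_between_dyes(0.5, 0.75, 0.375), 2 / 3)
  expect_equal(translate_occupancy_between_dyes(0.3, 1.2, 1.2), 0.3)
  expect_lt(translate_occupancy_between_dyes(0.5, 0.75, 1e6), 1e-5)
  kd <- c(0.2, 0.5, 1, 2)
  out <- vapply(kd, function(k)
    translate_occupancy_between_dyes(0.4, 0.75, k), numeric(1))
  expect_true(all(diff(out) < 0))
  expect_error(translate_occupancy_between_dyes(1, 0.75, 0.5), "strictly")
})

test_that("equivalence classification groups by relative SN difference", {
  rep1 <- classify_equivalence(c(set_i = 2.5, set_ii = 1.5, set_iii = 2.1),
                               threshold = 0.25)
  expect_length(rep1$classes, 2)
  grp <- split(rep1$settings$setting, rep1$settings$class)
  expect_true(any(vapply(grp, function(g)
    setequal(g, c("set_i", "set_iii")), logical(1))))
  expect_true(any(vapply(grp, function(g)
    setequal(g, "set_ii"), logical(1))))

  same <- classify_equivalence(c(a = 2, b = 2, c = 2))
  expect_length(same$classes, 1)

  strict <- classify_equivalence(c(a = 1, b = 1, c = 1.01), threshold = 0)
  expect_length(strict$classes, 2)

  # single linkage chains through intermediates
  chain <- classify_equivalence(c(a = 1, b = 1.2, c = 1.44), threshold = 0.18)
  expect_length(chain$classes, 1)
})
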