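# Type I/II/III fits and the consolidated calibration.

test_that("noise-free ensembles are fitted exactly", {
  base <- fluct_params(gain = 2, eps_bound = 1e-4, eps_free = 1e-6,
                       occupancy = 0.1, mean_molecules = 100)
  # tiny brightness: slope is A to within eps_b-order corrections
  e1 <- exact_ensemble("I", base, seq(50, 200, length.out = 10))
  # noise-free input: lm warns about a perfect fit, which is the point
  f1 <- suppressWarnings(fit_type1(e1))
  expect_equal(f1$A_hat, 2, tolerance = 1e-3)
  expect_lt(abs(f1$intercept), 1e-8)
  expect_false(f1$intercept_warn)

  base2 <- fluct_params(2, 0.2, 0.01, 0.1, 100)
  e2 <- exact_ensemble("II", base2, seq(0.2, 2, length.out = 9))
  f2 <- suppressWarnings(fit_type2(e2))
  co <- type2_coefficients(2, 100, 0.1, 0.05)
  expect_equal(f2$a1, co$a1, tolerance = 1e-9)
  expect_equal(f2$a2, co$a2, tolerance = 1e-9)
  expect_equal(f2$N_hat(0.1, 0.05), 100, tolerance = 1e-9)
  expect_equal(f2$N_hat(1, 1), 1 / f2$a2)

  # occupancy sweep with eps_f = 0: zero intercept, slope A (1 + eps_b)
  base3 <- fluct_params(2, 0.2, 0, 0.5, 100)
  e3 <- exact_ensemble("III", base3, seq(0.1, 0.9, length.out = 9))
  f3 <- fit_type3(e3, gain = 2, ratio = 0)
  expect_equal(f3$slope_high, 2 * 1.2, tolerance = 1e-9)
  expect_equal(f3$eps_b_hat, 0.2, tolerance = 1e-9)
})

test_that("noise-free occupancy inversion recovers the per-point truth", {
  # oracle: moments built forward from the closed forms; the inversion
  # must return the exact occupancy used to build them
  base <- fluct_params(1.5, 0.2, 0.01, 0.5, 100)
  lam <- seq(0.05, 0.95, length.out = 12)
  e <- exact_ensemble("III", base, lam)
  inv <- invert_type3_occupancy(e$mean_F, e$var_F, 1.5, 0.2, 0.01)
  expect_true(all(inv$valid))
  expect_equal(inv$lambda, lam, tolerance = 1e-10)

  # full fit on noise-free data: internal estimates are close but carry
  # the origin-constrained high-F bias, so only percent-level agreement
  f <- fit_type3(e, gain = 1.5, ratio = 0.05)
  expect_equal(f$eps_b_hat, 0.2, tolerance = 0.05)
  pts <- f$lambda_points[f$lambda_points$valid, ]
  expect_equal(pts$lambda, lam[seq_len(nrow(pts))], tolerance = 0.1)
})

test_that("parameters are recovered from sampled ensembles", {
  truth <- fluct_params(gain = 1.5, eps_bound = 0.2, eps_free = 0.01,
                        occupancy = 0.1, mean_molecules = 100)
  e1 <- gen_moment_ensemble(fixture_spec("I", truth, 84, 2e4, seed = 101))
  e2 <- gen_moment_ensemble(fixture_spec("II", truth, 21, 2e4, seed = 102))
  e3 <- gen_moment_ensemble(fixture_spec("III", truth, 55, 2e4, seed = 103))
  cal <- calibrate(e1, e2, e3, ratio = 0.05)
  expect_equal(cal$gain, 1.5, tolerance = 0.05)
  expect_equal(cal$eps_bound, 0.2, tolerance = 0.15)
  expect_true(isTRUE(cal$flags$gain_consistency$ok))
  n2 <- cal$fits$type2$N_hat(0.1, 0.05)
  expect_equal(n2, 100, tolerance = 0.3)
  # recovered basal occupancies on the low-F subset track the truth
  pts <- cal$fits$type3$lambda_points
  tl <- e3$true_lambda[order(e3$mean_F)][seq_len(nrow(pts))]
  ok <- pts$valid
  expect_gt(mean(ok), 0.6)
  expect_equal(stats::median(pts$lambda[ok]), stats::median(tl[ok]),
               tolerance = 0.3)
})

test_that("fits are order-invariant and scale equivariantly with the gain", {
  truth <- fluct_params(1.5, 0.1, 0.005, 0.1, 100)
  e1 <- gen_moment_ensemble(fixture_spec("I", truth, 30, 5e3, seed = 7))
  shuffled <- moment_ensemble(e1[sample(nrow(e1)), ], type = "I")
  expect_equal(fit_type1(e1)$A_hat, fit_type1(shuffled)$A_hat)

  scaled <- e1
  scaled$mean_F <- scaled$mean_F * 3
  scaled$var_F <- scaled$var_F * 9
  scaled <- moment_ensemble(scaled, type = "I")
  expect_equal(fit_type1(scaled)$A_hat, 3 * fit_type1(e1)$A_hat,
               tolerance = 1e-9)
})

test_that("diagnostic flags fire on pathological or inconsistent input", {
  truth <- fluct_params(1.5, 0.02, 0.001, 0.1, 1e5)
  # huge N, small eps: quadratic term unidentifiable -> linear regime
  e2 <- gen_moment_ensemble(fixture_spec("II", truth, 21, 5e3, seed = 9))
  f2 <- fit_type2(e2)
  expect_true(f2$linear_regime)

  e1 <- gen_moment_ensemble(fixture_spec("I",
          fluct_params(1.5, 0.1, 0.005, 0.1, 100), 30, 5e3, seed = 10))
  cal <- calibrate(e1, e2, ratio = 0.05)
  expect_true(!is.null(cal$flags$linear_regime))
  expect_match(cal$flags$linear_regime$note, "nonlinear part")

  # grossly inconsistent gain estimates between Type I and Type II
  fake2 <- e2
  fake2$var_F <- 6 * fake2$mean_F          # a1 = 6 vs A ~ 1.5
  fake2 <- moment_ensemble(fake2, type = "II")
  cal2 <- suppressWarnings(calibrate(e1, fake2, ratio = 0.05))
  expect_false(cal2$flags$gain_consistency$ok)

  # no Type III: occupancy-dependent parameter sets are refused
  expect_true(is.na(cal$eps_bound))
  expect_error(as_fluct_params(cal, 0.1, 100), "Type III")
})

test_that("molecule-number ratios across sets track dye concentrations", {
  mk <- function(n_mol, seed) {
    truth <- fluct_params(1.5, 0.2, 0.01, 0.1, n_mol)
    e1 <- gen_moment_ensemble(fixture_spec("I", truth, 30, 1e4, seed = seed))
    e3 <- gen_moment_ensemble(fixture_spec("III", truth, 30, 1e4,
                                           seed = seed + 1))
    calibrate(e1, type3 = e3, ratio = 0.05)
  }
  cals <- list(low = mk(100, 301), high = mk(250, 303))
  cmp <- consistency_across_sets(cals, c(low = 36, high = 90))
  expect_true(all(cmp$ok))
})
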