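# Reaction-diffusion solver: equilibrium, conservation, source statistics
# and convergence.  The quantitative Green's-function and
# Richardson-convergence checks run in the acceptance suite at full
# resolution; here they run in inexpensive versions.

test_that("equilibrium initialization solves the binding steady state", {
  expect_equal(equilibrium_bound_fraction(fluo4_species(), 0.1),
               0.1 / (0.1 + 0.75))       # Kd = 180/240 = 0.75 uM
  expect_equal(equilibrium_bound_fraction(egta_species(), 0.1), 0.4)
  expect_equal(equilibrium_bound_fraction(fluo4_species(), 0), 0)

  cfg <- gen_puff_scenario("i", source = NULL, t_end_ms = 1)
  st <- equilibrium_init(cfg)
  expect_true(all(st$ca == 0.1))
  for (j in seq_along(cfg$species)) {
    sp <- cfg$species[[j]]
    rate <- sp$kon * 0.1 * (sp$total - st$bound[[j]]) - sp$koff * st$bound[[j]]
    expect_lt(max(abs(rate)), 1e-10)
  }
})

test_that("the equilibrium state is a fixed point of the dynamics", {
  cfg <- gen_puff_scenario("i", source = NULL, t_end_ms = 1, dt_ms = 0.01)
  sol <- rd_run(cfg)   # 100 steps, no source
  st0 <- equilibrium_init(cfg)
  expect_lt(max(abs(sol$ca[nrow(sol$ca), ] - st0$ca) / st0$ca), 1e-9)
  for (j in seq_along(sol$bound)) {
    b <- sol$bound[[j]]
    expect_lt(max(abs(b[nrow(b), ] - st0$bound[[j]]) / st0$bound[[j]]), 1e-9)
  }
  mb <- mass_balance_report(sol)
  expect_lt(mb$max_rel_imbalance, 1e-6)
})

test_that("channel open durations are exponential with the configured mean", {
  src <- puff_source()
  d <- sample_open_durations(src, seed = 5)
  expect_length(d, 6L)
  expect_true(all(d > 0))
  expect_identical(d, sample_open_durations(src, seed = 5))

  set.seed(6)
  many <- stats::rexp(1e4, rate = 1 / src$mean_open_ms)
  se <- src$mean_open_ms / sqrt(1e4)
  expect_lt(abs(mean(many) - 20), 3 * se)
  expect_error(sample_open_durations(constant_source(1e5)), "stochastic")
})

test_that("mass is conserved during a sourced, pumped, buffered run", {
  cfg <- gen_puff_scenario("i", t_end_ms = 5, dt_ms = 0.02,
                           source = puff_source(flux_ions_per_s = 3e5))
  sol <- rd_run(cfg, closings = c(4, 8, 2, 6, 3, 5))
  mb <- mass_balance_report(sol)
  injected <- max(sol$injected_ions)
  expect_gt(injected, 0)
  drift <- max(abs(mb$balance$total_ions - mb$balance$expected_ions))
  expect_lt(drift, 0.01 * injected)
  expect_true(all(mb$species_min > 0))    # bound never exceeds total
  # dye bookkeeping: free + bound = total by formulation; bound stays
  # within [0, total] at every node and frame
  expect_true(all(sol$bound$dye >= 0))
})

test_that("a constant point source approaches the free-space diffusion profile", {
  sigma <- 5e4
  cfg <- rd_config(radius_um = 20, dr_um = 0.1, dt_ms = 0.2, t_end_ms = 200,
                   ca_basal = 0.1, species = list(), pump_koff = 0,
                   source = constant_source(sigma))
  sol <- rd_run(cfg, record_every = 500)
  r <- sol$r_um
  x <- r / sqrt(4 * 220 * 0.2)
  oracle <- 0.1 + sigma / (602.214076 * 4 * pi * 220 * r) *
    (2 * stats::pnorm(-sqrt(2) * x))      # erfc via the normal cdf
  num <- sol$ca[nrow(sol$ca), ]
  band <- r >= 0.3 & r <= 2
  expect_lt(max(abs(num - oracle)[band] / oracle[band]), 0.05)
})

test_that("halving the grid reduces the error about fourfold", {
  run_at <- function(dr) {
    cfg <- rd_config(radius_um = 5, dr_um = dr, dt_ms = 0.005, t_end_ms = 1,
                     ca_basal = 0.1, species = list(fluo4_species()),
                     source = constant_source(1e6))
    sol <- rd_run(cfg, record_every = 1e9)
    list(r = sol$r_um, ca = sol$ca[nrow(sol$ca), ])
  }
  s <- lapply(c(0.2, 0.1, 0.05), run_at)
  pts <- seq(0.4, 3, by = 0.1)
  at <- function(x) stats::approx(x$r, x$ca, pts)$y
  e12 <- max(abs(at(s[[1]]) - at(s[[2]])))
  e23 <- max(abs(at(s[[2]]) - at(s[[3]])))
  expect_gt(e12 / e23, 2.5)
  expect_lt(e12 / e23, 6)
})

test_that("invalid configurations are rejected", {
  expect_error(gen_puff_scenario("iv"), "unknown set")
  expect_error(rd_config(radius_um = 1), "radius")
  expect_error(rd_config(species = list(1)), "species_spec")
})
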