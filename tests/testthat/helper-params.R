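# Shared fixtures: reference parameter sets and small builders.

ref_params <- function() {
  fluct_params(gain = 2, eps_bound = 0.1, eps_free = 0.01,
               occupancy = 0.25, mean_molecules = 100)
}

# Random valid parameter sets for property-style loops.
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    eb <- runif(1, 0.01, 0.8)
    fluct_params(gain = runif(1, 0.5, 5),
                 eps_bound = eb,
                 eps_free = runif(1, 0, eb),
                 occupancy = runif(1, 0.02, 0.98),
                 mean_molecules = runif(1, 5, 500))
  })
}

# Noise-free moment "ensemble" rows computed from the closed forms at a
# sweep of one parameter; used as exact-fit oracles.
exact_ensemble <- function(type, base, sweep) {
  rows <- lapply(seq_along(sweep), function(i) {
    p <- switch(type,
      I = update_fluct_params(base, mean_molecules = sweep[i]),
      II = update_fluct_params(base, eps_bound = base$eps_bound * sweep[i],
                               eps_free = base$eps_free * sweep[i]),
      III = update_fluct_params(base, occupancy = sweep[i]))
    data.frame(image_id = as.character(i), type = type,
               power_rel = if (type == "II") sweep[i] else 1,
               region = as.character(i), ca_added = 0,
               mean_F = mean_fluorescence(p),
               var_F = variance_fluorescence(p), n_pixels = 1e6)
  })
  moment_ensemble(do.call(rbind, rows), type = type)
}

# Minimal rd_solution stand-in with a prescribed radial dye field, for
# exercising the PSF blur without running the solver.
fake_solution <- function(field_fun, dye_total = 36, radius = 5, dr = 0.05,
                          t_ms = 0) {
  cfg <- rd_config(radius_um = radius, dr_um = dr, t_end_ms = 1,
                   species = list(species_spec("dye", 15, 240, 180,
                                               dye_total)))
  grid <- puffsnr:::rd_grid(cfg)
  field <- matrix(field_fun(grid$centers), nrow = length(t_ms),
                  ncol = grid$n, byrow = TRUE)
  structure(list(r_um = grid$centers, t_ms = t_ms, ca = field * 0,
                 bound = list(dye = field), injected_ions = 0,
                 pumped_ions = 0, closings = NULL, config = cfg,
                 grid = grid),
            class = "rd_solution")
}
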