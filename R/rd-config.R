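## Conversion: ions per cubic micrometer at 1 uM
## (1 uM = 1e-6 mol/L = 1e-6 * 6.02214076e23 / 1e15 um^3).
IONS_PER_UM3_PER_UM <- 602.214076

#' Buffer / dye species specification
#'
#' One Ca2+-binding species of the reaction-diffusion model: a single ion
#' binds a single molecule with mass-action kinetics
#' `kon * [Ca][S_free] - koff * [CaS]`.  Free and bound forms are assumed
#' to diffuse equally, so the total concentration stays uniform and only
#' the bound concentration needs to be evolved.
#'
#' @param name Species label (e.g. `"dye"`, `"egta"`).
#' @param D Diffusion coefficient (um^2/s; 0 for an immobile buffer).
#' @param kon On-rate (per uM per s).
#' @param koff Off-rate (per s).
#' @param total Total concentration (uM).
#' @return An object of class `species_spec` with derived `Kd = koff/kon`.
#' @export
species_spec <- function(name, D, kon, koff, total) {
  stopifnot(is.character(name), length(name) == 1L,
            D >= 0, kon >= 0, koff >= 0, total > 0)
  structure(list(name = name, D = as.numeric(D), kon = as.numeric(kon),
                 koff = as.numeric(koff), total = as.numeric(total),
                 Kd = koff / kon),
            class = "species_spec")
}

#' Standard species presets
#'
#' Kinetic parameters of the indicator dyes and buffers used throughout
#' the package (dextran-conjugated Fluo-4 and Rhod-2, EGTA, an immobile
#' endogenous buffer and two optional mobile endogenous buffers).  Two
#' published rate pairs exist for Rhod-2; both are exposed as variants
#' `"a"` (kon 70 per uM per s, koff 130 per s) and `"b"` (kon 85, koff 170)
#' rather than choosing silently.
#'
#' @param total Total concentration in uM.
#' @param variant Rhod-2 rate-pair variant, `"a"` or `"b"`.
#' @return A [species_spec()].
#' @name species_presets
NULL

#' @rdname species_presets
#' @export
fluo4_species <- function(total = 36)
  species_spec("dye", D = 15, kon = 240, koff = 180, total = total)

#' @rdname species_presets
#' @export
rhod2_species <- function(total = 36, variant = c("a", "b")) {
  variant <- match.arg(variant)
  if (variant == "a") species_spec("dye", D = 15, kon = 70, koff = 130, total = total)
  else species_spec("dye", D = 15, kon = 85, koff = 170, total = total)
}

#' @rdname species_presets
#' @export
egta_species <- function(total = 45)
  species_spec("egta", D = 80, kon = 5, koff = 0.75, total = total)

#' @rdname species_presets
#' @export
immobile_buffer_species <- function(total = 300)
  species_spec("immobile", D = 0, kon = 400, koff = 800, total = total)

#' @rdname species_presets
#' @export
slow_mobile_buffer_species <- function(total = 250)
  species_spec("mobile_slow", D = 27, kon = 20, koff = 8.6, total = total)

#' @rdname species_presets
#' @export
rapid_mobile_buffer_species <- function(total = 10)
  species_spec("mobile_rapid", D = 32, kon = 500, koff = 750, total = total)

#' Stochastic channel-cluster Ca2+ source
#'
#' A puff source: `n_channels` channels (a cluster of IP3 receptors) open
#' simultaneously at t = 0 and each closes after a time drawn from an
#' exponential distribution with mean `mean_open_ms`.  Each open channel
#' injects `flux_ions_per_s` Ca2+ ions per second into the innermost
#' radial shell.  The per-channel flux is an experiment-design quantity
#' with no universal value; [calibrate_source_flux()] adjusts it so the
#' blurred peak occupancy reaches a chosen target.
#'
#' @param n_channels Number of channels (>= 1, default 6).
#' @param mean_open_ms Mean open time (ms, > 0, default 20).
#' @param flux_ions_per_s Ca2+ ions per second per open channel (> 0;
#'   default 3e5, about 0.1 pA of Ca2+ current).
#' @return An object of class `puff_source`.
#' @export
puff_source <- function(n_channels = 6L, mean_open_ms = 20,
                        flux_ions_per_s = 3e5) {
  stopifnot(n_channels >= 1, mean_open_ms > 0, flux_ions_per_s > 0)
  structure(list(kind = "puff", n_channels = as.integer(n_channels),
                 mean_open_ms = as.numeric(mean_open_ms),
                 flux_ions_per_s = as.numeric(flux_ions_per_s)),
            class = "puff_source")
}

#' Constant point source
#'
#' Deterministic constant-rate source used for verification against the
#' closed-form diffusion solution of a point source in free space.
#'
#' @param flux_ions_per_s Total Ca2+ ions per second (> 0).
#' @param duration_ms Source on-time (default `Inf`).
#' @return An object of class `puff_source` with `kind = "constant"`.
#' @export
constant_source <- function(flux_ions_per_s, duration_ms = Inf) {
  stopifnot(flux_ions_per_s > 0, duration_ms > 0)
  structure(list(kind = "constant",
                 flux_ions_per_s = as.numeric(flux_ions_per_s),
                 duration_ms = as.numeric(duration_ms)),
            class = "puff_source")
}

#' Sample channel closing times
#'
#' @param source A [puff_source()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_channels` positive closing times (ms).
#' @export
sample_open_durations <- function(source, seed = NULL) {
  stopifnot(inherits(source, "puff_source"))
  if (source$kind != "puff")
    stop("sample_open_durations: not a stochastic puff source", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::rexp(source$n_channels, rate = 1 / source$mean_open_ms)
}

#' Reaction-diffusion configuration
#'
#' Domain, numerics, kinetics and source for the spherically symmetric
#' Ca2+ reaction-diffusion model.  Ca2+ is removed uniformly by a
#' linearized pump `J_pump = pump_rate * ([Ca] - ca_basal)`; with the
#' default pump parameters (koff-P 0.1 per s, \[P\]_T 0.9 uM, basal Ca
#' 0.1 uM) the rate is `0.1 * 0.9 / 0.1 = 0.9` per s.  This form is
#' units-consistent and leaves the equilibrium initial condition exactly
#' stationary.
#'
#' @param radius_um Domain radius R (um).
#' @param dr_um Radial grid spacing (um).
#' @param dt_ms Time step (ms).
#' @param t_end_ms End time (ms).
#' @param ca_basal Basal free Ca2+ concentration (uM, default 0.1).
#' @param species List of [species_spec()] objects.
#' @param pump_koff Pump rate constant koff-P (per s, default 0.1).
#' @param pump_total Pump concentration \[P\]_T (uM, default 0.9).
#' @param source A [puff_source()] / [constant_source()], or `NULL`.
#' @return An object of class `rd_config`.
#' @export
rd_config <- function(radius_um = 5, dr_um = 0.05, dt_ms = 0.01,
                      t_end_ms = 40, ca_basal = 0.1,
                      species = list(), pump_koff = 0.1, pump_total = 0.9,
                      source = NULL) {
  stopifnot(radius_um > 0, dr_um > 0, dt_ms > 0, t_end_ms > 0, ca_basal >= 0,
            pump_koff >= 0, pump_total >= 0)
  if (radius_um < 2)
    stop("rd_config: domain radius should be at least a few micrometers",
         call. = FALSE)
  for (s in species)
    if (!inherits(s, "species_spec"))
      stop("rd_config: species must be species_spec objects", call. = FALSE)
  if (!is.null(source) && !inherits(source, "puff_source"))
    stop("rd_config: source must be a puff_source/constant_source",
         call. = FALSE)
  pump_rate <- if (ca_basal > 0) pump_koff * pump_total / ca_basal else 0
  structure(list(radius_um = radius_um, dr_um = dr_um, dt_ms = dt_ms,
                 t_end_ms = t_end_ms, ca_basal = ca_basal,
                 D_ca = 220, species = species,
                 pump_koff = pump_koff, pump_total = pump_total,
                 pump_rate = pump_rate, source = source),
            class = "rd_config")
}

#' Concentration-set presets for the puff scenarios
#'
#' The three dye/EGTA combinations compared throughout the package:
#' set `"i"` is Fluo-4 dextran 36 uM with EGTA 90 uM, set `"ii"` Rhod-2
#' dextran 36 uM with EGTA 90 uM, set `"iii"` Rhod-2 dextran 90 uM with
#' EGTA 45 uM.  All include the immobile endogenous buffer; the mobile
#' endogenous buffers are available but off by default in puff scenarios.
#'
#' @param set One of `"i"`, `"ii"`, `"iii"`.
#' @param rhod2_variant Rhod-2 rate-pair variant (see [rhod2_species()]).
#' @param include_mobile_buffers Add the slow and rapid mobile endogenous
#'   buffers (default `FALSE`).
#' @param source A [puff_source()] (default: 6 channels, 20 ms mean open
#'   time).
#' @param ... Further arguments passed to [rd_config()] (numerics etc.).
#' @return An [rd_config()] for the requested set.
#' @export
gen_puff_scenario <- function(set = c("i", "ii", "iii"),
                              rhod2_variant = c("a", "b"),
                              include_mobile_buffers = FALSE,
                              source = puff_source(), ...) {
  if (!is.character(set) || !set[1] %in% c("i", "ii", "iii"))
    stop("gen_puff_scenario: unknown set label '", set[1],
         "' (use \"i\", \"ii\" or \"iii\")", call. = FALSE)
  set <- match.arg(set)
  rhod2_variant <- match.arg(rhod2_variant)
  dye <- switch(set,
                i = fluo4_species(total = 36),
                ii = rhod2_species(total = 36, variant = rhod2_variant),
                iii = rhod2_species(total = 90, variant = rhod2_variant))
  egta <- switch(set,
                 i = egta_species(total = 90),
                 ii = egta_species(total = 90),
                 iii = egta_species(total = 45))
  sp <- list(dye, egta, immobile_buffer_species())
  if (include_mobile_buffers)
    sp <- c(sp, list(slow_mobile_buffer_species(),
                     rapid_mobile_buffer_species()))
  rd_config(species = sp, source = source, ...)
}

#' Equilibrium bound fraction of a species
#'
#' At uniform basal Ca2+ the mass-action steady state gives
#' `[CaS]/[S]_T = kon Ca / (kon Ca + koff) = Ca / (Ca + Kd)`.
#'
#' @param species A [species_spec()].
#' @param ca Free Ca2+ concentration (uM).
#' @return Bound fraction in \[0, 1\].
#' @export
equilibrium_bound_fraction <- function(species, ca) {
  stopifnot(inherits(species, "species_spec"), ca >= 0)
  if (species$kon == 0) return(0)
  species$kon * ca / (species$kon * ca + species$koff)
}
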