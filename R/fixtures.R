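#' Fixture specification for synthetic moment ensembles
#'
#' Describes how a stationary-experiment ensemble is generated from a
#' ground-truth parameter set, following the variable/fixed pattern of
#' each experiment type: Type I varies the molecule number across imaged
#' regions (log-uniform jitter, default x0.5..x2, emulating slightly
#' different dye concentrations between cytosolic regions); Type II
#' varies the laser intensity (both brightnesses scale together, ratio
#' fixed); Type III varies the occupancy over a grid (and jitters the
#' molecule number across regions).
#'
#' @param type `"I"`, `"II"` or `"III"`.
#' @param params Ground-truth [fluct_params()] (occupancy = basal value;
#'   brightnesses at the standard intensity).
#' @param n_images Number of images in the ensemble.
#' @param pixels_per_image Pixels pooled per image.
#' @param n_jitter Molecule-number jitter range (Type I/III), multiplicative.
#' @param intensity_range Relative-intensity sweep (Type II).
#' @param lambda_range Occupancy sweep (Type III).
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(type = c("I", "II", "III"), params,
                         n_images, pixels_per_image,
                         n_jitter = c(0.5, 2),
                         intensity_range = c(0.2, 2),
                         lambda_range = c(0.1, 0.9),
                         seed = 1L) {
  type <- match.arg(type)
  validate_fluct_params(params)
  stopifnot(n_images >= 5, pixels_per_image >= 2)
  structure(list(type = type, params = params,
                 n_images = as.integer(n_images),
                 pixels_per_image = as.integer(pixels_per_image),
                 n_jitter = n_jitter, intensity_range = intensity_range,
                 lambda_range = lambda_range, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic moment ensemble
#'
#' Samples each image's pixels through the generative chain
#' ([sample_pixel()]) with the per-image parameter variation prescribed
#' by the fixture type, then records the pooled (mean, variance) pair.
#' The per-image ground truth is embedded in columns `true_N`,
#' `true_eps_b`, `true_eps_f`, `true_lambda` so that recovery tests never
#' read hidden state.
#'
#' @param spec A [fixture_spec()].
#' @return A [moment_ensemble()] with embedded ground-truth columns and
#'   attribute `truth` (the base parameter set).
#' @export
gen_moment_ensemble <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  p <- spec$params
  n <- spec$n_images
  jit <- function(range) exp(stats::runif(n, log(range[1]), log(range[2])))
  per <- switch(spec$type,
    I = data.frame(N = p$mean_molecules * jit(spec$n_jitter),
                   eps_b = p$eps_bound, eps_f = p$eps_free,
                   lambda = p$occupancy,
                   power_rel = 1),
    II = {
      ii <- seq(spec$intensity_range[1], spec$intensity_range[2],
                length.out = n)
      data.frame(N = p$mean_molecules, eps_b = p$eps_bound * ii,
                 eps_f = p$eps_free * ii, lambda = p$occupancy,
                 power_rel = ii)
    },
    III = data.frame(N = p$mean_molecules * jit(spec$n_jitter),
                     eps_b = p$eps_bound, eps_f = p$eps_free,
                     lambda = seq(spec$lambda_range[1], spec$lambda_range[2],
                                  length.out = n),
                     power_rel = 1))
  rows <- lapply(seq_len(n), function(i) {
    pi <- fluct_params(gain = p$gain, eps_bound = per$eps_b[i],
                       eps_free = per$eps_f[i], occupancy = per$lambda[i],
                       mean_molecules = per$N[i])
    px <- sample_pixel(pi, spec$pixels_per_image)
    data.frame(image_id = sprintf("sim_%s_%03d", spec$type, i),
               type = spec$type, power_rel = per$power_rel[i],
               region = sprintf("region_%03d", i),
               ca_added = if (spec$type == "III") per$lambda[i] else 0,
               mean_F = mean(px), var_F = stats::var(px),
               n_pixels = spec$pixels_per_image,
               true_N = per$N[i], true_eps_b = per$eps_b[i],
               true_eps_f = per$eps_f[i], true_lambda = per$lambda[i],
               stringsAsFactors = FALSE)
  })
  ens <- moment_ensemble(do.call(rbind, rows), type = spec$type)
  attr(ens, "truth") <- p
  attr(ens, "seed") <- spec$seed
  ens
}

#' Generate a granule-striped linescan fixture
#'
#' Stationary synthetic linescan with known dark (granule) rows, for
#' exercising the preprocessing chain: a constant-occupancy cytosol with
#' dark fringes inserted at known positions.
#'
#' @param params Ground-truth [fluct_params()] (its occupancy is used
#'   everywhere in the cytosol).
#' @param n_rows Total spatial rows of the image.
#' @param n_cols Time columns.
#' @param granule_rows Output-row indices of the dark fringes (default: a
#'   band near the top and one near the bottom).
#' @param granule_level Granule mean as a fraction of the cytosolic mean.
#' @param seed Integer seed.
#' @return A [linescan_image()] whose attributes `granule_rows` and
#'   `lambda_map` are the embedded ground truth.
#' @export
gen_linescan_fixture <- function(params, n_rows = 64, n_cols = 256,
                                 granule_rows = NULL, granule_level = 0.1,
                                 seed = 1L) {
  validate_fluct_params(params)
  if (is.null(granule_rows))
    granule_rows <- c(seq(5L, 9L), seq(n_rows - 12L, n_rows - 8L))
  lam <- matrix(params$occupancy, n_rows - length(granule_rows), n_cols)
  synthesize_image(lam, params, lambda_basal = params$occupancy,
                   granule_rows = granule_rows,
                   granule_level = granule_level, seed = seed,
                   annotations = list(type = "I", image_id = "fixture"))
}

#' Default fluctuation parameters of the three concentration sets
#'
#' Study-condition parameter sets used when synthesizing noisy puff
#' images for sets i-iii.  The mean molecule number scales with the
#' total dye concentration (100 at 36 uM, 250 at 90 uM; the confocal
#' volume is common to all settings).  The bound-dye brightness at the
#' standard illumination is 0.1 photons/molecule/dwell, a typical
#' photon-counting confocal value, for both dyes.  The brightness ratio
#' r = eps_f/eps_b follows the fluorescence-enhancement factors of the
#' dyes: about 100-fold for Fluo-4 (r = 0.01) and about 14-fold for
#' Rhod-2 (r = 0.07).  The occupancy field carries the dye's basal
#' equilibrium occupancy at 0.1 uM free Ca2+.
#'
#' @param set One of `"i"`, `"ii"`, `"iii"`.
#' @param eps_f_zero Zero out the free-dye brightness (the control that
#'   isolates the role of free-dye fluorescence).
#' @param rhod2_variant Rhod-2 kinetic variant for the basal occupancy.
#' @return A [fluct_params()].
#' @export
puff_set_params <- function(set = c("i", "ii", "iii"), eps_f_zero = FALSE,
                            rhod2_variant = c("a", "b")) {
  set <- match.arg(set)
  rhod2_variant <- match.arg(rhod2_variant)
  dye <- switch(set, i = fluo4_species(36),
                ii = rhod2_species(36, rhod2_variant),
                iii = rhod2_species(90, rhod2_variant))
  n <- c(i = 100, ii = 100, iii = 250)[[set]]
  r <- if (set == "i") 0.01 else 0.07
  eb <- 0.1
  fluct_params(gain = 1, eps_bound = eb,
               eps_free = if (eps_f_zero) 0 else r * eb,
               occupancy = equilibrium_bound_fraction(dye, 0.1),
               mean_molecules = n)
}
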