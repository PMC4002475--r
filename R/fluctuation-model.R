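#' Mean pixel fluorescence of the fluctuation model
#'
#' Closed-form first moment of the generative pixel chain
#' N ~ Poisson(<N>), B | N ~ Binomial(N, lambda),
#' P ~ Poisson(eps_b B + eps_f (N - B)), F = A P:
#'
#'   <F> = A <N> (eps_b lambda + eps_f (1 - lambda)).
#'
#' @param params A [fluct_params()] object.
#' @return Mean fluorescence (nonnegative scalar, detector output units).
#' @seealso [variance_fluorescence()], [sample_pixel()]
#' @export
mean_fluorescence <- function(params) {
  validate_fluct_params(params)
  with(params, gain * mean_molecules *
         (eps_bound * occupancy + eps_free * (1 - occupancy)))
}

#' Pixel fluorescence variance of the fluctuation model
#'
#' Exact second central moment of the Poisson -> Binomial -> Poisson photon
#' -> Poisson detector chain.  Because a binomial thinning of a Poisson
#' count yields two independent Poisson counts (B and N - B), the photon
#' mean eps_b B + eps_f (N - B) has variance
#' <N> (eps_b^2 lambda + eps_f^2 (1 - lambda)), and the detector stage adds
#' the photon shot term:
#'
#'   sigma_F^2 = A^2 <N> \[(eps_b lambda + eps_f (1 - lambda)) +
#'                        (eps_b^2 lambda + eps_f^2 (1 - lambda))\].
#'
#' The first bracket term equals A <F> after scaling, so
#' sigma_F^2 >= A <F> always: molecule-number and occupancy fluctuations
#' can only add noise on top of photon shot noise.
#'
#' @inheritParams mean_fluorescence
#' @return Fluorescence variance (nonnegative scalar).
#' @export
variance_fluorescence <- function(params) {
  validate_fluct_params(params)
  with(params, {
    shot <- eps_bound * occupancy + eps_free * (1 - occupancy)
    molec <- eps_bound^2 * occupancy + eps_free^2 * (1 - occupancy)
    gain^2 * mean_molecules * (shot + molec)
  })
}

#' Draw pixel fluorescence values from the generative model
#'
#' Samples the full chain per pixel: the number of contributing dye
#' molecules N is Poisson with mean `mean_molecules`; given N the number of
#' Ca2+-bound molecules B is Binomial(N, occupancy); the detected photon
#' count P is Poisson with mean `eps_bound * B + eps_free * (N - B)`; the
#' reported fluorescence is `gain * P`.  Uses R's global random stream;
#' supply `seed` for a reproducible draw.
#'
#' @inheritParams mean_fluorescence
#' @param n Number of independent pixel values to draw.
#' @param seed Optional integer seed applied with [set.seed()] before sampling.
#' @return Numeric vector of length `n`; each value is a nonnegative
#'   multiple of `gain`.
#' @export
sample_pixel <- function(params, n = 1L, seed = NULL) {
  validate_fluct_params(params)
  if (!is.null(seed)) set.seed(seed)
  N <- stats::rpois(n, params$mean_molecules)
  B <- stats::rbinom(n, N, params$occupancy)
  photon_mean <- params$eps_bound * B + params$eps_free * (N - B)
  params$gain * stats::rpois(n, photon_mean)
}

#' Variance-versus-mean slope for fixed brightness and occupancy
#'
#' When only the molecule number varies between images (different cytosolic
#' regions, same dye batch and laser power), eliminating `<N>` between the
#' two moment expressions leaves a proportionality
#'
#'   sigma_F^2 = slope * <F>,
#'   slope = A \[1 + eps_b (lambda + r^2 (1 - lambda)) /
#'                        (lambda + r  (1 - lambda))\],
#'
#' with r = eps_f/eps_b.  The slope is at least A and collapses to A in the
#' small-brightness limit, which is why the fitted slope of such an
#' ensemble estimates the detector amplification directly.
#'
#' @param gain Detector amplification A (> 0).
#' @param eps_bound Brightness of the bound dye (> 0).
#' @param ratio Brightness ratio r = eps_free/eps_bound in \[0, 1\].
#' @param occupancy Occupancy lambda in \[0, 1\].
#' @return The slope (scalar >= `gain`).
#' @export
type1_slope <- function(gain, eps_bound, ratio, occupancy) {
  stopifnot(gain > 0, eps_bound > 0, ratio >= 0, ratio <= 1,
            occupancy >= 0, occupancy <= 1)
  denom <- occupancy + ratio * (1 - occupancy)
  if (denom <= 0)
    stop("type1_slope: degenerate input (occupancy = 0 with ratio = 0)",
         call. = FALSE)
  gain * (1 + eps_bound * (occupancy + ratio^2 * (1 - occupancy)) / denom)
}

#' Variance-versus-mean polynomial for a laser-power sweep
#'
#' When the laser power varies at fixed molecule number and occupancy, both
#' brightnesses scale together (fixed ratio r) and eliminating eps_b gives
#' a second-degree polynomial through the origin,
#'
#'   sigma_F^2 = a1 <F> + a2 <F>^2,
#'   a1 = A,
#'   a2 = (lambda + r^2 (1 - lambda)) /
#'        (<N> (lambda + r (1 - lambda))^2).
#'
#' The crossover fluorescence `fstar = a1/a2` marks where the quadratic
#' (molecule-number / occupancy) term overtakes photon shot noise; power
#' sweeps that never exceed it look perfectly linear and cannot constrain
#' `<N>`.
#'
#' @inheritParams type1_slope
#' @param mean_molecules Mean molecules per pixel `<N>` (> 0).
#' @return List with `a1`, `a2` and the crossover `fstar = a1/a2`.
#' @export
type2_coefficients <- function(gain, mean_molecules, occupancy, ratio) {
  stopifnot(gain > 0, mean_molecules > 0, ratio >= 0, ratio <= 1,
            occupancy >= 0, occupancy <= 1)
  denom <- occupancy + ratio * (1 - occupancy)
  if (denom <= 0)
    stop("type2_coefficients: degenerate input (occupancy = 0 with ratio = 0)",
         call. = FALSE)
  a2 <- (occupancy + ratio^2 * (1 - occupancy)) / (mean_molecules * denom^2)
  list(a1 = gain, a2 = a2, fstar = gain / a2)
}

#' Variance-versus-mean line for an occupancy sweep
#'
#' When the cytosolic Ca2+ level (hence the occupancy) varies at fixed
#' brightness and molecule number, eliminating lambda gives an affine
#' relation
#'
#'   sigma_F^2 = A (1 + eps_b + eps_f) <F> - A^2 <N> eps_b eps_f,
#'
#' i.e. slope `A (1 + eps_b + eps_f)` and intercept
#' `-A^2 <N> eps_b eps_f <= 0`.  For eps_f = 0 (or occupancy -> 1) the
#' intercept vanishes and the slope reduces to `A (1 + eps_b)`, which is
#' the relation used to extract eps_b from the high-fluorescence points of
#' an occupancy sweep.
#'
#' @inheritParams type2_coefficients
#' @param eps_free Brightness of the free dye (>= 0).
#' @param eps_bound Brightness of the bound dye (> 0).
#' @return List with `slope` and `intercept`.
#' @export
type3_line <- function(gain, eps_bound, eps_free, mean_molecules) {
  stopifnot(gain > 0, eps_bound > 0, eps_free >= 0, mean_molecules > 0)
  list(slope = gain * (1 + eps_bound + eps_free),
       intercept = -gain^2 * mean_molecules * eps_bound * eps_free)
}
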