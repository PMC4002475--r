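#' Confocal point-spread-function parameters
#'
#' Anisotropic 3-D Gaussian observation volume in the 1/e^2 convention:
#' weight proportional to `exp(-2 (x^2 + y^2)/w_r^2 - 2 z^2/w_z^2)`.
#' Defaults (w_r 0.3 um lateral, w_z 1.0 um axial) are typical of a 60x
#' high-NA oil-immersion confocal; both are always configurable and are
#' recorded in synthesized-image sidecars.
#'
#' @param w_r Lateral half-width (um, > 0).
#' @param w_z Axial half-width (um, >= `w_r`).
#' @return An object of class `psf_params`.
#' @export
psf_params <- function(w_r = 0.3, w_z = 1.0) {
  stopifnot(w_r > 0, w_z > 0)
  if (w_z < w_r)
    stop("psf_params: the axial half-width cannot be smaller than the lateral one",
         call. = FALSE)
  structure(list(w_r = as.numeric(w_r), w_z = as.numeric(w_z)),
            class = "psf_params")
}

## Quadrature matrix mapping a radial field to blurred values along the
## scan line: out[j, ] %*% field(r) approximates the normalized Gaussian-
## weighted average centered at (scan_x[j], 0, 0).  Kernel truncated at 3
## half-widths and renormalized.
blur_matrix <- function(scan_x, psf, r_grid, r_max, pts_per_width = 8L) {
  du <- seq(-3 * psf$w_r, 3 * psf$w_r, length.out = 6L * pts_per_width + 1L)
  dw <- seq(-3 * psf$w_z, 3 * psf$w_z, length.out = 6L * pts_per_width + 1L)
  offs <- expand.grid(u = du, v = du, w = dw)
  wts <- exp(-2 * (offs$u^2 + offs$v^2) / psf$w_r^2 - 2 * offs$w^2 / psf$w_z^2)
  nr <- length(r_grid)
  M <- matrix(0, length(scan_x), nr)
  for (j in seq_along(scan_x)) {
    rad <- sqrt((scan_x[j] + offs$u)^2 + offs$v^2 + offs$w^2)
    if (max(rad) > r_max)
      stop("blur_radial_field: scan line (plus 3 PSF half-widths) extends ",
           "beyond the simulation domain", call. = FALSE)
    # linear interpolation weights onto the radial grid
    idx <- findInterval(rad, r_grid, all.inside = TRUE)
    frac <- (rad - r_grid[idx]) / (r_grid[idx + 1L] - r_grid[idx])
    frac <- pmin(pmax(frac, 0), 1)
    row <- numeric(nr)
    lo <- tapply(wts * (1 - frac), idx, sum)
    hi <- tapply(wts * frac, idx + 1L, sum)
    row[as.integer(names(lo))] <- row[as.integer(names(lo))] + lo
    row[as.integer(names(hi))] <- row[as.integer(names(hi))] + hi
    M[j, ] <- row / sum(wts)
  }
  M
}

#' Blur a radial bound-dye field along a scan line
#'
#' Converts the spherically symmetric Ca2+-bound dye concentration of an
#' [rd_run()] solution into the confocal signal along a linescan through
#' the source: for every scan position x and recorded time, the
#' PSF-weighted (normalized, truncated at 3 half-widths) average of the
#' radial field centered at (x, 0, 0).  Dividing by the total dye
#' concentration yields the space- and time-dependent occupancy map
#' lambda(x, t) used to synthesize noisy images.
#'
#' @param solution An `rd_solution`.
#' @param psf A [psf_params()].
#' @param scan_x Scan positions (um); must stay 3 PSF half-widths inside
#'   the domain radius.
#' @param species Name of the blurred species (default `"dye"`).
#' @param times Optional subset of recorded times (ms) to blur (defaults
#'   to all frames).
#' @return An object of class `blurred_profile`: `x_um`, `t_ms`,
#'   `cabound` (scan x time matrix, uM), `occupancy` (same shape),
#'   `dye_total`, `psf`.
#' @export
blur_radial_field <- function(solution, psf, scan_x, species = "dye",
                              times = NULL) {
  stopifnot(inherits(solution, "rd_solution"), inherits(psf, "psf_params"))
  if (!species %in% names(solution$bound))
    stop("blur_radial_field: no species named '", species, "' in solution",
         call. = FALSE)
  keep <- if (is.null(times)) seq_along(solution$t_ms)
          else vapply(times, function(tt) which.min(abs(solution$t_ms - tt)),
                      integer(1))
  M <- blur_matrix(scan_x, psf, solution$r_um, solution$config$radius_um)
  field <- solution$bound[[species]][keep, , drop = FALSE]  # frames x cells
  blurred <- M %*% t(field)                                 # x positions x frames
  sp <- solution$config$species[[
    which(vapply(solution$config$species, `[[`, "", "name") == species)]]
  structure(list(x_um = scan_x, t_ms = solution$t_ms[keep],
                 cabound = blurred, occupancy = blurred / sp$total,
                 dye_total = sp$total, psf = psf),
            class = "blurred_profile")
}

#' @export
print.blurred_profile <- function(x, ...) {
  cat(sprintf("Blurred profile: %d scan positions x %d times; occupancy %.4g .. %.4g\n",
              length(x$x_um), length(x$t_ms), min(x$occupancy),
              max(x$occupancy)))
  invisible(x)
}

#' Synthesize a noisy linescan image from an occupancy map
#'
#' Draws every pixel independently through the generative fluctuation
#' chain ([sample_pixel()]) with that pixel's occupancy lambda(x, t).
#' Optional granule rows emulate the persistently dark cortical-granule
#' fringes of oocyte linescans: their occupancy is set so that the mean
#' granule fluorescence is about `granule_level` times the basal
#' cytosolic mean (clamped at occupancy 0 when the free-dye floor is
#' higher than that), purely so that preprocessing has realistic dark
#' fringes to remove.
#'
#' @param lambda_map Matrix of occupancies in \[0, 1\]
#'   (rows = scan positions, columns = times).
#' @param params A [fluct_params()]; its own `occupancy` field is ignored
#'   in favor of the map, but its basal value is used for granule scaling.
#' @param lambda_basal Basal occupancy used for granule-row scaling
#'   (default `min(lambda_map)`).
#' @param granule_rows Integer positions (in the output image) at which
#'   dark granule rows are inserted, or `NULL`.
#' @param granule_level Granule mean fluorescence as a fraction of the
#'   basal cytosolic mean (default 0.1).
#' @param pixel_um,line_ms Image metadata for the returned
#'   [linescan_image()].
#' @param seed Optional integer seed; the same (map, params, seed) tuple
#'   yields a bit-identical image.
#' @param annotations Annotations stored in the image.
#' @return A [linescan_image()] with attributes `lambda_map` (the map
#'   actually used, including granule rows) and `granule_rows`.
#' @export
synthesize_image <- function(lambda_map, params, lambda_basal = NULL,
                             granule_rows = NULL, granule_level = 0.1,
                             pixel_um = 0.2, line_ms = 2, seed = NULL,
                             annotations = list(type = "0")) {
  lambda_map <- as.matrix(lambda_map)
  if (anyNA(lambda_map) || any(lambda_map < 0) || any(lambda_map > 1))
    stop("synthesize_image: occupancies must lie in [0, 1]", call. = FALSE)
  validate_fluct_params(params)
  if (is.null(lambda_basal)) lambda_basal <- min(lambda_map)

  if (!is.null(granule_rows)) {
    granule_rows <- sort(unique(as.integer(granule_rows)))
    n_out <- nrow(lambda_map) + length(granule_rows)
    if (any(granule_rows < 1L | granule_rows > n_out))
      stop("synthesize_image: granule_rows outside the output image",
           call. = FALSE)
    # granule occupancy: mean F equal to granule_level * basal mean
    eb <- params$eps_bound; ef <- params$eps_free
    target <- granule_level * (eb * lambda_basal + ef * (1 - lambda_basal))
    lam_g <- max(0, min(1, (target - ef) / (eb - ef)))
    full <- matrix(NA_real_, n_out, ncol(lambda_map))
    full[granule_rows, ] <- lam_g
    full[setdiff(seq_len(n_out), granule_rows), ] <- lambda_map
    lambda_map <- full
  }

  if (!is.null(seed)) set.seed(seed)
  npx <- length(lambda_map)
  N <- stats::rpois(npx, params$mean_molecules)
  B <- stats::rbinom(npx, N, as.vector(lambda_map))
  P <- stats::rpois(npx, params$eps_bound * B + params$eps_free * (N - B))
  values <- matrix(params$gain * P, nrow(lambda_map), ncol(lambda_map))

  img <- linescan_image(values, pixel_um = pixel_um, line_ms = line_ms,
                        annotations = annotations)
  attr(img, "lambda_map") <- lambda_map
  attr(img, "granule_rows") <- granule_rows
  img
}
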