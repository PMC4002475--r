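#' Image-based signal-to-noise ratio
#'
#' For a (synthetic or measured) linescan image containing a signal,
#' `SN = (F_max - F_min) / sigma_basal`, where the extrema are taken over
#' the bright-fringe (cytosol) pixels and `sigma_basal` is the model
#' fluorescence standard deviation ([variance_fluorescence()]) evaluated
#' at the basal occupancy.  The extrema are literal image extrema by
#' default; a percentile-based robust variant is available and is flagged
#' in the result as a deviation from the plain definition.
#'
#' @param image A [linescan_image()].
#' @param params A [fluct_params()] (gain, brightnesses, molecule number
#'   used for the basal noise).
#' @param lambda_basal Basal occupancy.
#' @param exclude_rows Row indices excluded from the extrema (e.g. granule
#'   rows); defaults to the image's `granule_rows` attribute, if any.
#' @param robust Use percentile extrema instead of min/max.
#' @param probs Percentiles used when `robust = TRUE`.
#' @return An object of class `snr_report` (list with `sn`, `f_max`,
#'   `f_min`, `sigma_basal`, `lambda_basal`, `robust`, `params`).
#' @export
snr_image <- function(image, params, lambda_basal, exclude_rows = NULL,
                      robust = FALSE, probs = c(0.001, 0.999)) {
  stopifnot(inherits(image, "linescan_image"))
  validate_fluct_params(params)
  stopifnot(lambda_basal >= 0, lambda_basal <= 1)
  if (is.null(exclude_rows)) exclude_rows <- attr(image, "granule_rows")
  keep <- setdiff(seq_len(nrow(image$values)), exclude_rows)
  px <- as.vector(image$values[keep, , drop = FALSE])
  sigma <- sqrt(variance_fluorescence(
    update_fluct_params(params, occupancy = lambda_basal)))
  if (sigma == 0)
    stop("snr_image: basal fluorescence standard deviation is zero",
         call. = FALSE)
  ex <- if (robust) stats::quantile(px, probs, names = FALSE) else range(px)
  structure(list(sn = (ex[2] - ex[1]) / sigma, f_max = ex[2], f_min = ex[1],
                 sigma_basal = sigma, lambda_basal = lambda_basal,
                 robust = robust, params = params),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SN = %.4g  (F range %.4g .. %.4g, basal sigma %.4g%s)\n",
              x$sn, x$f_min, x$f_max, x$sigma_basal,
              if (x$robust) ", robust percentile extrema" else ""))
  invisible(x)
}

#' Analytic signal-to-noise ratio
#'
#' Model-predicted SN for a signal that raises the occupancy from
#' `lambda_basal` (taken from `params$occupancy`) to `lambda_peak`:
#'
#'   SN = (<F>(lambda_peak) - <F>(lambda_basal)) / sigma_F(lambda_basal),
#'
#' with both moments from the exact expressions
#' ([mean_fluorescence()], [variance_fluorescence()]).  The detector gain
#' cancels exactly and SN is proportional to `sqrt(mean_molecules)`, so
#' raising the dye concentration c-fold raises SN by `sqrt(c)`.  The
#' documented small-brightness approximation
#' `sqrt(N) (eps_b - eps_f)(lambda_p - lambda_b) /
#'  sqrt(eps_b lambda_b + eps_f (1 - lambda_b))`
#' (photon shot noise only) is available via `simplified = TRUE`.
#'
#' @param params A [fluct_params()]; its `occupancy` is the basal value.
#' @param lambda_peak Peak occupancy during the signal.  A value below
#'   the basal occupancy yields a signed result with a warning.
#' @param simplified Use the small-brightness form.
#' @return The SN value (scalar).
#' @export
snr_analytic <- function(params, lambda_peak, simplified = FALSE) {
  validate_fluct_params(params)
  stopifnot(lambda_peak >= 0, lambda_peak <= 1)
  lb <- params$occupancy
  if (lambda_peak < lb)
    warning("snr_analytic: lambda_peak below basal; returning a signed value",
            call. = FALSE)
  if (simplified) {
    with(params, sqrt(mean_molecules) * (eps_bound - eps_free) *
           (lambda_peak - lb) /
           sqrt(eps_bound * lb + eps_free * (1 - lb)))
  } else {
    peak <- update_fluct_params(params, occupancy = lambda_peak)
    (mean_fluorescence(peak) - mean_fluorescence(params)) /
      sqrt(variance_fluorescence(params))
  }
}

#' Signal-to-noise surface over experimentally accessible parameters
#'
#' Tabulates the analytic SN over grids of mean molecule number (i.e. dye
#' concentration), relative laser intensity and basal occupancy, at a
#' fixed peak occupancy.  Brightness scales with intensity:
#' `eps_b = eps_b0 * (I/I0)` and `eps_f = r * eps_b`, with `eps_b0` the
#' calibrated brightness at the standard illumination `I0`.
#'
#' @param params Calibrated [fluct_params()] at the standard intensity
#'   (`I/I0 = 1`); its occupancy is the default basal value.
#' @param n_grid Grid of mean molecule numbers.
#' @param intensity_grid Grid of relative intensities `I/I0`.
#' @param lambda_basal_grid Grid of basal occupancies.
#' @param lambda_peak Peak occupancy.
#' @return Data frame with columns `mean_molecules`, `intensity_rel`,
#'   `lambda_basal`, `sn`.
#' @export
snr_surface <- function(params, n_grid = params$mean_molecules,
                        intensity_grid = 1,
                        lambda_basal_grid = params$occupancy,
                        lambda_peak) {
  validate_fluct_params(params)
  grid <- expand.grid(mean_molecules = n_grid,
                      intensity_rel = intensity_grid,
                      lambda_basal = lambda_basal_grid,
                      KEEP.OUT.ATTRS = FALSE)
  r <- brightness_ratio(params)
  grid$sn <- vapply(seq_len(nrow(grid)), function(i) {
    eb <- params$eps_bound * grid$intensity_rel[i]
    p <- fluct_params(gain = params$gain, eps_bound = eb, eps_free = r * eb,
                      occupancy = grid$lambda_basal[i],
                      mean_molecules = grid$mean_molecules[i])
    snr_analytic(p, lambda_peak)
  }, numeric(1))
  grid
}

#' Translate a peak occupancy between dyes
#'
#' When planning a dye replacement, the same free-Ca2+ peak gives a
#' different occupancy for a dye with a different dissociation constant.
#' Assuming dye-Ca2+ equilibrium at the peak of the signal,
#' `Ca_peak = Kd_old * lambda / (1 - lambda)` and
#' `lambda_new = Ca_peak / (Ca_peak + Kd_new)`.
#'
#' @param lambda_peak_old Peak occupancy with the old dye, in (0, 1).
#' @param kd_old,kd_new Dissociation constants (uM, > 0).
#' @return The translated peak occupancy in (0, 1), monotone decreasing
#'   in `kd_new`.
#' @export
translate_occupancy_between_dyes <- function(lambda_peak_old, kd_old, kd_new) {
  stopifnot(kd_old > 0, kd_new > 0)
  if (lambda_peak_old <= 0 || lambda_peak_old >= 1)
    stop("translate_occupancy_between_dyes: occupancy must lie strictly in (0, 1)",
         call. = FALSE)
  ca_peak <- kd_old * lambda_peak_old / (1 - lambda_peak_old)
  ca_peak / (ca_peak + kd_new)
}

#' Group experimental settings into SN equivalence classes
#'
#' Single-linkage grouping: two settings are linked when their relative
#' SN difference `|SN_a - SN_b| / max(SN_a, SN_b)` is at most
#' `threshold`; classes are the connected components of the link graph.
#' The default threshold 0.25 separates SN differences of ~40% (distinct
#' detectability) from ~16% (equivalent detectability).
#'
#' @param sn Named numeric vector of SN values (>= 2 settings).
#' @param threshold Relative-difference threshold (default 0.25).
#' @return An object of class `equivalence_report`: data frame `settings`
#'   (setting, sn, class), the `threshold`, and `classes` (list of
#'   setting-name vectors).
#' @export
classify_equivalence <- function(sn, threshold = 0.25) {
  stopifnot(is.numeric(sn), length(sn) >= 2L, threshold >= 0)
  if (is.null(names(sn))) names(sn) <- paste0("setting_", seq_along(sn))
  n <- length(sn)
  linked <- outer(sn, sn, function(a, b) abs(a - b) / pmax(a, b) <= threshold)
  diag(linked) <- TRUE
  # connected components by label propagation
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[linked[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  comp <- as.integer(factor(comp, levels = unique(comp)))
  settings <- data.frame(setting = names(sn), sn = unname(sn), class = comp,
                         stringsAsFactors = FALSE)
  classes <- split(settings$setting, settings$class)
  structure(list(settings = settings, threshold = threshold,
                 linkage = "single", classes = unname(classes)),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat(sprintf("Equivalence classes (single linkage, relative threshold %.3g):\n",
              x$threshold))
  for (i in seq_along(x$classes)) {
    members <- x$settings[x$settings$class == i, ]
    cat(sprintf("  class %d: %s\n", i,
                paste(sprintf("%s (SN %.3g)", members$setting, members$sn),
                      collapse = ", ")))
  }
  invisible(x)
}
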