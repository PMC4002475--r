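#' Moment ensemble
#'
#' Stack of per-image moment samples sharing one experiment type, ready
#' for a variance-versus-mean fit.  Type I ensembles vary the imaged
#' region (molecule number), Type II the laser power (brightness), Type
#' III the cytosolic Ca2+ (occupancy, and in practice also the region).
#'
#' @param samples A data frame with at least `mean_F` and `var_F` columns
#'   (e.g. rbind-ed [bright_moments()] rows).
#' @param type Experiment type label: `"I"`, `"II"` or `"III"`.
#' @param dye Optional dye identity label.
#' @param set Optional concentration-set label.
#' @return The data frame with class `moment_ensemble` and attributes
#'   `type`, `dye`, `set`.
#' @export
moment_ensemble <- function(samples, type, dye = NA_character_,
                            set = NA_character_) {
  stopifnot(is.data.frame(samples),
            all(c("mean_F", "var_F") %in% names(samples)))
  type <- match.arg(type, c("I", "II", "III"))
  if (nrow(samples) < 5L)
    stop("moment_ensemble: need at least 5 samples for any fit", call. = FALSE)
  structure(as.data.frame(samples),
            class = c("moment_ensemble", "data.frame"),
            type = type, dye = dye, set = set)
}

ensure_type <- function(ensemble, type) {
  stopifnot(inherits(ensemble, "moment_ensemble"))
  if (!identical(attr(ensemble, "type"), type))
    stop("expected a Type ", type, " ensemble, got Type ",
         attr(ensemble, "type"), call. = FALSE)
  invisible(ensemble)
}

#' Fit a Type I (region-sweep) moment ensemble
#'
#' Ordinary least squares of variance against mean.  Because only the
#' molecule number differs between the images, the points fall on a line
#' through the origin whose slope estimates the detector amplification A
#' up to a brightness-dependent factor close to 1 (see [type1_slope()]);
#' in the small-brightness regime the slope is reported directly as
#' `A_hat`.  A recorded warning flag is raised when the fitted intercept
#' exceeds 10% of the median variance, i.e. when the curve does not
#' practically go through the origin.
#'
#' @param ensemble A Type I [moment_ensemble()].
#' @param conf_level Confidence level for the parameter intervals.
#' @return List with `slope`, `intercept`, `A_hat` (= slope), `ci`
#'   (matrix), `intercept_warn`, `r_squared` and the fitted `model`.
#' @export
fit_type1 <- function(ensemble, conf_level = 0.95) {
  ensure_type(ensemble, "I")
  fit <- stats::lm(var_F ~ mean_F, data = ensemble)
  co <- stats::coef(fit)
  if (co[["mean_F"]] <= 0)
    stop("fit_type1: nonpositive slope; ensemble violates the model",
         call. = FALSE)
  ci <- stats::confint(fit, level = conf_level)
  warn <- abs(co[["(Intercept)"]]) > 0.1 * stats::median(ensemble$var_F)
  list(slope = unname(co[["mean_F"]]),
       intercept = unname(co[["(Intercept)"]]),
       A_hat = unname(co[["mean_F"]]),
       ci = ci,
       intercept_warn = warn,
       r_squared = summary(fit)$r.squared,
       model = fit)
}

#' Fit a Type II (laser-power-sweep) moment ensemble
#'
#' Second-degree polynomial through the origin,
#' `var_F = a1 mean_F + a2 mean_F^2`.  `a1` re-estimates the detector
#' amplification A; `a2` carries the molecule number (see
#' [type2_coefficients()]), inverted for caller-supplied occupancy and
#' brightness-ratio scenarios by `N_hat`.  When the confidence interval
#' of `a2` contains zero the ensemble never reached the nonlinear part of
#' the curve (`linear_regime` flag): the power sweep then constrains A
#' but not `<N>`.  An `a2` negative beyond its interval contradicts the
#' model and raises `model_violation`.
#'
#' @param ensemble A Type II [moment_ensemble()] spanning >= 3 laser powers.
#' @param through_origin Keep the polynomial origin-constrained (default
#'   `TRUE`, the model form); `FALSE` adds a free intercept as a diagnostic.
#' @param conf_level Confidence level for the parameter intervals.
#' @return List with `a1`, `a2`, `ci`, `linear_regime`, `model_violation`,
#'   the fitted `model` and `N_hat(occupancy, ratio)`, a function returning
#'   the molecule-number estimate for an assumed occupancy / brightness
#'   ratio.
#' @export
fit_type2 <- function(ensemble, through_origin = TRUE, conf_level = 0.95) {
  ensure_type(ensemble, "II")
  if ("power_rel" %in% names(ensemble) &&
      length(unique(stats::na.omit(ensemble$power_rel))) > 0 &&
      length(unique(stats::na.omit(ensemble$power_rel))) < 3L)
    stop("fit_type2: ensemble must span at least 3 laser powers", call. = FALSE)
  fit <- if (through_origin)
    stats::lm(var_F ~ 0 + mean_F + I(mean_F^2), data = ensemble)
  else
    stats::lm(var_F ~ mean_F + I(mean_F^2), data = ensemble)
  co <- stats::coef(fit)
  ci <- stats::confint(fit, level = conf_level)
  a1 <- unname(co[["mean_F"]])
  a2 <- unname(co[["I(mean_F^2)"]])
  ci_a2 <- ci["I(mean_F^2)", ]
  linear_regime <- ci_a2[1] <= 0 && ci_a2[2] >= 0
  model_violation <- ci_a2[2] < 0
  n_hat <- function(occupancy, ratio) {
    denom <- occupancy + ratio * (1 - occupancy)
    if (denom <= 0) stop("N_hat: degenerate occupancy/ratio", call. = FALSE)
    (occupancy + ratio^2 * (1 - occupancy)) / (a2 * denom^2)
  }
  list(a1 = a1, a2 = a2, ci = ci,
       linear_regime = linear_regime, model_violation = model_violation,
       N_hat = n_hat, model = fit)
}

#' Closed-form occupancy inversion of a basal moment pair
#'
#' Inverts the occupancy-sweep affine relation point by point: with
#' `y = A (1 + eps_b + eps_f) mean_F - var_F` (which equals
#' `A^2 N eps_b eps_f` under the model and must be positive), the
#' occupancy is `lambda = (A eps_f mean_F / y - r) / (1 - r)` with
#' `r = eps_f/eps_b`.  The molecule number cancels, so the inversion is
#' immune to region-to-region concentration differences.  Requires
#' `0 < eps_f < eps_b`.
#'
#' @param mean_F,var_F Moment pair(s) of basal-condition images.
#' @param gain,eps_bound,eps_free Model parameters.
#' @return List with `lambda` (NA where invalid), the excess-variance
#'   ratio `rho = (var_F - gain mean_F)/(gain mean_F)`, the affine
#'   intercept term `y = gain (1+eps_b+eps_f) mean_F - var_F` (must be
#'   positive under the model), and `valid`.
#' @export
invert_type3_occupancy <- function(mean_F, var_F, gain, eps_bound, eps_free) {
  stopifnot(gain > 0, eps_bound > 0, eps_free >= 0, eps_free <= eps_bound)
  # the excess-variance form of the same relation conditions best: the
  # molecule-number term rho depends on lambda alone
  rho <- (var_F - gain * mean_F) / (gain * mean_F)
  y <- gain * (1 + eps_bound + eps_free) * mean_F - var_F
  if (eps_free == 0) {
    # a perfectly dark free form leaves no basal-occupancy information
    lam <- rep(NA_real_, length(mean_F))
    return(list(lambda = lam, rho = rho, y = y,
                valid = rep(FALSE, length(mean_F))))
  }
  lam <- eps_free * (eps_free - rho) /
    (eps_bound * (rho - eps_bound) + eps_free * (eps_free - rho))
  valid <- is.finite(lam) & lam >= 0 & lam <= 1 & y > 0
  lam[!is.finite(lam)] <- NA_real_
  list(lambda = lam, rho = rho, y = y, valid = valid)
}

#' Fit a Type III (occupancy-sweep) moment ensemble
#'
#' Two-part analysis of a Ca2+-addition sweep.  The high-fluorescence
#' points (occupancy driven toward 1) follow the zero-intercept reduction
#' `var_F = A (1 + eps_b) mean_F`.  With the gain already calibrated,
#' that line is fitted in its excess-variance arrangement: an
#' origin-constrained regression of `var_F - A mean_F` on `A mean_F`,
#' whose slope is eps_b directly.  (Fitting the raw line and subtracting
#' 1 from `slope/A` is the same equation, but any percent-level slope
#' error is amplified several-fold by the subtraction; the excess form
#' avoids that.)  A short fixed-point refinement corrects for the high
#' points not being fully saturated (occupancy slightly below 1) and for
#' the free-dye contribution.  The low-fluorescence (basal) points are
#' then inverted one by one through [invert_type3_occupancy()]; points
#' violating the model (nonpositive intercept term) are excluded and
#' counted in `n_excluded`.  Because the estimate of eps_b depends on
#' how many points are kept in the high-F subset, the fit is repeated
#' over `sensitivity_cuts` and all values reported.
#'
#' @param ensemble A Type III [moment_ensemble()] spanning added-Ca levels.
#' @param gain Calibrated detector amplification A (from a Type I fit).
#' @param ratio Dye brightness ratio r = eps_free/eps_bound (a required
#'   dye property; there is no default).
#' @param high_q Quantile above which points enter the high-F fit
#'   (default 0.7, i.e. the top 30%).
#' @param low_q Quantile below which points enter the basal-occupancy
#'   inversion (default 0.3).
#' @param sensitivity_cuts High-F quantile cuts re-fitted for the
#'   sensitivity report.
#' @return List with `slope_high`, `eps_b_hat`, `eps_f_hat`,
#'   `lambda_points` (data frame of per-point inversions), `lambda_range`,
#'   `n_excluded`, and `sensitivity` (data frame of cut vs eps_b_hat).
#' @export
fit_type3 <- function(ensemble, gain, ratio, high_q = 0.7, low_q = 0.3,
                      sensitivity_cuts = c(0.6, 0.7, 0.8)) {
  ensure_type(ensemble, "III")
  stopifnot(gain > 0, ratio >= 0, ratio <= 1)
  fit_high <- function(q) {
    thr <- stats::quantile(ensemble$mean_F, q)
    sub <- ensemble[ensemble$mean_F >= thr, , drop = FALSE]
    if (nrow(sub) < 2L) return(NA_real_)
    x <- gain * sub$mean_F
    excess <- sub$var_F - x
    eb <- sum(excess * x) / sum(x^2)
    if (!is.finite(eb) || eb <= 0) return(NA_real_)
    # saturation / free-dye correction: the per-point excess ratio is
    # eps_b psi(lambda) with psi = (l + r^2(1-l))/(l + r(1-l)) <= 1
    for (it in 1:3) {
      inv <- invert_type3_occupancy(sub$mean_F, sub$var_F, gain, eb,
                                    ratio * eb)
      lam <- ifelse(inv$valid, inv$lambda, 1)
      psi <- (lam + ratio^2 * (1 - lam)) / (lam + ratio * (1 - lam))
      eb <- sum((excess / psi) * x) / sum(x^2)
    }
    eb
  }
  eps_b <- fit_high(high_q)
  if (is.na(eps_b) || eps_b <= 0)
    stop("fit_type3: high-F excess variance is nonpositive; cannot extract ",
         "a brightness", call. = FALSE)
  eps_f <- ratio * eps_b
  slope_high <- gain * (1 + eps_b + eps_f)
  sens <- data.frame(high_q = sensitivity_cuts,
                     eps_b_hat = vapply(sensitivity_cuts, fit_high,
                                        numeric(1)))
  thr_low <- stats::quantile(ensemble$mean_F, low_q)
  low <- ensemble[ensemble$mean_F <= thr_low, , drop = FALSE]
  inv <- invert_type3_occupancy(low$mean_F, low$var_F, gain, eps_b, eps_f)
  lambda_points <- data.frame(mean_F = low$mean_F, var_F = low$var_F,
                              y = inv$y, lambda = inv$lambda,
                              valid = inv$valid)
  lam_ok <- inv$valid
  list(slope_high = slope_high,
       eps_b_hat = eps_b,
       eps_f_hat = eps_f,
       lambda_points = lambda_points,
       lambda_range = if (any(lam_ok)) range(inv$lambda[lam_ok])
                      else c(NA_real_, NA_real_),
       n_excluded = sum(inv$y <= 0),
       sensitivity = sens)
}

#' Consolidate Type I/II/III fits into a calibration
#'
#' Combines the three stationary-experiment fits into one parameter set.
#' The consolidated detector amplification prefers the linear
#' coefficient of the Type II polynomial, which estimates A without
#' bias in every regime; the raw Type I slope overestimates A by the
#' factor `1 + eps_b phi(lambda, r)` with
#' `phi = (l + r^2 (1-l))/(l + r (1-l))`, which only vanishes for dim
#' dyes.  Without a Type II ensemble, A and eps_b are solved jointly by
#' alternating the Type I slope relation with the Type III brightness
#' extraction (with the basal occupancy re-estimated from the low-F
#' inversion each round).  The result then runs the self-consistency
#' checks: (a) the detector amplification
#' from the Type I slope must agree with the linear coefficient of the
#' Type II polynomial; (b) the molecule number from the Type II quadratic
#' coefficient must agree with the range obtained by inverting the mean
#' fluorescence (first moment) over the observed `<F>` range.  Agreement
#' means "within a factor of `consistency_factor`" (default 3); the
#' method is a moment method, not a joint likelihood, so factor-level
#' agreement is the meaningful scale.  Because the basal occupancy enters
#' the first-moment inversion, molecule numbers are evaluated over a grid
#' of occupancy scenarios and reported as ranges.
#'
#' @param type1 A Type I [moment_ensemble()] (required).
#' @param type2 Optional Type II ensemble.
#' @param type3 Optional Type III ensemble.  Without it the bound-dye
#'   brightness is reported as `NA` and occupancy-dependent predictions
#'   (e.g. [snr_analytic()]) cannot be built from the result.
#' @param ratio Dye brightness ratio r = eps_free/eps_bound (required).
#' @param lambda_grid Occupancy scenarios for the molecule-number
#'   inversion (default `c(0.05, 0.1, 0.3)`).
#' @param consistency_factor Tolerated factor between independent
#'   estimates before a flag is raised.
#' @param conf_level Confidence level passed to the fits.
#' @return An object of class `calibration_result`.
#' @export
calibrate <- function(type1, type2 = NULL, type3 = NULL, ratio,
                      lambda_grid = c(0.05, 0.1, 0.3),
                      consistency_factor = 3, conf_level = 0.95) {
  if (is.null(type2) && is.null(type3))
    stop("calibrate: need Type I plus at least one other ensemble",
         call. = FALSE)
  stopifnot(ratio >= 0, ratio <= 1)
  f1 <- fit_type1(type1, conf_level = conf_level)
  f2 <- if (!is.null(type2)) fit_type2(type2, conf_level = conf_level) else NULL

  f3 <- NULL
  if (!is.null(f2)) {
    # a1 is an unbiased gain estimate in every regime
    A <- f2$a1
    if (!is.null(type3)) f3 <- fit_type3(type3, gain = A, ratio = ratio)
  } else {
    # no power sweep: solve the Type I slope relation
    # s1 = A (1 + eps_b phi(lambda_b, r)) jointly with the Type III
    # brightness extraction by alternation, re-estimating the basal
    # occupancy each round
    A <- f1$A_hat
    for (iter in seq_len(100L)) {
      f3 <- fit_type3(type3, gain = A, ratio = ratio)
      lam_b <- stats::median(
        f3$lambda_points$lambda[f3$lambda_points$valid])
      if (!is.finite(lam_b)) lam_b <- stats::median(lambda_grid)
      phi <- (lam_b + ratio^2 * (1 - lam_b)) / (lam_b + ratio * (1 - lam_b))
      A_new <- f1$slope / (1 + f3$eps_b_hat * phi)
      if (abs(A_new - A) < 1e-8 * A) break
      A <- 0.5 * (A + A_new)   # damped step
    }
  }

  eps_b <- if (!is.null(f3)) f3$eps_b_hat else NA_real_
  eps_f <- if (!is.null(f3)) f3$eps_f_hat else NA_real_
  lambda_range <- if (!is.null(f3)) f3$lambda_range else c(NA_real_, NA_real_)

  flags <- list()
  # (a) A from the Type I slope vs a1 from the Type II polynomial
  if (!is.null(f2)) {
    fac <- max(f1$A_hat, f2$a1) / min(f1$A_hat, f2$a1)
    flags$gain_consistency <- list(A_type1 = f1$A_hat, a1_type2 = f2$a1,
                                   factor = fac,
                                   ok = fac <= consistency_factor)
    if (f2$linear_regime)
      flags$linear_regime <- list(
        ok = NA,
        note = paste("Type II quadratic coefficient is statistically zero:",
                     "the nonlinear part of the variance-mean curve was not",
                     "reached, so <N> is unconstrained by the power sweep"))
  }

  # <N> range from the first moment over the observed <F> range
  n_range <- NULL
  if (!is.na(eps_b)) {
    frange <- range(type1$mean_F)
    n_vals <- vapply(lambda_grid, function(l)
      frange / (A * (eps_b * l + eps_f * (1 - l))), numeric(2))
    n_range <- data.frame(lambda = rep(lambda_grid, each = 2),
                          bound = rep(c("min", "max"), length(lambda_grid)),
                          N = as.vector(n_vals))
  }

  # (b) <N> from Type II quadratic vs the first-moment inversion
  if (!is.null(f2) && !is.null(n_range) && !f2$linear_regime) {
    n2 <- vapply(lambda_grid, function(l) f2$N_hat(l, ratio), numeric(1))
    n1 <- vapply(lambda_grid, function(l) {
      v <- n_range$N[n_range$lambda == l]
      exp(mean(log(v)))
    }, numeric(1))
    fac <- max(n2 / n1, n1 / n2)
    flags$molecule_number_consistency <-
      list(N_type2 = n2, N_moment = n1, lambda = lambda_grid,
           factor = max(fac), ok = max(fac) <= consistency_factor)
  }

  gain_ci <- if (!is.null(f2)) f2$ci["mean_F", ] else f1$ci["mean_F", ]
  structure(list(gain = A, gain_ci = gain_ci,
                 eps_bound = eps_b, eps_free = eps_f, ratio = ratio,
                 n_range = n_range, lambda_basal_range = lambda_range,
                 fits = list(type1 = f1, type2 = f2, type3 = f3),
                 lambda_grid = lambda_grid,
                 consistency_factor = consistency_factor,
                 flags = flags),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Fluctuation-model calibration\n")
  cat(sprintf("  gain A        : %.4g  (CI %.4g .. %.4g)\n",
              x$gain, x$gain_ci[1], x$gain_ci[2]))
  cat(sprintf("  eps_bound     : %s\n",
              if (is.na(x$eps_bound)) "unavailable (no Type III ensemble)"
              else format(x$eps_bound, digits = 4)))
  cat(sprintf("  eps_free      : %s (r = %.4g)\n",
              if (is.na(x$eps_free)) "unavailable" else
                format(x$eps_free, digits = 4), x$ratio))
  if (!all(is.na(x$lambda_basal_range)))
    cat(sprintf("  basal lambda  : %.4g .. %.4g\n",
                x$lambda_basal_range[1], x$lambda_basal_range[2]))
  if (!is.null(x$n_range))
    cat(sprintf("  <N> range     : %.4g .. %.4g (over lambda scenarios %s)\n",
                min(x$n_range$N), max(x$n_range$N),
                paste(x$lambda_grid, collapse = ", ")))
  for (nm in names(x$flags)) {
    fl <- x$flags[[nm]]
    status <- if (isTRUE(fl$ok)) "ok" else if (isFALSE(fl$ok)) "FLAG" else "note"
    cat(sprintf("  check %-28s: %s\n", nm, status))
    if (!is.null(fl$note)) cat("    ", fl$note, "\n")
  }
  invisible(x)
}

#' Compare molecule numbers across concentration sets
#'
#' Third self-consistency check: the ratio of fitted molecule numbers
#' between two calibrations performed at different total dye
#' concentrations should match the concentration ratio (the confocal
#' volume is the same, so `<N>` is proportional to `[D]_T`).
#'
#' @param calibrations Named list of `calibration_result` objects.
#' @param dye_totals Named numeric vector of total dye concentrations
#'   (same names, micromolar).
#' @param consistency_factor Tolerated factor between the `<N>` ratio and
#'   the concentration ratio.
#' @return Data frame of pairwise comparisons with an `ok` column.
#' @export
consistency_across_sets <- function(calibrations, dye_totals,
                                    consistency_factor = 3) {
  stopifnot(length(calibrations) >= 2L,
            all(names(calibrations) %in% names(dye_totals)))
  nm <- names(calibrations)
  geo_n <- vapply(calibrations, function(cl) {
    if (is.null(cl$n_range)) return(NA_real_)
    exp(mean(log(cl$n_range$N)))
  }, numeric(1))
  pairs <- utils::combn(nm, 2)
  out <- data.frame(set_a = pairs[1, ], set_b = pairs[2, ])
  out$n_ratio <- geo_n[out$set_a] / geo_n[out$set_b]
  out$conc_ratio <- dye_totals[out$set_a] / dye_totals[out$set_b]
  fac <- out$n_ratio / out$conc_ratio
  out$factor <- pmax(fac, 1 / fac)
  out$ok <- out$factor <= consistency_factor
  rownames(out) <- NULL
  out
}

#' Build a fluctuation parameter set from a calibration
#'
#' @param calibration A `calibration_result`.
#' @param occupancy Occupancy to embed (e.g. the basal value).
#' @param mean_molecules Molecule number to embed.
#' @return A [fluct_params()] object.
#' @export
as_fluct_params <- function(calibration, occupancy, mean_molecules) {
  stopifnot(inherits(calibration, "calibration_result"))
  if (is.na(calibration$eps_bound))
    stop("calibration carries no bound-dye brightness (Type III ensemble ",
         "missing); occupancy-dependent outputs are unavailable", call. = FALSE)
  fluct_params(gain = calibration$gain,
               eps_bound = calibration$eps_bound,
               eps_free = calibration$eps_free,
               occupancy = occupancy,
               mean_molecules = mean_molecules)
}
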