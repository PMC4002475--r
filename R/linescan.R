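#' Linescan image container
#'
#' A confocal linescan is a repeated scan of one spatial line; the result
#' is a space-by-time array of photon-counting fluorescence values.  Rows
#' are spatial positions along the line, columns are successive line
#' scans.
#'
#' @param values Numeric matrix of nonnegative fluorescence values
#'   (rows = space, columns = time).
#' @param pixel_um Spatial pixel size (micrometers).
#' @param line_ms Line period (milliseconds).
#' @param dwell_us Pixel dwell time (microseconds), optional.
#' @param annotations Named list of per-image experiment annotations;
#'   recognised fields are `image_id`, `type` (one of `"0"`, `"I"`, `"II"`,
#'   `"III"`), `power_rel` (laser power relative to the standard
#'   illumination), `region` (cytosolic region id) and `ca_added`
#'   (micromolar Ca2+ added on top of basal).
#' @return An object of class `linescan_image`.
#' @export
linescan_image <- function(values, pixel_um, line_ms, dwell_us = NA_real_,
                           annotations = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(values) == 0L)
    stop("linescan_image: 'values' must be a nonempty numeric matrix",
         call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("linescan_image: fluorescence values must be finite and >= 0",
         call. = FALSE)
  stopifnot(is.numeric(pixel_um), pixel_um > 0, is.numeric(line_ms), line_ms > 0)
  ann <- modifyList(list(image_id = NA_character_, type = NA_character_,
                         power_rel = NA_real_, region = NA_character_,
                         ca_added = NA_real_),
                    as.list(annotations))
  structure(list(values = values, pixel_um = as.numeric(pixel_um),
                 line_ms = as.numeric(line_ms), dwell_us = as.numeric(dwell_us),
                 annotations = ann),
            class = "linescan_image")
}

#' @export
print.linescan_image <- function(x, ...) {
  cat(sprintf("Linescan image: %d spatial rows x %d lines (%.3g um/px, %.3g ms/line)\n",
              nrow(x$values), ncol(x$values), x$pixel_um, x$line_ms))
  a <- x$annotations
  cat(sprintf("  id=%s type=%s power_rel=%s region=%s ca_added=%s\n",
              a$image_id, a$type, format(a$power_rel), a$region,
              format(a$ca_added)))
  invisible(x)
}

#' Time-averaged fluorescence profile
#'
#' Arithmetic mean over time of each spatial row, the first step of the
#' bright-fringe (cytosol) detection.
#'
#' @param image A [linescan_image()].
#' @return Numeric vector, one value per spatial row.
#' @export
time_average_profile <- function(image) {
  stopifnot(inherits(image, "linescan_image"))
  if (ncol(image$values) < 2L)
    stop("time_average_profile: need at least 2 time columns", call. = FALSE)
  rowMeans(image$values)
}

#' Detect bright (cytosolic) fringes of a linescan
#'
#' In Xenopus oocytes the cortical granules show up as persistently dark
#' horizontal fringes; the cytosol forms bright fringes.  A row is called
#' bright when its time-averaged fluorescence f(x) satisfies
#' `f(x) >= mu_f + k * sigma_f`, where mu_f and sigma_f are the mean and
#' standard deviation of the profile.  The default `k = 0` (threshold at
#' the profile mean) separates the two populations whenever the granule
#' rows are strongly dark; `k` is recorded in the returned mask so that
#' downstream tables are reproducible.
#'
#' @param profile Time-averaged profile from [time_average_profile()].
#' @param k Threshold offset in units of sigma_f (default 0).
#' @return An object of class `fringe_mask` with fields `bright` (logical
#'   vector), `k`, `mu`, `sigma` and `failed` (`TRUE` when no row passes;
#'   a warning is emitted rather than returning a silently empty mask).
#' @export
detect_bright_fringes <- function(profile, k = 0) {
  stopifnot(is.numeric(profile), length(profile) >= 1L, is.finite(k) || is.infinite(k))
  mu <- mean(profile)
  sigma <- stats::sd(profile)
  if (is.na(sigma)) sigma <- 0  # single-row profile
  bright <- profile >= mu + k * sigma
  failed <- !any(bright)
  if (failed)
    warning("detect_bright_fringes: no bright rows at k = ", k, call. = FALSE)
  structure(list(bright = bright, k = k, mu = mu, sigma = sigma,
                 failed = failed),
            class = "fringe_mask")
}

#' Pooled moments of the bright-fringe pixels
#'
#' Mean and variance of the fluorescence pooled over every pixel (all
#' times, all bright rows) of a linescan image; per the stationarity
#' assumption no per-row weighting is applied.  The sample (n - 1)
#' variance is the default; the population variance is available because
#' at typical pixel counts (10^4-10^5) the two are indistinguishable but
#' the convention should be explicit.
#'
#' @param image A [linescan_image()].
#' @param mask A `fringe_mask` from [detect_bright_fringes()].
#' @param var_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return A one-row data frame of class `moment_sample` with columns
#'   `image_id`, `type`, `power_rel`, `region`, `ca_added`, `mean_F`,
#'   `var_F`, `n_pixels`.
#' @export
bright_moments <- function(image, mask, var_type = c("sample", "population")) {
  stopifnot(inherits(image, "linescan_image"), inherits(mask, "fringe_mask"))
  var_type <- match.arg(var_type)
  if (length(mask$bright) != nrow(image$values))
    stop("bright_moments: mask length does not match image rows", call. = FALSE)
  if (!any(mask$bright))
    stop("bright_moments: mask has no bright rows", call. = FALSE)
  px <- as.vector(image$values[mask$bright, , drop = FALSE])
  if (length(px) < 2L)
    stop("bright_moments: need at least 2 pixels", call. = FALSE)
  m <- mean(px)
  v <- stats::var(px)
  if (var_type == "population") v <- v * (length(px) - 1) / length(px)
  a <- image$annotations
  out <- data.frame(image_id = a$image_id, type = a$type,
                    power_rel = a$power_rel, region = a$region,
                    ca_added = a$ca_added,
                    mean_F = m, var_F = v, n_pixels = length(px),
                    stringsAsFactors = FALSE)
  class(out) <- c("moment_sample", class(out))
  out
}

#' Normalize a linescan by its per-row baseline
#'
#' Computes F(x, t) / F0(x) with F0(x) the time average of row x over a
#' baseline window preceding signal evocation.  Row-wise normalization
#' minimizes artifacts from spatial heterogeneities (uneven dye loading,
#' granule shadows).  Rows whose baseline is zero cannot be normalized and
#' come back as `NA` with an attribute flag.
#'
#' @param image A [linescan_image()].
#' @param baseline Integer vector of time-column indices forming the
#'   baseline window (default: first 10 columns or all columns before
#'   `ncol/5`, whichever is larger).
#' @return Numeric matrix of ratios with attribute `zero_baseline_rows`
#'   (integer indices of rows that could not be normalized).
#' @export
f_over_f0 <- function(image, baseline = NULL) {
  stopifnot(inherits(image, "linescan_image"))
  nt <- ncol(image$values)
  if (is.null(baseline))
    baseline <- seq_len(max(10L, nt %/% 5L))
  baseline <- as.integer(baseline)
  if (any(baseline < 1L | baseline > nt))
    stop("f_over_f0: baseline window outside the image", call. = FALSE)
  f0 <- rowMeans(image$values[, baseline, drop = FALSE])
  zero <- which(f0 <= 0)
  f0[f0 <= 0] <- NA_real_
  out <- image$values / f0
  attr(out, "zero_baseline_rows") <- zero
  if (length(zero))
    warning("f_over_f0: ", length(zero), " row(s) with zero baseline flagged NA",
            call. = FALSE)
  out
}

#' One-call preprocessing of a linescan image
#'
#' Runs bright-fringe detection on the time-averaged profile and extracts
#' the pooled moment sample.  Fringe preprocessing is only needed when the
#' profile is bimodal (dark granule rows present); when the coefficient of
#' variation of the profile falls below `bimodality_cv` the mask step is
#' skipped and all rows are used.
#'
#' @inheritParams bright_moments
#' @param k Threshold offset passed to [detect_bright_fringes()].
#' @param bimodality_cv Profile SD/mean below which no fringe masking is
#'   applied (default 0.2).
#' @return A `moment_sample` (see [bright_moments()]); the mask used is
#'   attached as attribute `"mask"`.
#' @export
extract_moments <- function(image, k = 0, bimodality_cv = 0.2,
                            var_type = c("sample", "population")) {
  prof <- time_average_profile(image)
  cv <- stats::sd(prof) / mean(prof)
  mask <- if (is.finite(cv) && cv > bimodality_cv) {
    detect_bright_fringes(prof, k = k)
  } else {
    structure(list(bright = rep(TRUE, length(prof)), k = NA_real_,
                   mu = mean(prof), sigma = stats::sd(prof), failed = FALSE),
              class = "fringe_mask")
  }
  out <- bright_moments(image, mask, var_type = match.arg(var_type))
  attr(out, "mask") <- mask
  out
}
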