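#' Fluctuation-model parameter set
#'
#' Container for the five parameters of the single-wavelength-dye
#' fluorescence fluctuation model: the detector amplification `gain` (A),
#' the molecular brightnesses of the Ca2+-bound and Ca2+-free forms of the
#' dye `eps_bound` / `eps_free` (detected photons per molecule per pixel
#' dwell), the probability `occupancy` that a dye molecule is Ca2+-bound,
#' and `mean_molecules`, the mean number of dye molecules contributing to
#' one pixel.
#'
#' The free form of a single-wavelength indicator is dimmer than the bound
#' form, so `eps_free <= eps_bound` is enforced; their ratio
#' `r = eps_free/eps_bound` is a dye property (of the order of the ratio of
#' the quantum efficiencies of the two forms) and does not change with
#' laser power.
#'
#' @param gain Detector amplification factor A (> 0, dimensionless).
#' @param eps_bound Brightness of the Ca2+-bound dye (photons/molecule/dwell, > 0).
#' @param eps_free Brightness of the Ca2+-free dye (>= 0, <= `eps_bound`).
#' @param occupancy Probability a dye molecule is Ca2+-bound, in \[0, 1\].
#' @param mean_molecules Mean number of dye molecules per pixel (> 0).
#' @return An object of class `fluct_params`.
#' @examples
#' p <- fluct_params(gain = 2, eps_bound = 0.1, eps_free = 0.01,
#'                   occupancy = 0.25, mean_molecules = 100)
#' mean_fluorescence(p)
#' @export
fluct_params <- function(gain, eps_bound, eps_free, occupancy, mean_molecules) {
  p <- list(gain = as.numeric(gain),
            eps_bound = as.numeric(eps_bound),
            eps_free = as.numeric(eps_free),
            occupancy = as.numeric(occupancy),
            mean_molecules = as.numeric(mean_molecules))
  validate_fluct_params(p)
  structure(p, class = "fluct_params")
}

validate_fluct_params <- function(p) {
  num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  for (f in c("gain", "eps_bound", "eps_free", "occupancy", "mean_molecules"))
    if (!num1(p[[f]]))
      stop("fluct_params: '", f, "' must be a single finite number", call. = FALSE)
  if (p$gain <= 0) stop("fluct_params: gain must be > 0", call. = FALSE)
  if (p$eps_bound <= 0) stop("fluct_params: eps_bound must be > 0", call. = FALSE)
  if (p$eps_free < 0) stop("fluct_params: eps_free must be >= 0", call. = FALSE)
  if (p$eps_free > p$eps_bound)
    stop("fluct_params: eps_free must not exceed eps_bound", call. = FALSE)
  if (p$occupancy < 0 || p$occupancy > 1)
    stop("fluct_params: occupancy must lie in [0, 1]", call. = FALSE)
  if (p$mean_molecules <= 0)
    stop("fluct_params: mean_molecules must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.fluct_params <- function(x, ...) {
  cat("Fluctuation model parameters\n")
  cat(sprintf("  gain (A)            : %g\n", x$gain))
  cat(sprintf("  eps_bound           : %g photons/molecule/dwell\n", x$eps_bound))
  cat(sprintf("  eps_free            : %g photons/molecule/dwell (r = %.4g)\n",
              x$eps_free, brightness_ratio(x)))
  cat(sprintf("  occupancy (lambda)  : %g\n", x$occupancy))
  cat(sprintf("  mean_molecules <N>  : %g\n", x$mean_molecules))
  invisible(x)
}

#' Brightness ratio of a parameter set
#'
#' Ratio `r = eps_free/eps_bound`, a fixed property of the dye that is
#' independent of laser power.
#'
#' @param params A [fluct_params()] object.
#' @return A number in \[0, 1\].
#' @export
brightness_ratio <- function(params) {
  validate_fluct_params(params)
  params$eps_free / params$eps_bound
}

#' Replace fields of a parameter set
#'
#' Convenience constructor used throughout the package to vary one model
#' parameter (for example the occupancy during a signal) while keeping the
#' rest fixed.
#'
#' @param params A [fluct_params()] object.
#' @param ... Named fields to replace (`gain`, `eps_bound`, `eps_free`,
#'   `occupancy`, `mean_molecules`).
#' @return A new `fluct_params` object.
#' @export
update_fluct_params <- function(params, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), c("gain", "eps_bound", "eps_free",
                                "occupancy", "mean_molecules"))
  if (length(bad)) stop("unknown fluct_params field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p <- unclass(params)
  p[names(repl)] <- lapply(repl, as.numeric)
  do.call(fluct_params, p)
}

#' Read / write fluctuation parameters as a flat key-value config
#'
#' Parameters serialize to a flat JSON (or YAML) mapping with keys
#' `gain`, `eps_bound`, `eps_free`, `occupancy`, `mean_molecules`.
#'
#' @param params A [fluct_params()] object.
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_fluct_params` returns a `fluct_params` object;
#'   `write_fluct_params` returns `path` invisibly.
#' @export
write_fluct_params <- function(params, path) {
  validate_fluct_params(params)
  x <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML output", call. = FALSE)
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_fluct_params
#' @export
read_fluct_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML input", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  need <- c("gain", "eps_bound", "eps_free", "occupancy", "mean_molecules")
  if (!all(need %in% names(x)))
    stop("parameter file misses key(s): ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  do.call(fluct_params, x[need])
}
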