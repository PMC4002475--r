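## Radial finite-volume machinery.
##
## Cells i = 1..n span [(i-1) dr, i dr]; concentrations live at cell
## centers r_i = (i - 1/2) dr.  Fluxes cross the faces at i dr with area
## 4 pi (i dr)^2, which makes the discrete divergence telescoping: with
## no-flux boundaries the scheme conserves the volume integral of each
## field to solver tolerance.  The stencil is first-neighbor and
## second-order accurate; the r = 0 regularity condition is automatic
## because the innermost face has zero area.

rd_grid <- function(config) {
  n <- round(config$radius_um / config$dr_um)
  if (abs(n * config$dr_um - config$radius_um) > 1e-9)
    stop("rd grid: radius must be an integer multiple of dr", call. = FALSE)
  dr <- config$dr_um
  faces <- (0:n) * dr
  centers <- (seq_len(n) - 0.5) * dr
  volumes <- 4 * pi / 3 * diff(faces^3)
  areas <- 4 * pi * faces^2  # length n + 1; areas[1] = 0
  list(n = n, dr = dr, centers = centers, faces = faces,
       volumes = volumes, areas = areas)
}

## Cached backward-Euler diffusion operator (I - dt L) for one D;
## returns a sparseLU factorisation reusable every step.
diffusion_factor <- function(grid, D, dt_s) {
  n <- grid$n
  cond <- D * grid$areas / grid$dr           # face conductances
  sup <- cond[2:n] / grid$volumes[1:(n - 1)] # coupling to the outer neighbor
  sub <- cond[2:n] / grid$volumes[2:n]       # coupling to the inner neighbor
  diag_main <- numeric(n)
  diag_main[1:(n - 1)] <- diag_main[1:(n - 1)] + sup
  diag_main[2:n] <- diag_main[2:n] + sub
  M <- Matrix::bandSparse(n, n, k = -1:1,
                          diagonals = list(-dt_s * sub,
                                           1 + dt_s * diag_main,
                                           -dt_s * sup))
  Matrix::lu(M)
}

## Implicit reaction + source + pump substep, vectorized over nodes.
## Backward Euler turns the per-node coupled system into a single scalar
## equation for the new free Ca: every bound concentration is an explicit
## monotone function of it, and total mass closes the system.  The
## residual is strictly increasing, so Newton converges to the unique
## root.
reaction_substep <- function(ca, bound, species, dt_s, source_rate,
                             pump_rate, ca_basal) {
  ns <- length(species)
  target <- ca + dt_s * source_rate +
    (if (ns) Reduce(`+`, lapply(seq_len(ns), function(j) bound[[j]])) else 0)
  bound_new_at <- function(j, c) {
    sp <- species[[j]]
    (bound[[j]] + dt_s * sp$kon * c * sp$total) /
      (1 + dt_s * (sp$kon * c + sp$koff))
  }
  c <- ca
  for (it in seq_len(60L)) {
    g <- c + dt_s * pump_rate * (c - ca_basal) - target
    dg <- rep(1 + dt_s * pump_rate, length(c))
    for (j in seq_len(ns)) {
      sp <- species[[j]]
      u <- 1 + dt_s * (sp$kon * c + sp$koff)
      bj <- (bound[[j]] + dt_s * sp$kon * c * sp$total) / u
      g <- g + bj
      dg <- dg + dt_s * sp$kon * (sp$total - bj) / u
    }
    step <- g / dg
    c <- c - step
    c[c < 0] <- 0
    if (max(abs(step)) < 1e-13 * max(1, max(c))) break
    if (it == 60L)
      stop("reaction substep: Newton failed to converge (max residual ",
           format(max(abs(g))), ")", call. = FALSE)
  }
  list(ca = c,
       bound = lapply(seq_len(ns), function(j) bound_new_at(j, c)),
       pumped_conc = dt_s * pump_rate * (c - ca_basal))
}

#' Equilibrated initial state of a reaction-diffusion configuration
#'
#' All concentrations are uniform, free Ca2+ sits at its basal value and
#' every buffer is in binding equilibrium with it, so the state is an
#' exact fixed point of the dynamics in the absence of a source.
#'
#' @param config An [rd_config()].
#' @return List with `ca` (vector over radial cells) and `bound` (list of
#'   vectors, one per species).
#' @export
equilibrium_init <- function(config) {
  stopifnot(inherits(config, "rd_config"))
  grid <- rd_grid(config)
  ca <- rep(config$ca_basal, grid$n)
  bound <- lapply(config$species, function(sp)
    rep(sp$total * equilibrium_bound_fraction(sp, config$ca_basal), grid$n))
  names(bound) <- vapply(config$species, `[[`, "", "name")
  list(ca = ca, bound = bound)
}

#' Run the reaction-diffusion simulation
#'
#' Backward-Euler time marching from the equilibrium initial state.
#' Each step solves the stiff reaction / source / pump system implicitly
#' per node (Newton), then the diffusion of every mobile field implicitly
#' with a cached tridiagonal factorization.  The channel-cluster source
#' injects into the innermost radial shell from t = 0 until each
#' channel's sampled closing time.
#'
#' @param config An [rd_config()].
#' @param closings Optional vector of channel closing times (ms) to reuse
#'   a source realization across runs; by default sampled from the
#'   source's exponential open-time distribution.
#' @param seed Optional integer seed for the closing-time draw.
#' @param record_every Record a frame every this many steps (default
#'   chosen to keep about 200 frames).
#' @return An object of class `rd_solution`: radial cell centers `r_um`,
#'   recorded times `t_ms`, matrices `ca` and `bound[[species]]`
#'   (frames x cells, uM), cumulative `injected_ions` and `pumped_ions`
#'   per frame, the `closings` used and the `config`.
#' @export
rd_run <- function(config, closings = NULL, seed = NULL, record_every = NULL) {
  stopifnot(inherits(config, "rd_config"))
  grid <- rd_grid(config)
  dt_s <- config$dt_ms / 1000
  nsteps <- ceiling(config$t_end_ms / config$dt_ms)
  if (is.null(record_every))
    record_every <- max(1L, nsteps %/% 200L)

  src <- config$source
  if (!is.null(src) && src$kind == "puff" && is.null(closings))
    closings <- sample_open_durations(src, seed = seed)

  flux_at <- function(t_ms) {
    if (is.null(src)) return(0)
    if (src$kind == "constant")
      return(if (t_ms < src$duration_ms) src$flux_ions_per_s else 0)
    src$flux_ions_per_s * sum(closings > t_ms)
  }

  state <- equilibrium_init(config)
  mobile <- vapply(config$species, function(sp) sp$D > 0, logical(1))
  lu_ca <- diffusion_factor(grid, config$D_ca, dt_s)
  lu_sp <- lapply(seq_along(config$species), function(j)
    if (mobile[j]) diffusion_factor(grid, config$species[[j]]$D, dt_s) else NULL)

  frames <- seq(0L, nsteps, by = record_every)
  if (frames[length(frames)] != nsteps) frames <- c(frames, nsteps)
  nf <- length(frames)
  rec_ca <- matrix(NA_real_, nf, grid$n)
  rec_bound <- lapply(config$species, function(sp) matrix(NA_real_, nf, grid$n))
  names(rec_bound) <- names(state$bound)
  rec_inj <- rec_pump <- numeric(nf)
  rec_t <- frames * config$dt_ms

  store <- function(fi, inj, pump) {
    rec_ca[fi, ] <<- state$ca
    for (j in seq_along(rec_bound)) rec_bound[[j]][fi, ] <<- state$bound[[j]]
    rec_inj[fi] <<- inj
    rec_pump[fi] <<- pump
  }
  injected <- pumped <- 0
  fi <- 1L
  store(fi, injected, pumped)

  src_vec <- numeric(grid$n)
  for (step in seq_len(nsteps)) {
    t_mid <- (step - 0.5) * config$dt_ms
    flux <- flux_at(t_mid)
    src_vec[1] <- flux / (IONS_PER_UM3_PER_UM * grid$volumes[1])
    rs <- reaction_substep(state$ca, state$bound, config$species, dt_s,
                           src_vec, config$pump_rate, config$ca_basal)
    injected <- injected + flux * dt_s
    pumped <- pumped +
      sum(rs$pumped_conc * grid$volumes) * IONS_PER_UM3_PER_UM
    state$ca <- as.numeric(Matrix::solve(lu_ca, rs$ca))
    state$bound <- rs$bound
    for (j in seq_along(state$bound))
      if (mobile[j])
        state$bound[[j]] <- as.numeric(Matrix::solve(lu_sp[[j]],
                                                     state$bound[[j]]))
    names(state$bound) <- names(rec_bound)
    if (any(state$ca < -1e-12) ||
        any(vapply(state$bound, function(b) any(b < -1e-12), logical(1))))
      stop("rd_run: negative concentration at step ", step, call. = FALSE)
    if (step %in% frames) {
      fi <- fi + 1L
      store(fi, injected, pumped)
    }
  }

  structure(list(r_um = grid$centers, t_ms = rec_t, ca = rec_ca,
                 bound = rec_bound, injected_ions = rec_inj,
                 pumped_ions = rec_pump, closings = closings,
                 config = config, grid = grid),
            class = "rd_solution")
}

#' @export
print.rd_solution <- function(x, ...) {
  cat(sprintf("RD solution: %d radial cells (dr %.3g um, R %.3g um), %d frames to %.3g ms\n",
              length(x$r_um), x$config$dr_um, x$config$radius_um,
              length(x$t_ms), max(x$t_ms)))
  cat(sprintf("  species: %s\n",
              paste(names(x$bound), collapse = ", ")))
  cat(sprintf("  injected %.4g ions, pumped %.4g ions\n",
              max(x$injected_ions), max(x$pumped_ions)))
  invisible(x)
}

#' Mass-balance verification of a solution
#'
#' Bookkeeping harness: at every recorded frame the total Ca2+ content
#' (free plus bound, volume-integrated, in ions) is compared with the
#' initial content plus cumulative injection minus cumulative pumping.
#' Per-species conservation (free + bound = total) holds identically in
#' this formulation because free concentrations are carried as
#' `total - bound`; the report instead records the worst negative-margin
#' of each species, which is the meaningful failure mode.
#'
#' @param solution An `rd_solution` from [rd_run()].
#' @return List with `balance` (data frame: `t_ms`, `total_ions`,
#'   `expected_ions`, `rel_imbalance`), `max_rel_imbalance`, and
#'   `species_min` (per-species minimum of `total - bound`, uM).
#' @export
mass_balance_report <- function(solution) {
  stopifnot(inherits(solution, "rd_solution"))
  V <- solution$grid$volumes
  tot_conc <- solution$ca
  for (b in solution$bound) tot_conc <- tot_conc + b
  total_ions <- as.numeric(tot_conc %*% V) * IONS_PER_UM3_PER_UM
  expected <- total_ions[1] + solution$injected_ions - solution$pumped_ions
  rel <- (total_ions - expected) / pmax(expected, .Machine$double.eps)
  species_min <- vapply(seq_along(solution$bound), function(j)
    min(solution$config$species[[j]]$total - solution$bound[[j]]),
    numeric(1))
  names(species_min) <- names(solution$bound)
  list(balance = data.frame(t_ms = solution$t_ms, total_ions = total_ions,
                            expected_ions = expected, rel_imbalance = rel),
       max_rel_imbalance = max(abs(rel)),
       species_min = species_min)
}

#' Calibrate the per-channel source flux to a target peak occupancy
#'
#' Adjusts the per-channel Ca2+ flux so that the peak of the
#' PSF-blurred bound-dye occupancy reaches `target_lambda_peak`
#' (default twice the basal occupancy, i.e. a signal of the order of the
#' smallest detectable one).  The response of the peak occupancy to the
#' flux is close to linear for small signals; a few fixed-point
#' rescalings suffice.
#'
#' @param config An [rd_config()] with a puff source.
#' @param psf A [psf_params()].
#' @param scan_x Scan positions (um) passed to [blur_radial_field()].
#' @param closings Channel closing times (ms) reused across iterations so
#'   the calibration targets one source realization.
#' @param target_lambda_peak Desired peak occupancy (default
#'   `2 * basal occupancy` of the dye).
#' @param iterations Number of rescaling iterations (default 4).
#' @return The calibrated [rd_config()] (flux updated in its source),
#'   with attributes `flux_ions_per_s` and `achieved_lambda_peak`.
#' @export
calibrate_source_flux <- function(config, psf, scan_x, closings,
                                  target_lambda_peak = NULL,
                                  iterations = 4L) {
  stopifnot(inherits(config, "rd_config"),
            !is.null(config$source), config$source$kind == "puff")
  dye <- config$species[[which(vapply(config$species, `[[`, "", "name") == "dye")]]
  lam_basal <- equilibrium_bound_fraction(dye, config$ca_basal)
  if (is.null(target_lambda_peak)) target_lambda_peak <- 2 * lam_basal
  flux <- config$source$flux_ions_per_s
  achieved <- NA_real_
  for (i in seq_len(iterations)) {
    config$source$flux_ions_per_s <- flux
    sol <- rd_run(config, closings = closings)
    bp <- blur_radial_field(sol, psf, scan_x)
    achieved <- max(bp$occupancy)
    if (abs(achieved - target_lambda_peak) < 1e-3 * target_lambda_peak) break
    # rescale the flux by the ratio of occupancy elevations above basal
    flux <- flux * (target_lambda_peak - lam_basal) /
      max(achieved - lam_basal, 1e-12)
  }
  config$source$flux_ions_per_s <- flux
  attr(config, "flux_ions_per_s") <- flux
  attr(config, "achieved_lambda_peak") <- achieved
  config
}
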