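# Synthetic FRAP data: analytic recovery traces and full 2-D image stacks
# with known ground truth, standing in for the microscope.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Conditions of a synthetic FRAP experiment. The defaults reproduce the
#' reference acquisition: a 10 um-diameter spot bleached in a 50 um x 50 um
#' field imaged at 128 x 128 px, 100 post-bleach frames at 0.5 s intervals
#' after 5 pre-bleach frames, a deep (95%) bleach, and 1% Gaussian read
#' noise. The membrane itself is simulated on a periodic domain
#' `pad_factor` times the imaged field (same pixel size) and the camera
#' records the central field, so the field of view behaves as a window into
#' a much larger bilayer.
#'
#' @param d_true ground-truth lateral diffusion coefficient, um^2/s (> 0).
#' @param geometry a [bleach_geometry()].
#' @param grid_size camera pixels across the field (default 128).
#' @param n_frames post-bleach frames (default 100).
#' @param n_prebleach pre-bleach frames (default 5).
#' @param immobile_fraction fraction of fluorophores that never diffuses,
#'   in [0, 1).
#' @param bleach_depth fraction of fluorescence destroyed inside the spot,
#'   in (0, 1] (default 0.95).
#' @param noise_sd Gaussian noise SD relative to the local intensity
#'   (multiplicative noise; default 0.01, i.e. 1%).
#' @param shot_noise add Poisson shot noise before the read noise?
#' @param photons_per_unit mean photon count at unit intensity when
#'   `shot_noise = TRUE`.
#' @param acquisition_bleach_rate per-frame fractional loss from imaging
#'   illumination (applied to whole frames; cancelled by the double
#'   normalization).
#' @param pad_factor membrane extent as a multiple of the field (default 2);
#'   the periodic simulation domain must be at least 5 spot radii wide.
#' @param seed integer seed; identical seeds give bit-identical data. Draws
#'   are made frame by frame, Poisson before Gaussian.
#' @return A `frap_sim_config` object (named list).
#' @export
frap_sim_config <- function(d_true,
                            geometry = bleach_geometry(),
                            grid_size = 128L,
                            n_frames = 100L,
                            n_prebleach = 5L,
                            immobile_fraction = 0,
                            bleach_depth = 0.95,
                            noise_sd = 0.01,
                            shot_noise = FALSE,
                            photons_per_unit = 1e4,
                            acquisition_bleach_rate = 0,
                            pad_factor = 2L,
                            seed = NULL) {
  stopifnot(inherits(geometry, "bleach_geometry"))
  if (!is.numeric(d_true) || length(d_true) != 1L || d_true <= 0) {
    .hs_error("`d_true` must be a single positive number (um^2/s).", "hydrasense_sim_error")
  }
  if (immobile_fraction < 0 || immobile_fraction >= 1) {
    .hs_error("`immobile_fraction` must be in [0, 1).", "hydrasense_sim_error")
  }
  if (bleach_depth <= 0 || bleach_depth > 1) {
    .hs_error("`bleach_depth` must be in (0, 1].", "hydrasense_sim_error")
  }
  if (noise_sd < 0 || acquisition_bleach_rate < 0 || acquisition_bleach_rate >= 1) {
    .hs_error("noise and acquisition-bleach parameters must be non-negative (rate < 1).",
              "hydrasense_sim_error")
  }
  if (n_frames < 2L || n_prebleach < 1L || grid_size < 16L || pad_factor < 1) {
    .hs_error("degenerate grid/frame configuration.", "hydrasense_sim_error")
  }
  structure(
    list(
      d_true = d_true, geometry = geometry, grid_size = as.integer(grid_size),
      n_frames = as.integer(n_frames), n_prebleach = as.integer(n_prebleach),
      immobile_fraction = immobile_fraction, bleach_depth = bleach_depth,
      noise_sd = noise_sd, shot_noise = isTRUE(shot_noise),
      photons_per_unit = photons_per_unit,
      acquisition_bleach_rate = acquisition_bleach_rate,
      pad_factor = as.integer(pad_factor), seed = seed
    ),
    class = "frap_sim_config"
  )
}

#' Simulate an analytic recovery trace
#'
#' Draws a normalized recovery trace directly from the forward model
#' \eqn{F(t_i) = b + a f(t_i; \tau_D)} with \eqn{\tau_D = w^2/(4 D)},
#' `b = 1 - bleach_depth` and `a = (1 - b)(1 - immobile_fraction)`, plus
#' seeded Gaussian noise. Frame times follow the mid-exposure convention
#' `t_i = (i - 0.5) * frame_interval`.
#'
#' @param config a [frap_sim_config()].
#' @return List with elements `trace` (a [recovery_trace()]) and `truth`
#'   (ground-truth record: `d_true`, `tau_d`, `a`, `b`, `plateau`).
#' @examples
#' sim <- simulate_trace(frap_sim_config(d_true = 5.35, noise_sd = 0, seed = 1))
#' fit_recovery(sim$trace, bleach_geometry())$d
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  g <- config$geometry
  tau_d <- g$spot_radius_w^2 / (4 * config$d_true)
  t <- (seq_len(config$n_frames) - 0.5) * g$frame_interval
  b <- 1 - config$bleach_depth
  a <- (1 - b) * (1 - config$immobile_fraction)
  f <- recovery_model(t, a, b, tau_d)
  # relative noise: SD proportional to the local intensity
  y <- .with_seed(config$seed, f * (1 + stats::rnorm(length(t), 0, config$noise_sd)))
  trace <- recovery_trace(t, pmin(pmax(y, 0), 1.5))
  list(
    trace = trace,
    truth = list(d_true = config$d_true, tau_d = tau_d, a = a, b = b, plateau = a + b)
  )
}

#' Simulate a full FRAP image stack
#'
#' Forward-simulates the imaging experiment: a uniform fluorophore field on
#' a periodic membrane domain (`pad_factor` times the camera field, same
#' pixel size); at the bleach, the concentration inside the ideal sharp-edged
#' disk is multiplied by `1 - bleach_depth`; the mobile pool then evolves by
#' free 2-D diffusion computed spectrally (multiplication with the Gaussian
#' Green's function in Fourier space, exact for periodic boundaries) while
#' the immobile pool stays frozen. Optional global exponential acquisition
#' bleaching, Poisson shot noise and Gaussian read noise are applied in that
#' order, frame by frame. The returned stack is the central camera field.
#'
#' @param config a [frap_sim_config()].
#' @return List with elements `stack` (a [frap_stack()]) and `truth`
#'   (ground truth: `d_true`, `tau_d`, plus `domain_total` - the per-frame
#'   total fluorophore over the full simulation domain before noise and
#'   acquisition bleaching, which diffusion must conserve).
#' @export
simulate_stack <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  g <- config$geometry
  w <- g$spot_radius_w
  n <- config$grid_size
  px <- g$field_size / n
  nbig <- n * config$pad_factor
  membrane <- nbig * px
  if (membrane < 5 * w) {
    .hs_error(
      "bleached spot too large for the periodic membrane domain (needs >= 5 spot radii); increase `pad_factor` or the field size.",
      "hydrasense_sim_error"
    )
  }
  tau_d <- w^2 / (4 * config$d_true)

  pos <- (seq_len(nbig) - 0.5) * px
  ctr <- membrane / 2
  r2 <- outer((pos - ctr)^2, (pos - ctr)^2, `+`)
  bleach_mask <- r2 <= w^2

  field0 <- matrix(1, nbig, nbig)
  bleached <- field0
  bleached[bleach_mask] <- 1 - config$bleach_depth
  mobile0 <- (1 - config$immobile_fraction) * bleached
  immobile <- config$immobile_fraction * bleached

  freq <- c(0:(nbig %/% 2), -((nbig - nbig %/% 2 - 1):1)) / (nbig * px)
  k2 <- outer((2 * pi * freq)^2, (2 * pi * freq)^2, `+`)
  f_mobile0 <- stats::fft(mobile0)

  nt <- config$n_prebleach + config$n_frames
  s <- (nbig - n) %/% 2
  crop <- (s + 1L):(s + n)
  frames <- array(0, dim = c(nt, n, n))
  domain_total <- numeric(nt)

  clean_frame <- function(j) {
    if (j <= config$n_prebleach) return(field0)
    t <- (j - config$n_prebleach - 0.5) * g$frame_interval
    mob <- Re(stats::fft(f_mobile0 * exp(-config$d_true * k2 * t), inverse = TRUE)) / nbig^2
    mob + immobile
  }

  .with_seed(config$seed, {
    for (j in seq_len(nt)) {
      fld <- clean_frame(j)
      domain_total[j] <- sum(fld)
      img <- fld[crop, crop]
      if (config$acquisition_bleach_rate > 0) {
        img <- img * (1 - config$acquisition_bleach_rate)^(j - 1)
      }
      if (config$shot_noise) {
        img <- matrix(
          stats::rpois(length(img), img * config$photons_per_unit) / config$photons_per_unit,
          n, n
        )
      }
      if (config$noise_sd > 0) {
        img <- img * (1 + stats::rnorm(length(img), 0, config$noise_sd))
      }
      frames[j, , ] <- pmax(img, 0)
    }
  })

  cam_ctr <- n / 2 + 0.5
  stack <- frap_stack(
    frames = frames,
    pixel_size = px,
    frame_interval = g$frame_interval,
    bleach_frame_index = config$n_prebleach + 1L,
    roi_center = c(cam_ctr, cam_ctr),
    roi_radius = w / px
  )
  # pre-bleach frames hold the unbleached total; post-bleach totals must be
  # constant among themselves (diffusion conserves mass)
  list(
    stack = stack,
    truth = list(
      d_true = config$d_true, tau_d = tau_d,
      a = (1 - config$immobile_fraction) * config$bleach_depth,
      b = 1 - config$bleach_depth,
      domain_total = domain_total,
      config = config
    )
  )
}

#' Reference diffusion-versus-humidity tables
#'
#' Ground-truth D(RH) tables used by the simulator, for a single-component
#' liquid-disordered bilayer and for the liquid-disordered phase of a
#' phase-separated bilayer. Knot values at the measured humidity levels
#' honor the reported endpoints (single component: 5.35 um^2/s fully
#' hydrated, 4.75 at 85% RH, 0.25 at ~0% RH; phase-separated: 1.66, 1.52,
#' 0.04) with the transition knee placed at 50% RH, near-flat below it.
#' The rehydration branch runs 15% below the dehydration branch at
#' intermediate humidity (hysteresis) and rejoins the fully hydrated value
#' at the bulk point (RH 100).
#'
#' @param system `"single"` or `"phase_separated"`.
#' @param branch `"dehydration"` or `"rehydration"`.
#' @return data.frame with columns `rh_percent`, `d_um2_per_s`, `branch`.
#' @export
default_d_rh_table <- function(system = c("single", "phase_separated"),
                               branch = c("dehydration", "rehydration")) {
  system <- match.arg(system)
  branch <- match.arg(branch)
  rh <- c(0, 30, 45, 65, 85, 100)
  d <- switch(system,
    single = c(0.25, 0.30, 0.50, 1.80, 4.75, 5.35),
    phase_separated = c(0.04, 0.05, 0.10, 0.55, 1.52, 1.66)
  )
  if (branch == "rehydration") {
    mid <- seq_along(d) > 1 & seq_along(d) < length(d)
    d[mid] <- 0.85 * d[mid]
  }
  data.frame(rh_percent = rh, d_um2_per_s = d, branch = branch)
}

#' Simulate FRAP runs along a humidity protocol
#'
#' For each humidity set-point, the equilibrium diffusion coefficient is
#' looked up in `d_of_rh` (monotone interpolation), an optional first-order
#' equilibration lag is applied (the membrane's hydration relaxes toward the
#' set-point with time constant `lag_tau_s` over the `dwell_s` spent at each
#' step; 0 means instantaneous equilibration), and a recovery trace is
#' generated at the resulting D.
#'
#' @param d_of_rh data.frame with columns `rh_percent`, `d_um2_per_s`
#'   (e.g. [default_d_rh_table()]).
#' @param protocol numeric vector of RH set-points (percent), each within
#'   the table's RH range.
#' @param config a [frap_sim_config()]; its `d_true` is ignored and its
#'   `seed` (required for reproducibility) is offset by the step index so
#'   every step gets an independent, reproducible noise draw.
#' @param lag_tau_s first-order equilibration time constant, seconds.
#' @param dwell_s time spent at each set-point before the measurement,
#'   seconds (default 300, i.e. 5 minutes per step).
#' @return List with vectors `rh`, `d_equilibrium`, `d_used` and list
#'   `traces` of [recovery_trace()] objects (one per set-point).
#' @export
simulate_rh_series <- function(d_of_rh, protocol, config,
                               lag_tau_s = 0, dwell_s = 300) {
  stopifnot(inherits(config, "frap_sim_config"))
  if (length(protocol) == 0L) {
    .hs_error("empty humidity protocol.", "hydrasense_sim_error")
  }
  if (any(protocol < min(d_of_rh$rh_percent)) || any(protocol > max(d_of_rh$rh_percent))) {
    .hs_error("protocol RH outside the table's domain.", "hydrasense_sim_error")
  }
  ord <- order(d_of_rh$rh_percent)
  interp <- stats::splinefun(d_of_rh$rh_percent[ord], d_of_rh$d_um2_per_s[ord],
                             method = "monoH.FC")
  d_eq <- interp(protocol)
  d_used <- numeric(length(protocol))
  state <- d_eq[1L]
  decay <- if (lag_tau_s > 0) exp(-dwell_s / lag_tau_s) else 0
  traces <- vector("list", length(protocol))
  for (i in seq_along(protocol)) {
    state <- d_eq[i] + (state - d_eq[i]) * decay
    d_used[i] <- state
    cfg_i <- config
    cfg_i$d_true <- state
    cfg_i$seed <- if (is.null(config$seed)) NULL else config$seed + i
    traces[[i]] <- simulate_trace(cfg_i)$trace
  }
  list(rh = protocol, d_equilibrium = d_eq, d_used = d_used, traces = traces)
}
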