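# Closed-form recovery function for free 2-D diffusion into a uniformly
# bleached disk, and the affine recovery model wrapped around it.

#' Soumpasis recovery function
#'
#' Fractional fluorescence recovery of a uniformly, instantaneously bleached
#' circular spot by free two-dimensional Brownian diffusion:
#' \deqn{f(t) = e^{-2\tau_D/t}\left[I_0(2\tau_D/t) + I_1(2\tau_D/t)\right]}
#' where \eqn{I_0, I_1} are modified Bessel functions of the first kind and
#' \eqn{\tau_D = w^2/(4D)} is the characteristic diffusion time of a spot of
#' radius \eqn{w}.
#'
#' The Bessel sum is evaluated with exponentially scaled routines so early
#' times (\eqn{t \ll \tau_D}, huge argument) do not overflow; beyond argument
#' 700 the four-term large-argument asymptotic expansion is used, where R's
#' scaled Bessel implementation loses accuracy.
#'
#' @param t time since the end of the bleach, seconds. Vectorized; all values
#'   must be strictly positive (the function has an essential singularity at
#'   `t = 0` and is never evaluated there).
#' @param tau_d characteristic diffusion time \eqn{\tau_D}, seconds (scalar,
#'   > 0).
#' @return Recovered fraction in (0, 1); strictly increasing in `t`, tending
#'   to 1 as `t -> Inf` and to 0 as `t -> 0+`.
#' @examples
#' soumpasis_f(1, 1)          # ~0.5238 at t = tau_D
#' soumpasis_f(50, 25 / (4 * 5.35))  # ~0.977: a hydrated membrane at 50 s
#' @seealso [recovery_model()], [fit_recovery()], [half_time()]
#' @export
soumpasis_f <- function(t, tau_d) {
  if (!is.numeric(t) || length(t) == 0L || anyNA(t) || any(t <= 0)) {
    stop("`t` must be positive (seconds since bleach end).", call. = FALSE)
  }
  if (!is.numeric(tau_d) || length(tau_d) != 1L || is.na(tau_d) || tau_d <= 0) {
    stop("`tau_d` must be a single positive number (seconds).", call. = FALSE)
  }
  x <- 2 * tau_d / t
  out <- numeric(length(x))
  small <- x <= 700
  if (any(small)) {
    xs <- x[small]
    out[small] <- besselI(xs, 0, expon.scaled = TRUE) +
      besselI(xs, 1, expon.scaled = TRUE)
  }
  if (any(!small)) {
    # e^{-x}[I0(x)+I1(x)] ~ (2*pi*x)^{-1/2} [2 - 1/(4x) - 3/(64x^2) - 15/(512x^3)]
    xl <- x[!small]
    out[!small] <- (2 - 1 / (4 * xl) - 3 / (64 * xl^2) - 15 / (512 * xl^3)) /
      sqrt(2 * pi * xl)
  }
  out
}

#' Affine FRAP recovery model
#'
#' The fitted recovery curve \eqn{F(t) = b + a f(t)}: `b` is the fluorescence
#' remaining in the spot right after bleaching, `a` the amplitude recovered by
#' diffusion, and \eqn{f} the Soumpasis function ([soumpasis_f()]). The
#' plateau (`t -> Inf`) is `a + b`; relative to a pre-bleach level of 1 it
#' falls short of full recovery when part of the fluorophores is immobile.
#'
#' @inheritParams soumpasis_f
#' @param a recovery amplitude (dimensionless, > 0).
#' @param b remaining fluorescence after bleaching (dimensionless, >= 0).
#' @return Model intensity at `t` (same length as `t`).
#' @examples
#' recovery_model(2, a = 1, b = 0, tau_d = 2)  # = soumpasis_f(2, 2)
#' @export
recovery_model <- function(t, a, b, tau_d) {
  b + a * soumpasis_f(t, tau_d)
}

#' Half-recovery time of the Soumpasis curve
#'
#' Time at which [soumpasis_f()] reaches 0.5, found by bracketed root finding.
#' By the scaling invariance \eqn{f(ct, c\tau_D) = f(t, \tau_D)} the ratio
#' \eqn{t_{1/2}/\tau_D} is a universal constant (~0.8946), so the result is
#' proportional to `tau_d`. A handy diagnostic for choosing starting values
#' and sanity-checking fits.
#'
#' @param tau_d characteristic diffusion time, seconds (> 0).
#' @return Half-recovery time in seconds.
#' @examples
#' half_time(1)   # ~0.895 s
#' half_time(10)  # exactly 10 * half_time(1)
#' @export
half_time <- function(tau_d) {
  if (!is.numeric(tau_d) || length(tau_d) != 1L || is.na(tau_d) || tau_d <= 0) {
    stop("`tau_d` must be a single positive number (seconds).", call. = FALSE)
  }
  tau_d * .soumpasis_half_unit()
}

# t1/2 / tau_D, computed once per session by root finding on the unit curve.
.half_unit_cache <- new.env(parent = emptyenv())
.soumpasis_half_unit <- function() {
  if (is.null(.half_unit_cache$value)) {
    .half_unit_cache$value <- stats::uniroot(
      function(r) soumpasis_f(r, 1) - 0.5,
      interval = c(0.05, 20), tol = 1e-12
    )$root
  }
  .half_unit_cache$value
}
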