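# Nonlinear least-squares fitting of normalized recovery traces.

#' Fit a normalized FRAP trace with the Soumpasis recovery model
#'
#' Least-squares estimation of `(a, b, tau_d)` in \eqn{F(t) = b + a f(t)}
#' ([recovery_model()]) by Levenberg-Marquardt with box bounds, then the
#' lateral diffusion coefficient \eqn{D = w^2 / (4 \tau_D)} with a 95%
#' confidence interval from the linearized parameter covariance, propagated
#' to `D` by the delta method (the same construction used to put error bars
#' on single-trace D estimates).
#'
#' Starting values are derivative-free: `b0` is the first post-bleach
#' intensity, the starting plateau the mean of the last frames, and `tau0`
#' the empirical half-recovery time divided by the universal ratio
#' \eqn{t_{1/2}/\tau_D} (~0.8946). The fit runs in the
#' `(plateau = a + b, b, tau_d)` parameterization with bounds
#' `plateau` in (0, 1.02] (the recovery cannot overshoot the pre-bleach
#' level beyond noise), `b` in [0, 1), `tau_d` in [1e-3, 1e4] s; estimates
#' landing on a bound are flagged in `$at_bounds` rather than silently
#' accepted. The plateau bound is what keeps slow, partially recovered
#' traces identifiable.
#'
#' @param trace a [recovery_trace()] (pre-bleach level 1, >= 10 frames).
#' @param geometry a [bleach_geometry()] supplying the spot radius `w`.
#' @param conf_level confidence level for the interval on D (default 0.95).
#' @return A `soumpasis_fit` object: list with elements `a`, `b`, `tau_d`
#'   (s), `d` (um^2/s), `se_d`, `ci_low_d`, `ci_high_d`, `mobile_fraction`
#'   (`a / (1 - b)` clipped to [0, 1]), `residual_rms`, `converged`,
#'   `at_bounds`, `n_frames`, `spot_radius_w`, `conf_level`.
#' @section Errors:
#' A trace whose first intensity is >= 0.95 carries no bleach signature and
#' raises a `hydrasense_no_bleach_error`; optimizer failure raises a
#' `hydrasense_fit_error` carrying the diagnostics.
#' @examples
#' geom <- bleach_geometry()
#' t <- ((1:100) - 0.5) * 0.5
#' tr <- recovery_trace(t, recovery_model(t, a = 0.9, b = 0.1, tau_d = 2))
#' fit <- fit_recovery(tr, geom)
#' fit$d  # 3.125 um^2/s = 25 / (4 * 2)
#' @export
fit_recovery <- function(trace, geometry, conf_level = 0.95) {
  stopifnot(inherits(trace, "recovery_trace"), inherits(geometry, "bleach_geometry"))
  t <- trace$time_s
  y <- trace$intensity_norm
  n <- length(t)
  if (n < 10L) {
    .hs_error("need at least 10 post-bleach frames to fit.", "hydrasense_fit_error")
  }
  if (y[1L] >= 0.95) {
    .hs_error(
      sprintf("no bleach signature: first intensity %.3f >= 0.95.", y[1L]),
      "hydrasense_no_bleach_error"
    )
  }

  # The model is fitted in the (plateau, b, tau_d) parameterization with
  # plateau m = a + b: the recovery plateau cannot exceed the pre-bleach
  # level beyond noise, and the box bound m <= 1.02 enforces exactly that.
  # Without it, low-recovery traces (tau_d >> window) leave a degenerate
  # (a, tau_d) valley and the unconstrained optimum is strongly biased.
  lower <- c(m = 0.01, b = 0, tau_d = 1e-3)
  upper <- c(m = 1.02, b = 0.999, tau_d = 1e4)
  start <- .fit_start(t, y, lower, upper)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + (m - b) * soumpasis_f(t, tau_d),
      data = data.frame(t = t, y = y),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    .hs_error(
      paste0("recovery fit did not converge: ", conditionMessage(fit)),
      "hydrasense_fit_error",
      start = start, n_frames = n
    )
  }

  cf <- stats::coef(fit)
  cf <- c(a = unname(cf[["m"]] - cf[["b"]]), cf)
  w <- geometry$spot_radius_w
  d <- w^2 / (4 * cf[["tau_d"]])

  se_tau <- tryCatch(sqrt(stats::vcov(fit)["tau_d", "tau_d"]), error = function(e) NA_real_)
  se_d <- (w^2 / (4 * cf[["tau_d"]]^2)) * se_tau
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = max(n - 3L, 1L))
  ci_low <- max(d - tcrit * se_d, 0)
  ci_high <- d + tcrit * se_d
  if (is.na(se_d)) {
    ci_low <- ci_high <- d
  }

  tol <- 1e-6
  pars <- cf[c("m", "b", "tau_d")]
  at_bounds <- (abs(pars - lower) < tol * pmax(1, abs(lower))) |
    (abs(pars - upper) < tol * pmax(1, abs(upper)))
  names(at_bounds) <- c("plateau", "b", "tau_d")

  res <- stats::resid(fit)
  structure(
    list(
      a = unname(cf[["a"]]),
      b = unname(cf[["b"]]),
      tau_d = unname(cf[["tau_d"]]),
      d = unname(d),
      se_d = unname(se_d),
      ci_low_d = unname(ci_low),
      ci_high_d = unname(ci_high),
      mobile_fraction = min(max(cf[["a"]] / (1 - cf[["b"]]), 0), 1),
      residual_rms = sqrt(mean(res^2)),
      converged = TRUE,
      at_bounds = at_bounds,
      n_frames = n,
      spot_radius_w = w,
      conf_level = conf_level
    ),
    class = "soumpasis_fit"
  )
}

# Derivative-free starting values (robust to noise; clipped into bounds).
.fit_start <- function(t, y, lower, upper) {
  b0 <- min(max(y[1L], lower[["b"]]), 0.9)
  tail_n <- min(5L, length(y))
  plateau <- mean(utils::tail(y, tail_n))
  m0 <- min(max(plateau, b0 + 0.05), upper[["m"]])
  # first crossing of the half-recovery level, linearly interpolated
  half_level <- b0 + 0.5 * (m0 - b0)
  above <- which(y >= half_level)
  t_half <- if (length(above) == 0L) {
    max(t)                     # recovery hasn't reached half level in-window
  } else if (above[1L] == 1L) {
    t[1L] / 2
  } else {
    i <- above[1L]
    t[i - 1L] + (half_level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
  }
  tau0 <- min(max(t_half / .soumpasis_half_unit(), lower[["tau_d"]] * 10), upper[["tau_d"]] / 10)
  c(m = m0, b = b0, tau_d = tau0)
}

#' @export
print.soumpasis_fit <- function(x, ...) {
  cat("<soumpasis_fit>\n")
  cat(sprintf("  D        = %.6g um^2/s  [%.6g, %.6g] (%.0f%% CI)\n",
              x$d, x$ci_low_d, x$ci_high_d, 100 * x$conf_level))
  cat(sprintf("  tau_D    = %.6g s   (w = %g um)\n", x$tau_d, x$spot_radius_w))
  cat(sprintf("  a = %.4g, b = %.4g, mobile fraction = %.3g\n",
              x$a, x$b, x$mobile_fraction))
  cat(sprintf("  residual RMS = %.3g over %d frames\n", x$residual_rms, x$n_frames))
  if (any(x$at_bounds)) {
    cat("  warning: parameter(s) at bounds:",
        paste(names(x$at_bounds)[x$at_bounds], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes the fit with keys `a, b, tau_d_s, d_um2_per_s, ci_low, ci_high,
#' mobile_fraction, residual_rms, converged`.
#'
#' @param fit a `soumpasis_fit`.
#' @param path output path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "soumpasis_fit"))
  obj <- list(
    a = fit$a, b = fit$b, tau_d_s = fit$tau_d, d_um2_per_s = fit$d,
    ci_low = fit$ci_low_d, ci_high = fit$ci_high_d,
    mobile_fraction = fit$mobile_fraction,
    residual_rms = fit$residual_rms, converged = fit$converged
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
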