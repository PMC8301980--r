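# End-to-end glue: extract -> normalize -> fit (-> sense), with a
# machine-readable report. The command-line entry points in
# inst/cli/hydrasense are thin wrappers over this.

.hs_log <- function(quiet, stage, msg) {
  if (!quiet) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
}

#' Run the FRAP hydration-sensing pipeline
#'
#' Takes a FRAP measurement - a [frap_stack()], a [recovery_trace()], or a
#' path to a trace CSV / multi-page TIFF (with metadata sidecar) - and runs
#' extraction, double normalization and the Soumpasis fit; when a
#' calibration curve is supplied the fitted D is additionally inverted into
#' a hydration estimate. Every number in the report is taken from the stage
#' outputs; the formatter computes nothing.
#'
#' @param input a `frap_stack`, `recovery_trace`, or file path (`.csv`
#'   trace, or `.tif`/`.tiff` stack with sidecar).
#' @param geometry a [bleach_geometry()]; for stack inputs its
#'   `frame_interval` is taken from the stack.
#' @param curve optional `calibration_curve` (or path to a curve JSON) for
#'   the sensing step.
#' @param out_json optional path; when given the report is written there.
#' @param quiet suppress progress log lines on stderr.
#' @return A `hydrasense_report`: list with `status` (`"ok"`,
#'   `"no-bleach"`, `"fit-failure"` or `"extrapolated-sense"`), `input`,
#'   `fit`, optional `hydration`, and `timestamp`.
#' @export
run_pipeline <- function(input, geometry = bleach_geometry(), curve = NULL,
                         out_json = NULL, quiet = FALSE) {
  report <- list(
    status = "ok",
    input = list(class = class(input)[1L]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (is.character(curve)) curve <- read_curve_json(curve)

  if (is.character(input)) {
    report$input$path <- input
    if (grepl("\\.csv$", input, ignore.case = TRUE)) {
      .hs_log(quiet, "load", paste("reading trace", input))
      input <- read_trace_csv(input)
    } else if (grepl("\\.tiff?$", input, ignore.case = TRUE)) {
      .hs_log(quiet, "load", paste("reading stack", input))
      input <- read_frap_tiff(input)
    } else {
      .hs_error("input path must be a .csv trace or .tif/.tiff stack.",
                "hydrasense_io_error")
    }
  }

  trace <- if (inherits(input, "frap_stack")) {
    .hs_log(quiet, "extract", "ROI and reference traces, double normalization")
    geometry$frame_interval <- input$frame_interval
    tr <- tryCatch(stack_to_trace(input), hydrasense_no_bleach_error = function(e) e)
    if (inherits(tr, "error")) {
      report$status <- "no-bleach"
      report$error <- conditionMessage(tr)
      if (!is.null(out_json)) jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA)
      return(structure(report, class = "hydrasense_report"))
    }
    tr
  } else if (inherits(input, "recovery_trace")) {
    input
  } else {
    .hs_error("unsupported input type.", "hydrasense_io_error")
  }
  report$input$n_frames <- attr(trace, "n_frames")

  .hs_log(quiet, "fit", sprintf("Soumpasis fit of %d frames", attr(trace, "n_frames")))
  fit <- tryCatch(
    fit_recovery(trace, geometry),
    hydrasense_no_bleach_error = function(e) e,
    hydrasense_fit_error = function(e) e
  )
  if (inherits(fit, "hydrasense_no_bleach_error")) {
    report$status <- "no-bleach"
    report$error <- conditionMessage(fit)
  } else if (inherits(fit, "error")) {
    report$status <- "fit-failure"
    report$error <- conditionMessage(fit)
  } else {
    report$fit <- list(
      a = fit$a, b = fit$b, tau_d_s = fit$tau_d, d_um2_per_s = fit$d,
      ci_low = fit$ci_low_d, ci_high = fit$ci_high_d,
      mobile_fraction = fit$mobile_fraction,
      residual_rms = fit$residual_rms, converged = fit$converged,
      at_bounds = as.list(fit$at_bounds)
    )
    .hs_log(quiet, "fit", sprintf("D = %.6g um^2/s [%.6g, %.6g]",
                                  fit$d, fit$ci_low_d, fit$ci_high_d))
    if (!is.null(curve)) {
      .hs_log(quiet, "sense", sprintf("inverting calibration branch '%s'", curve$branch))
      est <- sense(fit$d, curve, ci = c(fit$ci_low_d, fit$ci_high_d))
      report$hydration <- unclass(est)
      if (est$extrapolated) report$status <- "extrapolated-sense"
      .hs_log(quiet, "sense", sprintf("RH = %.4g%%, %.3g waters per lipid",
                                      est$rh_estimate, est$waters_per_lipid))
    }
  }

  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA)
    .hs_log(quiet, "report", paste("written to", out_json))
  }
  structure(report, class = "hydrasense_report")
}

#' @export
print.hydrasense_report <- function(x, ...) {
  cat(sprintf("<hydrasense_report> status: %s\n", x$status))
  if (!is.null(x$fit)) {
    cat(sprintf("  D = %.6g um^2/s [%.6g, %.6g], mobile fraction %.3g\n",
                x$fit$d_um2_per_s, x$fit$ci_low, x$fit$ci_high, x$fit$mobile_fraction))
  }
  if (!is.null(x$hydration)) {
    cat(sprintf("  RH = %.4g%% -> %.3g waters per lipid\n",
                x$hydration$rh_estimate, x$hydration$waters_per_lipid))
  }
  if (!is.null(x$error)) cat("  error:", x$error, "\n")
  invisible(x)
}
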