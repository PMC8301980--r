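# Containers for normalized recovery traces and bleach-spot geometry,
# plus the trace CSV dialect (time_s, intensity_norm).

.hs_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hydrasense_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Normalized FRAP recovery trace
#'
#' Time-stamped, normalized fluorescence intensities of the bleached region
#' for one FRAP run. Times are seconds since the end of the bleach (strictly
#' increasing, all positive; by convention the first frame sits at
#' mid-exposure, `frame_interval / 2`). Intensities are normalized so that
#' the pre-bleach level is 1.
#'
#' @param times numeric vector, seconds since bleach end; strictly
#'   increasing, all > 0.
#' @param intensities numeric vector of the same length; all >= 0 and, as a
#'   sanity bound for normalized data, <= 1.5.
#' @param prebleach_level the normalization reference (1 after
#'   normalization); kept for provenance.
#' @return A `recovery_trace` object (also a data.frame with columns
#'   `time_s`, `intensity_norm`).
#' @examples
#' tr <- recovery_trace(times = (1:10) - 0.5, intensities = seq(0.2, 0.9, length.out = 10))
#' tr$n_frames
#' @export
recovery_trace <- function(times, intensities, prebleach_level = 1) {
  if (!is.numeric(times) || !is.numeric(intensities)) {
    .hs_error("`times` and `intensities` must be numeric.", "hydrasense_trace_error")
  }
  if (length(times) != length(intensities)) {
    .hs_error("`times` and `intensities` must have equal length.", "hydrasense_trace_error")
  }
  if (anyNA(times) || anyNA(intensities)) {
    .hs_error("trace contains missing values.", "hydrasense_trace_error")
  }
  if (any(times <= 0) || any(diff(times) <= 0)) {
    .hs_error("`times` must be strictly increasing and all > 0.", "hydrasense_trace_error")
  }
  if (any(intensities < 0)) {
    .hs_error("`intensities` must be non-negative.", "hydrasense_trace_error")
  }
  if (any(intensities > 1.5)) {
    .hs_error(
      "normalized intensities exceed 1.5; trace does not look normalized.",
      "hydrasense_trace_error"
    )
  }
  structure(
    data.frame(time_s = as.numeric(times), intensity_norm = as.numeric(intensities)),
    prebleach_level = prebleach_level,
    n_frames = length(times),
    class = c("recovery_trace", "data.frame")
  )
}

#' @export
print.recovery_trace <- function(x, ...) {
  cat(sprintf(
    "<recovery_trace> %d frames, t = %.3g..%.3g s, I = %.3g..%.3g\n",
    attr(x, "n_frames"), min(x$time_s), max(x$time_s),
    min(x$intensity_norm), max(x$intensity_norm)
  ))
  invisible(x)
}

#' Bleach-spot geometry
#'
#' Geometry of the FRAP experiment: radius `w` of the uniformly bleached
#' disk, frame interval of the acquisition, and the (square) imaged field
#' size. Defaults are a 10 um-diameter spot in a 50 um x 50 um field imaged
#' every 0.5 s.
#'
#' @param spot_radius_w radius of the bleached disk, micrometres (> 0).
#' @param frame_interval time between frames, seconds (> 0).
#' @param field_size side of the square imaged field, micrometres; must
#'   exceed the spot diameter.
#' @return A `bleach_geometry` object (named list).
#' @examples
#' bleach_geometry()  # the default 10 um spot / 50 um field / 0.5 s
#' @export
bleach_geometry <- function(spot_radius_w = 5, frame_interval = 0.5, field_size = 50) {
  if (!is.numeric(spot_radius_w) || spot_radius_w <= 0) {
    .hs_error("`spot_radius_w` must be > 0 (micrometres).", "hydrasense_geometry_error")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    .hs_error("`frame_interval` must be > 0 (seconds).", "hydrasense_geometry_error")
  }
  if (!is.numeric(field_size) || 2 * spot_radius_w >= field_size) {
    .hs_error("`field_size` must exceed the spot diameter.", "hydrasense_geometry_error")
  }
  structure(
    list(
      spot_radius_w = as.numeric(spot_radius_w),
      frame_interval = as.numeric(frame_interval),
      field_size = as.numeric(field_size)
    ),
    class = "bleach_geometry"
  )
}

#' @export
print.bleach_geometry <- function(x, ...) {
  cat(sprintf(
    "<bleach_geometry> spot radius %g um, interval %g s, field %g um\n",
    x$spot_radius_w, x$frame_interval, x$field_size
  ))
  invisible(x)
}

#' Read / write recovery traces as CSV
#'
#' The trace CSV dialect has a header `time_s, intensity_norm` (UTF-8, '.'
#' decimal separator).
#'
#' @param path file path.
#' @return `read_trace_csv()` returns a [recovery_trace()];
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "intensity_norm")
  if (!all(need %in% names(df))) {
    .hs_error(
      sprintf("trace CSV must have columns %s.", paste(need, collapse = ", ")),
      "hydrasense_io_error"
    )
  }
  recovery_trace(df$time_s, df$intensity_norm)
}

#' @rdname read_trace_csv
#' @param trace a [recovery_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "recovery_trace"))
  utils::write.csv(
    data.frame(time_s = trace$time_s, intensity_norm = trace$intensity_norm),
    path,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
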