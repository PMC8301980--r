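# Extraction and normalization of recovery traces from FRAP image stacks.

#' FRAP image stack
#'
#' Single-channel confocal time series with the metadata needed to extract a
#' recovery trace: pixel size, frame interval, index of the first post-bleach
#' frame and the bleach-ROI geometry. Pixel indices are 1-based; a pixel's
#' center sits at `(index - 0.5) * pixel_size` micrometres.
#'
#' @param frames 3-D numeric array `[time, rows, cols]`, non-negative.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param bleach_frame_index 1-based index of the first post-bleach frame
#'   (>= 2, so at least one pre-bleach frame exists).
#' @param roi_center numeric `(row, col)` center of the bleached disk,
#'   pixels.
#' @param roi_radius radius of the bleached disk, pixels; the disk must lie
#'   fully inside the frame.
#' @return A `frap_stack` object.
#' @export
frap_stack <- function(frames, pixel_size, frame_interval, bleach_frame_index,
                       roi_center, roi_radius) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    .hs_error("`frames` must be a 3-D array [time, rows, cols].", "hydrasense_stack_error")
  }
  if (any(frames < 0)) {
    .hs_error("intensities must be non-negative.", "hydrasense_stack_error")
  }
  nt <- dim(frames)[1L]
  if (bleach_frame_index < 2L || bleach_frame_index > nt) {
    .hs_error("`bleach_frame_index` must leave at least one pre-bleach frame.",
              "hydrasense_stack_error")
  }
  nr <- dim(frames)[2L]
  nc <- dim(frames)[3L]
  if (length(roi_center) != 2L ||
      roi_center[1L] - roi_radius < 0.5 || roi_center[1L] + roi_radius > nr + 0.5 ||
      roi_center[2L] - roi_radius < 0.5 || roi_center[2L] + roi_radius > nc + 0.5) {
    .hs_error("ROI disk must lie fully inside the frame.", "hydrasense_stack_error")
  }
  structure(
    list(
      frames = frames,
      pixel_size = as.numeric(pixel_size),
      frame_interval = as.numeric(frame_interval),
      bleach_frame_index = as.integer(bleach_frame_index),
      roi_center = as.numeric(roi_center),
      roi_radius = as.numeric(roi_radius)
    ),
    class = "frap_stack"
  )
}

#' @export
print.frap_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frap_stack> %d frames of %dx%d px (%.3g um/px, %.3g s/frame), bleach at frame %d, ROI r=%.3g px\n",
    d[1L], d[2L], d[3L], x$pixel_size, x$frame_interval, x$bleach_frame_index, x$roi_radius
  ))
  invisible(x)
}

# Logical mask of pixels whose centers lie within `radius` of `center`
# (pixel-center-within-radius membership, no partial-pixel weighting).
.roi_mask <- function(nr, nc, center, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2
}

#' Locate the bleach frame
#'
#' Returns the 1-based index of the first post-bleach frame: the frame
#' following the largest single-step drop of the mean ROI intensity (earliest
#' index on ties). The drop must exceed 3x the inter-frame noise SD
#' (estimated from all other frame-to-frame steps); otherwise a
#' `hydrasense_no_bleach_error` is raised.
#'
#' @param stack a [frap_stack()] with at least 3 frames.
#' @return Integer frame index.
#' @export
detect_bleach_frame <- function(stack) {
  stopifnot(inherits(stack, "frap_stack"))
  nt <- dim(stack$frames)[1L]
  if (nt < 3L) {
    .hs_error("need at least 3 frames.", "hydrasense_stack_error")
  }
  mask <- .roi_mask(dim(stack$frames)[2L], dim(stack$frames)[3L],
                    stack$roi_center, stack$roi_radius)
  m <- vapply(seq_len(nt), function(i) mean(stack$frames[i, , ][mask]), numeric(1))
  steps <- diff(m)
  i <- which.min(steps)          # earliest index on ties (which.min contract)
  drop <- -steps[i]
  noise_sd <- stats::sd(steps[-i])
  if (drop <= 0 || is.na(noise_sd) || drop < 3 * noise_sd) {
    .hs_error("no bleach detected: largest intensity drop is within noise.",
              "hydrasense_no_bleach_error")
  }
  i + 1L
}

#' Extract a mean-intensity trace from a stack
#'
#' Per-frame arithmetic mean over the pixels of a region: the bleached ROI
#' disk, or the reference region (the whole field except the ROI disk,
#' optionally also excluding a guard annulus around it). Times are assigned
#' as `(frame - bleach_frame_index + 0.5) * frame_interval` (mid-exposure
#' convention); pre-bleach frames get negative times.
#'
#' @param stack a [frap_stack()].
#' @param region `"roi"` or `"reference"`.
#' @param guard_factor for `region = "reference"`, exclude pixels closer
#'   than `guard_factor * roi_radius` to the ROI center (default 1 = no
#'   guard annulus, i.e. exactly the field minus the ROI disk).
#' @return data.frame with columns `frame`, `time_s`, `intensity`.
#' @export
extract_trace <- function(stack, region = c("roi", "reference"), guard_factor = 1) {
  stopifnot(inherits(stack, "frap_stack"))
  region <- match.arg(region)
  nr <- dim(stack$frames)[2L]
  nc <- dim(stack$frames)[3L]
  roi <- .roi_mask(nr, nc, stack$roi_center, stack$roi_radius)
  mask <- if (region == "roi") {
    roi
  } else {
    !.roi_mask(nr, nc, stack$roi_center, stack$roi_radius * max(guard_factor, 1))
  }
  if (!any(mask)) {
    .hs_error("selected region contains no pixels.", "hydrasense_stack_error")
  }
  nt <- dim(stack$frames)[1L]
  means <- vapply(seq_len(nt), function(i) mean(stack$frames[i, , ][mask]), numeric(1))
  data.frame(
    frame = seq_len(nt),
    time_s = (seq_len(nt) - stack$bleach_frame_index + 0.5) * stack$frame_interval,
    intensity = means
  )
}

#' Double normalization of a raw ROI trace
#'
#' Normalizes the recovery trace the way FRAP experiments on a slowly
#' photobleaching field are analysed: (i) the ROI trace is divided frame-wise
#' by the reference trace (the field outside the bleached spot), cancelling
#' global acquisition photobleaching; (ii) the corrected trace is divided by
#' the mean of its pre-bleach values so the pre-bleach level is exactly 1.
#' Only the post-bleach portion (positive times) is returned.
#'
#' @param roi_trace,reference_trace data.frames as returned by
#'   [extract_trace()], on identical frame grids.
#' @param prebleach_frames number of pre-bleach frames (>= 1) to average for
#'   step (ii).
#' @return A [recovery_trace()].
#' @export
normalize_trace <- function(roi_trace, reference_trace, prebleach_frames) {
  if (nrow(roi_trace) != nrow(reference_trace)) {
    .hs_error("ROI and reference traces must cover the same frames.",
              "hydrasense_stack_error")
  }
  if (prebleach_frames < 1L || prebleach_frames >= nrow(roi_trace)) {
    .hs_error("`prebleach_frames` must be >= 1 and leave post-bleach frames.",
              "hydrasense_stack_error")
  }
  if (any(reference_trace$intensity <= 0)) {
    .hs_error("reference intensity is zero in some frame; cannot normalize.",
              "hydrasense_stack_error")
  }
  corrected <- roi_trace$intensity / reference_trace$intensity
  pre <- mean(corrected[seq_len(prebleach_frames)])
  if (pre <= 0) {
    .hs_error("pre-bleach corrected level is zero.", "hydrasense_stack_error")
  }
  norm <- corrected / pre
  post <- roi_trace$time_s > 0
  recovery_trace(roi_trace$time_s[post], pmin(pmax(norm[post], 0), 1.5),
                 prebleach_level = 1)
}

#' Read a FRAP stack from a multi-page TIFF plus metadata sidecar
#'
#' Image metadata (pixel size, frame interval, ROI, bleach frame) is taken
#' from a JSON or YAML sidecar, not from TIFF tags. The sidecar must provide
#' `pixel_size_um`, `frame_interval_s`, `bleach_frame_index`,
#' `roi_center_px` (row, col) and `roi_radius_px`; an optional
#' `intensity_scale` undoes the [0, 1] scaling applied when writing.
#'
#' @param tiff_path path to a single-channel multi-page TIFF.
#' @param sidecar_path path to the JSON (`.json`) or YAML (`.yml`/`.yaml`)
#'   sidecar; defaults to `tiff_path` with the extension swapped to `.json`.
#' @return A [frap_stack()].
#' @export
read_frap_tiff <- function(tiff_path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) {
    sidecar_path <- sub("\\.tiff?$", ".json", tiff_path, ignore.case = TRUE)
  }
  if (!file.exists(sidecar_path)) {
    .hs_error(sprintf("metadata sidecar not found: %s", sidecar_path),
              "hydrasense_io_error")
  }
  meta <- if (grepl("\\.ya?ml$", sidecar_path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      .hs_error("the 'yaml' package is required for YAML sidecars.", "hydrasense_io_error")
    }
    yaml::read_yaml(sidecar_path)
  } else {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  frames <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * scale
  frap_stack(
    frames = frames,
    pixel_size = meta$pixel_size_um,
    frame_interval = meta$frame_interval_s,
    bleach_frame_index = meta$bleach_frame_index,
    roi_center = unlist(meta$roi_center_px),
    roi_radius = meta$roi_radius_px
  )
}

#' Write a FRAP stack as 16-bit multi-page TIFF plus JSON sidecar
#'
#' Intensities are scaled into [0, 1] for the TIFF; the scale factor is
#' recorded in the sidecar so [read_frap_tiff()] restores the original
#' values (up to 16-bit quantization).
#'
#' @param stack a [frap_stack()].
#' @param tiff_path output TIFF path; the sidecar is written next to it with
#'   extension `.json`.
#' @param extra named list merged into the sidecar (e.g. ground truth).
#' @return `tiff_path` invisibly.
#' @export
write_frap_tiff <- function(stack, tiff_path, extra = list()) {
  stopifnot(inherits(stack, "frap_stack"))
  mx <- max(stack$frames)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(stack$frames)[1L]),
                  function(i) stack$frames[i, , ] / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  meta <- c(
    list(
      pixel_size_um = stack$pixel_size,
      frame_interval_s = stack$frame_interval,
      bleach_frame_index = stack$bleach_frame_index,
      roi_center_px = stack$roi_center,
      roi_radius_px = stack$roi_radius,
      intensity_scale = scale
    ),
    extra
  )
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", tiff_path, ignore.case = TRUE),
                       auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' One-call trace extraction from a stack
#'
#' Convenience wrapper: extracts ROI and reference traces and applies the
#' double normalization, yielding a fit-ready [recovery_trace()].
#'
#' @param stack a [frap_stack()].
#' @param guard_factor passed to [extract_trace()] for the reference region.
#' @return A [recovery_trace()].
#' @export
stack_to_trace <- function(stack, guard_factor = 1) {
  roi <- extract_trace(stack, "roi")
  ref <- extract_trace(stack, "reference", guard_factor = guard_factor)
  normalize_trace(roi, ref, prebleach_frames = stack$bleach_frame_index - 1L)
}
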