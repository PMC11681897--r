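#' Specify a circular region of interest
#'
#' ROI placement is user-supplied (operators circle the fingernail, ROI1, and
#' the fingertip skin, ROI2, on screen); this object records the circle in
#' 0-based pixel coordinates, `(x, y)` order, with the radius either in
#' pixels or in millimeters (converted via the acquisition pixel pitch).
#'
#' @param label `"ROI1"` or `"ROI2"`.
#' @param center numeric `(x, y)` center, 0-based pixel coordinates.
#' @param radius circle radius, in the units of `units`.
#' @param units `"px"` or `"mm"`.
#' @param anatomical_hint free text (e.g. "fingernail bed").
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(label = c("ROI1", "ROI2"), center, radius,
                     units = c("px", "mm"), anatomical_hint = "") {
  label <- match.arg(label)
  units <- match.arg(units)
  if (length(center) != 2L || any(!is.finite(center)))
    stop_invalid("center must be finite (x, y)")
  check_scalar_num(radius, "radius", positive = TRUE)
  structure(list(label = label, center = as.numeric(center), radius = radius,
                 units = units, anatomical_hint = anatomical_hint),
            class = "roi_spec")
}

#' Rasterize a circular ROI to a boolean pixel mask
#'
#' A pixel belongs to the mask iff its center lies within `radius` of the ROI
#' center (Euclidean distance, 0-based pixel-center coordinates). Radii given
#' in mm are converted with `pixel_pitch` (mm/px).
#'
#' @param spec an [roi_spec()].
#' @param shape image `(height, width)` in pixels.
#' @param pixel_pitch mm per pixel; required when the radius is in mm.
#' @param allow_clip permit a disc partially outside the image (clipped with
#'   a warning); if `FALSE` an out-of-bounds disc is an error.
#' @return logical `height x width` matrix.
#' @export
#' @examples
#' m <- circular_mask(roi_spec("ROI1", c(16, 16), 5), shape = c(32, 32))
#' sum(m)       # about pi * 25
circular_mask <- function(spec, shape, pixel_pitch = NULL, allow_clip = TRUE) {
  if (!inherits(spec, "roi_spec")) stop_invalid("spec must be an roi_spec")
  if (length(shape) != 2L || any(shape < 1)) stop_invalid("shape must be positive")
  r_px <- spec$radius
  if (spec$units == "mm") {
    if (is.null(pixel_pitch)) stop_invalid("pixel_pitch required for mm radius")
    check_scalar_num(pixel_pitch, "pixel_pitch", positive = TRUE)
    r_px <- spec$radius / pixel_pitch
  }
  h <- shape[1]; w <- shape[2]
  cx <- spec$center[1]; cy <- spec$center[2]
  clipped <- (cx - r_px < -0.5) || (cx + r_px > w - 0.5) ||
             (cy - r_px < -0.5) || (cy + r_px > h - 0.5)
  if (clipped && !allow_clip)
    stop_invalid("ROI extends outside the image and clipping is disabled")
  if (clipped) warning(sprintf("ROI '%s' clipped at the image border", spec$label))
  x <- matrix(rep(0:(w - 1L), each = h), h, w)     # column index = x
  y <- matrix(rep(0:(h - 1L), times = w), h, w)    # row index = y
  mask <- (x - cx)^2 + (y - cy)^2 <= r_px^2
  if (!any(mask)) stop("empty ROI mask: no pixel center falls inside the circle")
  mask
}

#' Extract dual-ROI perfusion time series
#'
#' For each map in a [stream_process()] output, the ROI value is the mean of
#' the valid perfusion pixels inside the mask; frames with no valid ROI pixel
#' yield NA and are flagged. ROI1 and ROI2 masks must not overlap (the
#' nail/skin circles are disjoint).
#'
#' @param seq a `perfusion_sequence`.
#' @param roi1,roi2 [roi_spec()] objects (fingernail / fingertip skin).
#' @param pixel_pitch mm per pixel for mm radii.
#' @return An object of class `roi_series`: data.frame with `time_s`, `roi1`,
#'   `roi2` plus attributes `sampling_rate` and `duration`.
#' @export
extract_roi_series <- function(seq, roi1, roi2, pixel_pitch = NULL) {
  if (!inherits(seq, "perfusion_sequence"))
    stop_invalid("seq must be a perfusion_sequence")
  shape <- dim(seq$maps[[1]]$P)
  m1 <- circular_mask(roi1, shape, pixel_pitch)
  m2 <- circular_mask(roi2, shape, pixel_pitch)
  if (any(m1 & m2)) stop("ROI1 and ROI2 masks overlap")
  roi_mean <- function(pm, m) {
    v <- pm$P[m & pm$valid_mask]
    if (!length(v)) NA_real_ else mean(v)
  }
  v1 <- vapply(seq$maps, roi_mean, numeric(1), m = m1)
  v2 <- vapply(seq$maps, roi_mean, numeric(1), m = m2)
  if (anyNA(v1) || anyNA(v2))
    warning("some frames had no valid ROI pixels; values set to NA")
  out <- data.frame(time_s = seq$timestamps, roi1 = v1, roi2 = v2)
  attr(out, "sampling_rate") <- seq$rate
  attr(out, "duration") <- diff(range(seq$timestamps))
  class(out) <- c("roi_series", "data.frame")
  out
}

#' Construct an ROI series directly from vectors
#'
#' Lets cohort-level or file-loaded ROI traces enter the shock-metric path
#' without going through image processing.
#' @param time_s timestamps in seconds.
#' @param roi1,roi2 perfusion values (arbitrary units).
#' @return an `roi_series`.
#' @export
roi_series <- function(time_s, roi1, roi2) {
  if (length(time_s) != length(roi1) || length(roi1) != length(roi2))
    stop_invalid("time_s, roi1, roi2 must have equal length")
  if (is.unsorted(time_s, strictly = TRUE))
    stop_invalid("time_s must be strictly increasing")
  out <- data.frame(time_s = time_s, roi1 = roi1, roi2 = roi2)
  attr(out, "sampling_rate") <-
    if (length(time_s) > 1) (length(time_s) - 1) / diff(range(time_s)) else NA_real_
  attr(out, "duration") <- diff(range(time_s))
  class(out) <- c("roi_series", "data.frame")
  out
}

#' Dual-ROI shock statistics over a time window
#'
#' Aggregates each ROI trace over the first `window_s` seconds of the
#' recording (configurable `offset_s`) and derives the two shock statistics:
#' the ROI difference `roi_diff = agg(ROI1) - agg(ROI2)` and its normalized
#' form `roi_ratio = roi_diff / agg(ROI2)`, which cancels global
#' illumination/gain changes.
#'
#' @param series an `roi_series`.
#' @param window_s window length in seconds (e.g. 10, 20, 30, 60); must not
#'   exceed the recording duration and must cover at least 3 samples.
#' @param aggregation `"mean"` (default) or `"median"`.
#' @param offset_s window start, seconds from recording start.
#' @return An object of class `shock_metrics`: `roi_diff`, `roi_ratio`,
#'   `roi1_agg`, `roi2_agg`, `window_s`, `offset_s`, `aggregation`,
#'   `n_samples`.
#' @export
#' @examples
#' s <- roi_series(seq(0, 59, by = 1/2.7)[1:162],
#'                 roi1 = rep(33674.6, 162), roi2 = rep(24656.0, 162))
#' compute_shock_metrics(s, window_s = 60)$roi_diff    # 9018.6
compute_shock_metrics <- function(series, window_s,
                                  aggregation = c("mean", "median"),
                                  offset_s = 0) {
  if (!inherits(series, "roi_series")) stop_invalid("series must be an roi_series")
  aggregation <- match.arg(aggregation)
  check_scalar_num(window_s, "window_s", positive = TRUE)
  check_scalar_num(offset_s, "offset_s")
  dur <- attr(series, "duration")
  if (window_s > dur + 1e-9 + 1)   # allow the last sample period
    stop_invalid("window_s exceeds the recording duration")
  t0 <- series$time_s[1] + offset_s
  inwin <- series$time_s >= t0 - 1e-9 & series$time_s < t0 + window_s - 1e-9
  if (sum(inwin) < 3L) stop_invalid("fewer than 3 samples in the window")
  agg <- if (aggregation == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) stats::median(v, na.rm = TRUE)
  }
  a1 <- agg(series$roi1[inwin])
  a2 <- agg(series$roi2[inwin])
  rd <- a1 - a2
  if (!is.finite(a2) || a2 <= 0)
    stop("roi_ratio undefined: aggregated ROI2 is not positive")
  structure(list(roi_diff = rd, roi_ratio = rd / a2,
                 roi1_agg = a1, roi2_agg = a2,
                 window_s = window_s, offset_s = offset_s,
                 aggregation = aggregation, n_samples = sum(inwin)),
            class = "shock_metrics")
}

#' @export
print.shock_metrics <- function(x, ...) {
  cat(sprintf(
    "<shock_metrics> window %g s (%s, n = %d): ROI diff = %.4g, ROI diff/ROI2 = %.4f\n",
    x$window_s, x$aggregation, x$n_samples, x$roi_diff, x$roi_ratio))
  invisible(x)
}
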