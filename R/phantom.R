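#' Acquisition configuration for a speckle imaging run
#'
#' Bundles the camera/illumination parameters that the contrast models need:
#' exposure time \eqn{T}, frame rate, laser wavelength \eqn{\lambda}, sensor
#' shape, pixel pitch and bit depth. Defaults match a near-infrared LSCI
#' system operating at 805 nm with a 5 ms exposure and 15 fps.
#'
#' @param exposure_time exposure \eqn{T} in seconds; must satisfy
#'   `exposure_time <= 1/frame_rate`.
#' @param frame_rate acquisition rate in Hz.
#' @param wavelength laser wavelength in meters.
#' @param sensor_shape integer `(height, width)` in pixels.
#' @param pixel_pitch physical size of one pixel on the object plane, mm/px.
#' @param bit_depth sensor bit depth (used when quantizing stacks for disk).
#' @return An object of class `acquisition_config`.
#' @export
#' @examples
#' acquisition_config()                      # the default 805 nm / 5 ms system
#' acquisition_config(exposure_time = 1e-3)  # shorter exposure
acquisition_config <- function(exposure_time = 0.005,
                               frame_rate = 15,
                               wavelength = 805e-9,
                               sensor_shape = c(1024L, 1280L),
                               pixel_pitch = 0.15625,
                               bit_depth = 16L) {
  check_scalar_num(exposure_time, "exposure_time", positive = TRUE)
  check_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  check_scalar_num(wavelength, "wavelength", positive = TRUE)
  check_scalar_num(pixel_pitch, "pixel_pitch", positive = TRUE)
  if (exposure_time > 1 / frame_rate)
    stop_invalid("exposure_time must not exceed the frame period 1/frame_rate")
  if (length(sensor_shape) != 2L || any(sensor_shape < 1))
    stop_invalid("sensor_shape must be positive (height, width)")
  structure(
    list(exposure_time = exposure_time,
         frame_rate = frame_rate,
         wavelength = wavelength,
         sensor_shape = as.integer(sensor_shape),
         pixel_pitch = pixel_pitch,
         bit_depth = as.integer(bit_depth)),
    class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> T = %g ms, %g fps, lambda = %g nm, %d x %d px\n",
    x$exposure_time * 1e3, x$frame_rate, x$wavelength * 1e9,
    x$sensor_shape[1], x$sensor_shape[2]))
  invisible(x)
}

#' Construct a flow phantom (ground-truth decorrelation-time map)
#'
#' A flow phantom holds the per-pixel speckle decorrelation time
#' \eqn{\tau_c(x, y)} (seconds) and the speckle-averaging correction factor
#' \eqn{\beta} used by [simulate_speckle_stack()]. Static regions are encoded
#' with `tau = Inf` (exact static-limit behavior rather than a large finite
#' stand-in).
#'
#' @param kind one of `"uniform"` (constant tau everywhere), `"two_region"`
#'   (left/right halves at two tau values, emulating a nail-bed vs
#'   fingertip-skin contrast), or `"vessel"` (a horizontal fast band across a
#'   slow background).
#' @param tau_values decorrelation time(s) in seconds; one value for
#'   `"uniform"`, two (fast, slow) for `"two_region"` and `"vessel"`. `Inf`
#'   marks static tissue.
#' @param shape integer `(height, width)` in pixels.
#' @param beta correction factor in (0, 1]; the static-limit speckle contrast
#'   squared equals `beta`.
#' @param label free-text description carried in outputs.
#' @return An object of class `flow_phantom` with fields `tau_map`
#'   (height x width matrix, seconds), `beta`, `shape`, `label`.
#' @export
#' @examples
#' ph <- make_phantom("two_region", tau_values = c(0.002, 0.008),
#'                    shape = c(64, 128))
#' range(ph$tau_map)
make_phantom <- function(kind = c("uniform", "two_region", "vessel"),
                         tau_values,
                         shape = c(64L, 64L),
                         beta = 1,
                         label = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(tau_values) || any(is.na(tau_values)) || any(tau_values <= 0))
    stop_invalid("tau_values must be positive (Inf allowed for static regions)")
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape < 1))
    stop_invalid("shape must be positive (height, width)")
  check_scalar_num(beta, "beta", positive = TRUE)
  if (beta > 1) stop_invalid("beta must lie in (0, 1]")
  shape <- as.integer(shape)
  h <- shape[1]; w <- shape[2]

  tau_map <- switch(kind,
    uniform = {
      if (length(tau_values) != 1L)
        stop_invalid("uniform phantom needs exactly one tau value")
      matrix(tau_values, h, w)
    },
    two_region = {
      if (length(tau_values) != 2L)
        stop_invalid("two_region phantom needs exactly two tau values")
      m <- matrix(tau_values[2], h, w)
      m[, seq_len(max(1L, w %/% 2L))] <- tau_values[1]
      m
    },
    vessel = {
      if (length(tau_values) != 2L)
        stop_invalid("vessel phantom needs (fast, slow) tau values")
      m <- matrix(tau_values[2], h, w)
      band <- max(1L, h %/% 8L)
      rows <- seq.int(h %/% 2L - band %/% 2L + 1L, length.out = band)
      m[rows, ] <- tau_values[1]
      m
    })

  structure(
    list(tau_map = tau_map, beta = beta, shape = shape,
         label = if (is.null(label)) kind else label),
    class = "flow_phantom")
}

#' @export
print.flow_phantom <- function(x, ...) {
  taus <- unique(as.vector(x$tau_map))
  cat(sprintf("<flow_phantom> '%s' %d x %d px, beta = %g, tau_c = {%s} s\n",
              x$label, x$shape[1], x$shape[2], x$beta,
              paste(signif(sort(taus), 4), collapse = ", ")))
  invisible(x)
}
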