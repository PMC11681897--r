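#' Simulate a raw speckle image stack with known flow ground truth
#'
#' Generates time-integrated speckle frames from a [make_phantom()] ground
#' truth. Each pixel carries an independent circular complex Gaussian field
#' whose amplitude autocorrelation decays as \eqn{\exp(-t/\tau_c)} (Lorentzian
#' velocity spectrum — the assumption under which the single-exposure contrast
#' models hold). The field is advanced as an AR(1) chain at `n_substeps`
#' points spanning the exposure \eqn{T}; the recorded intensity is the mean of
#' \eqn{|E|^2} over those points, i.e. a discrete exposure integral. Because
#' every pixel holds one independent speckle, a static phantom with
#' `beta = 1` yields fully developed speckle with global contrast
#' \eqn{K = 1}; finite \eqn{\tau_c} blurs the integral and lowers K exactly as
#' the single-exposure model predicts.
#'
#' Speckle averaging (\eqn{\beta < 1}) is emulated by shrinking each pixel's
#' intensity toward the mean of a statistically independent speckle
#' realization with weight calibrated so that static contrast satisfies
#' \eqn{K^2 = \beta}:
#' \eqn{I' = \sqrt{\beta} I + (1 - \sqrt{\beta}) \bar I_{indep}}.
#'
#' @param phantom a `flow_phantom`.
#' @param config an [acquisition_config()]; its `sensor_shape` is ignored in
#'   favor of the phantom shape.
#' @param n_frames number of frames to record.
#' @param n_substeps sub-integration points per exposure (default 32; bias in
#'   K below 2\% for `T/tau <= 4`). A warning is raised when the fastest
#'   phantom dynamics are under-resolved (`T/tau > n_substeps/4`).
#' @param seed integer seed; the same seed reproduces the stack bit for bit.
#' @param intensity_scale mean intensity in arbitrary units.
#' @param shot_noise if `TRUE`, replace each recorded intensity by a Poisson
#'   draw with that mean (photon shot noise).
#' @return An object of class `speckle_stack`: `frames` (array
#'   `[n_frames, height, width]`), `config`, `timestamps` (frame start times,
#'   seconds), `phantom_label`, `seed`.
#' @export
#' @examples
#' ph <- make_phantom("uniform", tau_values = 0.005, shape = c(32, 32))
#' st <- simulate_speckle_stack(ph, acquisition_config(), n_frames = 5, seed = 1)
#' dim(st$frames)
simulate_speckle_stack <- function(phantom,
                                   config = acquisition_config(),
                                   n_frames = 30,
                                   n_substeps = 32,
                                   seed,
                                   intensity_scale = 1000,
                                   shot_noise = FALSE) {
  if (!inherits(phantom, "flow_phantom")) stop_invalid("phantom must be a flow_phantom")
  if (!inherits(config, "acquisition_config")) stop_invalid("config must be an acquisition_config")
  n_frames <- check_count(n_frames, "n_frames")
  n_substeps <- check_count(n_substeps, "n_substeps", min = 8L)
  if (missing(seed)) stop_invalid("seed is required (reproducibility contract)")
  seed <- check_count(seed, "seed", min = 0L)
  check_scalar_num(intensity_scale, "intensity_scale", positive = TRUE)

  T_exp <- config$exposure_time
  h <- phantom$shape[1]; w <- phantom$shape[2]
  npix <- h * w
  tau <- as.vector(phantom$tau_map)

  tt_ratio <- T_exp / tau                      # 0 for static pixels
  if (any(tt_ratio > n_substeps / 4))
    warning(sprintf(
      "T/tau_c up to %.3g under-resolved by n_substeps = %d (limit n_substeps/4 = %g); K will be biased",
      max(tt_ratio), n_substeps, n_substeps / 4))

  dt <- T_exp / n_substeps
  rho_step <- exp(-dt / tau)                   # 1 for static pixels
  gap <- 1 / config$frame_rate - T_exp + dt
  rho_gap <- exp(-gap / tau)
  sig_step <- sqrt(pmax(0, 1 - rho_step^2))
  sig_gap <- sqrt(pmax(0, 1 - rho_gap^2))

  set.seed(seed)
  # stationary initial field: unit-power circular complex Gaussian
  draw_field <- function(n) complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                                    imaginary = stats::rnorm(n, sd = sqrt(0.5)))
  E <- draw_field(npix)

  frames <- array(0, dim = c(n_frames, h, w))
  acc <- numeric(npix)
  for (f in seq_len(n_frames)) {
    acc[] <- 0
    for (k in seq_len(n_substeps)) {
      if (f > 1L || k > 1L) {
        if (k == 1L) { rho <- rho_gap; sig <- sig_gap }
        else         { rho <- rho_step; sig <- sig_step }
        E <- rho * E + sig * draw_field(npix)
      }
      acc <- acc + Re(E * Conj(E))
    }
    frames[f, , ] <- acc / n_substeps
  }

  # speckle-averaging correction: static K^2 = beta
  if (phantom$beta < 1) {
    w_mix <- sqrt(phantom$beta)
    indep_mean <- mean(Re(draw_field(npix) * Conj(draw_field(npix))))
    frames <- w_mix * frames + (1 - w_mix) * indep_mean
  }
  frames <- frames * intensity_scale
  if (isTRUE(shot_noise)) {
    frames[] <- stats::rpois(length(frames), lambda = frames)
  }

  structure(
    list(frames = frames,
         config = config,
         timestamps = (seq_len(n_frames) - 1) / config$frame_rate,
         phantom_label = phantom$label,
         seed = seed),
    class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<speckle_stack> %d frames of %d x %d px, %g fps, T = %g ms, seed = %d\n",
              d[1], d[2], d[3], x$config$frame_rate,
              x$config$exposure_time * 1e3, x$seed))
  invisible(x)
}

#' Simulate a single static fully developed speckle frame
#'
#' Convenience generator for calibration and acceptance checks: intensity is
#' the squared magnitude of a unit-power circular complex Gaussian field with
#' one independent speckle per pixel, so the intensity histogram is negative
#' exponential and the global contrast is \eqn{K = 1} (scaled by
#' \eqn{\sqrt{\beta}} when `beta < 1`).
#'
#' @param shape `(height, width)` pixels.
#' @param beta speckle-averaging factor in (0, 1].
#' @param seed integer seed.
#' @return intensity matrix (mean approximately 1).
#' @export
static_speckle_frame <- function(shape = c(512L, 512L), beta = 1, seed) {
  if (missing(seed)) stop_invalid("seed is required")
  seed <- check_count(seed, "seed", min = 0L)
  check_scalar_num(beta, "beta", positive = TRUE)
  if (beta > 1) stop_invalid("beta must lie in (0, 1]")
  set.seed(seed)
  n <- prod(shape)
  I <- stats::rnorm(n, sd = sqrt(0.5))^2 + stats::rnorm(n, sd = sqrt(0.5))^2
  if (beta < 1) {
    w_mix <- sqrt(beta)
    I <- w_mix * I + (1 - w_mix) * mean(stats::rnorm(n, sd = sqrt(0.5))^2 +
                                          stats::rnorm(n, sd = sqrt(0.5))^2)
  }
  matrix(I, shape[1], shape[2])
}
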