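# braced single-exposure integral: 2/x^2 * (x - (1 - exp(-x))/1) with x = 2T/tau
# written via expm1 for numerical stability at small x
fb_k2 <- function(T, tau_c) {
  x <- 2 * T / tau_c                          # x -> 0 static, x -> Inf fast
  out <- ifelse(x < 1e-8, 1 - x / 2,          # series: (1 - e^-x)/x ~ 1 - x/2
                -expm1(-x) / x)
  out
}

bandyo_k2 <- function(T, tau_c) {
  x <- 2 * T / tau_c
  # tau/T + tau^2/(2T^2) (e^{-2T/tau} - 1) = (2/x) + (2/x^2)(e^{-x} - 1)
  ifelse(x < 1e-6, 1 - x / 3,                 # series expansion near static
         2 / x + 2 * expm1(-x) / x^2)
}

#' Single-exposure speckle contrast, velocity-distribution model
#'
#' The classic single-exposure relation between contrast and decorrelation
#' time: \eqn{K = \sqrt{(\tau_c / 2T)\,(1 - e^{-2T/\tau_c})}}. K lies in
#' (0, 1), tends to 1 in the static limit \eqn{T/\tau_c \to 0} and to 0 for
#' fast flow, and is strictly increasing in \eqn{\tau_c} at fixed exposure.
#'
#' @param T exposure time, seconds.
#' @param tau_c decorrelation time, seconds (`Inf` allowed: returns 1).
#' @return contrast K (vectorized over `tau_c`).
#' @export
#' @examples
#' contrast_fb(0.005, 0.005)      # T = tau_c: 0.65752
contrast_fb <- function(T, tau_c) {
  check_scalar_num(T, "T", positive = TRUE)
  if (any(tau_c <= 0, na.rm = TRUE)) stop_invalid("tau_c must be > 0")
  sqrt(fb_k2(T, tau_c))
}

#' Single-exposure speckle contrast with speckle-averaging correction
#'
#' Exposure-time-integrated contrast including the triangular weighting of
#' the intensity autocovariance and a speckle-averaging correction factor
#' \eqn{\beta}: by default
#' \deqn{K^2 = \beta \left[ \frac{\tau_c}{T} +
#'   \frac{\tau_c^2}{2T^2}\left(e^{-2T/\tau_c} - 1\right) \right],}
#' whose static limit is \eqn{K \to \sqrt{\beta}}. Some sources print the
#' right-hand side as equal to K itself; set `literal_form = TRUE` to
#' evaluate that printed variant (then the static limit is \eqn{K = \beta}).
#'
#' @param T exposure time, seconds.
#' @param tau_c decorrelation time, seconds.
#' @param beta correction factor in (0, 1].
#' @param literal_form use the as-printed `K = beta * {...}` variant.
#' @return contrast K (vectorized over `tau_c`).
#' @export
#' @examples
#' contrast_bandyo(0.005, 0.005)            # 0.75344
#' contrast_bandyo(0.005, 0.005, beta = 0.64)
contrast_bandyo <- function(T, tau_c, beta = 1, literal_form = FALSE) {
  check_scalar_num(T, "T", positive = TRUE)
  if (any(tau_c <= 0, na.rm = TRUE)) stop_invalid("tau_c must be > 0")
  check_scalar_num(beta, "beta", positive = TRUE)
  if (beta > 1) stop_invalid("beta must lie in (0, 1]")
  b <- bandyo_k2(T, tau_c)
  if (isTRUE(literal_form)) beta * b else sqrt(beta * b)
}

#' Specification of a contrast-decorrelation model
#'
#' @param model `"fercher_briers"` or `"bandyopadhyay"`.
#' @param beta correction factor (bandyopadhyay only).
#' @param literal_form evaluate the as-printed bandyopadhyay variant.
#' @return object of class `contrast_model_spec`.
#' @export
contrast_model_spec <- function(model = c("bandyopadhyay", "fercher_briers"),
                                beta = 1, literal_form = FALSE) {
  model <- match.arg(model)
  check_scalar_num(beta, "beta", positive = TRUE)
  if (beta > 1) stop_invalid("beta must lie in (0, 1]")
  structure(list(model = model, beta = beta,
                 literal_form = isTRUE(literal_form)),
            class = "contrast_model_spec")
}

model_forward <- function(spec, T, tau_c) {
  if (spec$model == "fercher_briers") contrast_fb(T, tau_c)
  else contrast_bandyo(T, tau_c, spec$beta, spec$literal_form)
}

model_static_limit <- function(spec) {
  if (spec$model == "fercher_briers") 1
  else if (spec$literal_form) spec$beta else sqrt(spec$beta)
}

#' Invert a contrast model to decorrelation time and velocity
#'
#' Solves forward(tau_c) = K for `tau_c` by bisection on
#' \eqn{\log_{10}(\tau_c / T)} over [-6, 6] (the forward models are strictly
#' increasing in `tau_c`, so the root is unique), followed by secant polish
#' to a residual below 1e-10. The particle velocity is then filled in via
#' [velocity_from_tau()].
#'
#' @param K measured contrast, strictly between 0 and the model's static
#'   limit (1 or \eqn{\sqrt\beta}).
#' @param T exposure time, seconds.
#' @param spec a [contrast_model_spec()].
#' @param wavelength laser wavelength (m) used for the velocity conversion.
#' @return An object of class `flow_estimate`: `tau_c` (s), `velocity` (m/s),
#'   `velocity_mm_s`, `model`, `K_input`, `T`.
#' @export
#' @examples
#' est <- invert_contrast(0.65752, T = 0.005,
#'                        spec = contrast_model_spec("fercher_briers"))
#' est$tau_c      # 0.005
invert_contrast <- function(K, T, spec = contrast_model_spec(),
                            wavelength = 805e-9) {
  check_scalar_num(T, "T", positive = TRUE)
  check_scalar_num(K, "K")
  if (!inherits(spec, "contrast_model_spec"))
    stop_invalid("spec must be a contrast_model_spec")
  if (K <= 0) stop_invalid("K must be > 0")
  kmax <- model_static_limit(spec)
  if (K >= kmax)
    stop(sprintf(
      "no solution: K = %g is at or above the static-limit contrast %g for model '%s'",
      K, kmax, spec$model))

  f <- function(lg) model_forward(spec, T, T * 10^lg) - K
  lo <- -6; hi <- 6
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0)
    stop(sprintf("K = %g not bracketed in tau_c/T within [1e-6, 1e6]", K))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= 1e-12) break
    if (fm < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-14) break
  }
  tau_c <- T * 10^((lo + hi) / 2)
  # secant polish on tau directly
  for (i in 1:8) {
    r <- model_forward(spec, T, tau_c) - K
    if (abs(r) <= 1e-12) break
    h <- tau_c * 1e-7
    dr <- (model_forward(spec, T, tau_c + h) - model_forward(spec, T, tau_c - h)) / (2 * h)
    if (!is.finite(dr) || dr == 0) break
    tau_c <- tau_c - r / dr
  }
  v <- velocity_from_tau(tau_c, wavelength)
  structure(list(tau_c = tau_c, velocity = v, velocity_mm_s = v * 1e3,
                 model = spec, K_input = K, T = T),
            class = "flow_estimate")
}

#' @export
print.flow_estimate <- function(x, ...) {
  cat(sprintf("<flow_estimate> tau_c = %.6g s, v = %.4g m/s (%.4g mm/s) [%s, K = %g, T = %g s]\n",
              x$tau_c, x$velocity, x$velocity_mm_s, x$model$model, x$K_input, x$T))
  invisible(x)
}

#' Scatterer velocity from decorrelation time
#'
#' \eqn{v_c = \lambda / (2\pi \tau_c)}: the characteristic speed of the
#' moving scatterers (red blood cells) implied by the speckle decorrelation
#' time at the illumination wavelength.
#'
#' @param tau_c decorrelation time, seconds.
#' @param wavelength wavelength in meters (default 805 nm, pulled from the
#'   default [acquisition_config()]).
#' @return velocity in m/s (vectorized).
#' @export
#' @examples
#' velocity_from_tau(1e-3)   # 1.2812e-4 m/s
velocity_from_tau <- function(tau_c,
                              wavelength = acquisition_config()$wavelength) {
  if (any(tau_c <= 0, na.rm = TRUE)) stop_invalid("tau_c must be > 0")
  check_scalar_num(wavelength, "wavelength", positive = TRUE)
  wavelength / (2 * pi * tau_c)
}

#' Estimate the speckle-averaging factor beta from a static stack
#'
#' Calibration helper: on a stack the user asserts to be static, the
#' static-limit relation \eqn{K^2 = \beta} gives
#' \eqn{\hat\beta = \mathrm{mean}(K^2)} over all valid pixels of all frames.
#' Because the windowed K uses the population variance of only
#' `window^2` samples, the raw mean of \eqn{K^2} underestimates
#' \eqn{\beta} by the factor \eqn{(n-1)/n}; the estimate is multiplied by
#' \eqn{n/(n-1)} to undo that finite-window bias.
#'
#' @param static_stack a `speckle_stack` of a static target.
#' @param window spatial contrast window (odd px).
#' @return estimated beta (scalar).
#' @export
estimate_beta <- function(static_stack, window = 7L) {
  if (!inherits(static_stack, "speckle_stack"))
    stop_invalid("static_stack must be a speckle_stack")
  n <- dim(static_stack$frames)[1]
  k2 <- numeric(0)
  nvalid <- 0
  for (f in seq_len(n)) {
    km <- spatial_contrast(static_stack$frames[f, , ], window)
    k2 <- c(k2, mean(km$K[km$valid_mask]^2))
    nvalid <- nvalid + sum(km$valid_mask)
  }
  if (nvalid < 1000)
    warning("fewer than 1000 valid pixels: low-confidence beta estimate")
  npx <- as.numeric(window)^2
  mean(k2) * npx / (npx - 1)
}
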