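# sliding-window sums over the valid interior via an integral image
box_sums <- function(m, w) {
  S <- apply(apply(m, 2, cumsum), 1, cumsum)      # transposed integral image
  S <- t(S)
  S <- rbind(0, cbind(0, S))                      # pad so S[i+1,j+1] = sum m[1:i,1:j]
  h <- nrow(m); wd <- ncol(m)
  ri <- seq_len(h - w + 1L); ci <- seq_len(wd - w + 1L)
  S[ri + w, ci + w, drop = FALSE] - S[ri, ci + w, drop = FALSE] -
    S[ri + w, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

#' Spatial speckle contrast map
#'
#' Computes the per-pixel speckle contrast \eqn{K = \sigma / \langle I
#' \rangle} — the ratio of the population standard deviation to the mean of
#' the intensity over a sliding `window` x `window` neighborhood. Border
#' pixels without a full window are masked invalid (no padding: no fabricated
#' statistics); pixels whose window mean is zero are masked rather than
#' propagating NaN. K is 1 for fully developed static speckle and decreases
#' with motion blur.
#'
#' @param frame non-negative 2-D intensity matrix.
#' @param window odd window side in pixels, between 3 and the smaller frame
#'   dimension (default 7, standard LSCI practice).
#' @return An object of class `contrast_map`: `K` (matrix, NA outside the
#'   valid mask), `valid_mask`, `window`, `frame_index`.
#' @export
#' @examples
#' fr <- static_speckle_frame(c(64, 64), seed = 1)
#' km <- spatial_contrast(fr, 7)
#' mean(km$K[km$valid_mask])     # close to 1
spatial_contrast <- function(frame, window = 7L) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop_invalid("frame must be a numeric matrix")
  if (any(frame < 0, na.rm = TRUE)) stop_invalid("frame must be non-negative")
  window <- check_count(window, "window", min = 3L)
  if (window %% 2L == 0L) stop_invalid("window must be odd")
  if (window > min(dim(frame))) stop_invalid("window exceeds frame dimensions")

  h <- nrow(frame); w <- ncol(frame)
  n <- window * window
  s1 <- box_sums(frame, window)
  s2 <- box_sums(frame * frame, window)
  mu <- s1 / n
  v <- pmax(s2 / n - mu^2, 0)                     # population variance

  Kin <- matrix(NA_real_, nrow(mu), ncol(mu))
  ok <- mu > 0
  Kin[ok] <- sqrt(v[ok]) / mu[ok]

  half <- (window - 1L) %/% 2L
  K <- matrix(NA_real_, h, w)
  valid <- matrix(FALSE, h, w)
  ri <- seq.int(half + 1L, h - half); ci <- seq.int(half + 1L, w - half)
  K[ri, ci] <- Kin
  valid[ri, ci] <- ok
  if (!any(valid)) warning("all-zero frame: contrast map fully masked")

  structure(list(K = K, valid_mask = valid, window = window,
                 frame_index = NA_integer_),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map> %d x %d px, window %d, mean K = %.4f (%d valid px)\n",
              nrow(x$K), ncol(x$K), x$window,
              mean(x$K[x$valid_mask]), sum(x$valid_mask)))
  invisible(x)
}

#' Mean contrast over the valid pixels of a contrast map
#' @param kmap a `contrast_map`.
#' @return scalar mean K.
#' @export
mean_contrast <- function(kmap) {
  if (!inherits(kmap, "contrast_map")) stop_invalid("kmap must be a contrast_map")
  mean(kmap$K[kmap$valid_mask])
}

#' Perfusion index map from a contrast map
#'
#' The perfusion index is the inverse-square of speckle contrast,
#' \eqn{P = 1/K^2}, the flow-proportional quantity used for the ROI shock
#' statistics. K is clamped at `k_floor` before squaring so saturated /
#' blur-free pixels do not explode.
#'
#' @param kmap a [spatial_contrast()] result.
#' @param k_floor positive clamp on K (default 0.01, so P caps at 1e4).
#' @return An object of class `perfusion_map`: `P` (matrix), `valid_mask`,
#'   `k_floor`, `frame_index`.
#' @export
perfusion_index <- function(kmap, k_floor = 0.01) {
  if (!inherits(kmap, "contrast_map")) stop_invalid("kmap must be a contrast_map")
  check_scalar_num(k_floor, "k_floor", positive = TRUE)
  P <- matrix(NA_real_, nrow(kmap$K), ncol(kmap$K))
  v <- kmap$valid_mask
  P[v] <- 1 / pmax(kmap$K[v], k_floor)^2
  structure(list(P = P, valid_mask = v, k_floor = k_floor,
                 frame_index = kmap$frame_index),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  cat(sprintf("<perfusion_map> %d x %d px, mean P = %.4g a.u. (%d valid px)\n",
              nrow(x$P), ncol(x$P), mean(x$P[x$valid_mask]), sum(x$valid_mask)))
  invisible(x)
}

#' Temporal speckle contrast
#'
#' Per-pixel contrast over sliding temporal windows of `window_frames`
#' frames: \eqn{K = \sigma_t / \langle I \rangle_t} at each pixel. On ergodic
#' simulated speckle this agrees with the spatial estimator; it serves as an
#' independent cross-check channel.
#'
#' @param stack a `speckle_stack`.
#' @param window_frames frames per window (>= 5, <= n_frames).
#' @return list of `contrast_map`, one per window position
#'   (`n_frames - window_frames + 1` maps); all pixels valid.
#' @export
temporal_contrast <- function(stack, window_frames) {
  if (!inherits(stack, "speckle_stack")) stop_invalid("stack must be a speckle_stack")
  window_frames <- check_count(window_frames, "window_frames", min = 5L)
  n <- dim(stack$frames)[1]
  if (window_frames > n) stop_invalid("window_frames exceeds number of frames")
  lapply(seq_len(n - window_frames + 1L), function(s) {
    sub <- stack$frames[s:(s + window_frames - 1L), , , drop = FALSE]
    mu <- apply(sub, c(2, 3), mean)
    v <- pmax(apply(sub * sub, c(2, 3), mean) - mu^2, 0)
    K <- matrix(NA_real_, nrow(mu), ncol(mu))
    ok <- mu > 0
    K[ok] <- sqrt(v[ok]) / mu[ok]
    structure(list(K = K, valid_mask = ok, window = window_frames,
                   frame_index = s),
              class = "contrast_map")
  })
}

#' Stream a speckle stack into perfusion maps at a reduced output rate
#'
#' Computes a spatial contrast and perfusion map for every raw frame, then
#' averages the perfusion maps within consecutive `1/output_rate`-second bins
#' (5 or 6 raw frames per bin for 15 fps input at the default 2.7 Hz), so the
#' emitted sequence has the system's effective "average sampling rate".
#' Averaging is done on the derived perfusion maps, not the raw frames, so
#' the speckle statistics inside each exposure are untouched.
#'
#' @param stack a `speckle_stack`.
#' @param window spatial contrast window (odd px).
#' @param output_rate output rate in Hz; must not exceed the frame rate.
#'   Default 2.7.
#' @param k_floor clamp passed to [perfusion_index()].
#' @return An object of class `perfusion_sequence`: `maps` (list of
#'   `perfusion_map`), `timestamps` (bin-mean times, seconds), `rate`.
#' @export
#' @examples
#' ph <- make_phantom("uniform", 0.005, shape = c(32, 32))
#' st <- simulate_speckle_stack(ph, n_frames = 15, seed = 3)
#' ps <- stream_process(st, window = 7, output_rate = 2.7)
#' length(ps$maps)
stream_process <- function(stack, window = 7L, output_rate = 2.7,
                           k_floor = 0.01) {
  if (!inherits(stack, "speckle_stack")) stop_invalid("stack must be a speckle_stack")
  check_scalar_num(output_rate, "output_rate", positive = TRUE)
  if (output_rate > stack$config$frame_rate)
    stop_invalid("output_rate must not exceed the frame rate")
  n <- dim(stack$frames)[1]
  bins <- floor(stack$timestamps * output_rate + 1e-9)
  ubins <- sort(unique(bins))
  maps <- vector("list", length(ubins))
  ts <- numeric(length(ubins))
  for (i in seq_along(ubins)) {
    idx <- which(bins == ubins[i])
    pm <- NULL
    for (f in idx) {
      km <- spatial_contrast(stack$frames[f, , ], window)
      km$frame_index <- f
      p <- perfusion_index(km, k_floor)
      if (is.null(pm)) {
        pm <- p
        pm$P[!pm$valid_mask] <- NA_real_
      } else {
        pm$P <- pm$P + p$P
        pm$valid_mask <- pm$valid_mask & p$valid_mask
      }
    }
    pm$P <- pm$P / length(idx)
    pm$frame_index <- idx[1]
    maps[[i]] <- pm
    ts[i] <- mean(stack$timestamps[idx])
  }
  structure(list(maps = maps, timestamps = ts, rate = output_rate),
            class = "perfusion_sequence")
}

#' @export
print.perfusion_sequence <- function(x, ...) {
  cat(sprintf("<perfusion_sequence> %d maps at %g Hz spanning %.2f s\n",
              length(x$maps), x$rate, diff(range(x$timestamps))))
  invisible(x)
}
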