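as_rr <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 2L) stop_invalid("need at least 2 RR intervals")
  if (any(!is.finite(rr)) || any(rr <= 0)) stop_invalid("RR intervals must be positive")
  rr
}

#' Time-domain HRV metrics
#'
#' SDRR (sample SD of the intervals, ms), RMSSD (root mean square of
#' successive differences, ms) and pNN50 (percentage of successive
#' differences exceeding 50 ms).
#'
#' @param rr RR intervals in ms (an `rr_series` or plain numeric vector).
#' @return list `sdrr`, `rmssd`, `pnn50`.
#' @export
#' @examples
#' hrv_time_domain(c(800, 810, 790, 800))   # rmssd 14.142
hrv_time_domain <- function(rr) {
  rr <- as_rr(rr)
  d <- diff(rr)
  list(sdrr = stats::sd(rr),
       rmssd = sqrt(mean(d^2)),
       pnn50 = 100 * mean(abs(d) > 50))
}

#' Poincare plot descriptors SD1 and SD2
#'
#' SD1 is the dispersion of the (RR_n, RR_n+1) scatter perpendicular to the
#' identity line, SD2 the population-SD dispersion along it (about its
#' mean). SD1 is measured about the identity line itself (the root mean
#' square of the rotated coordinate, no mean subtraction), so the identity
#' `sd1 = rmssd / sqrt(2)` holds exactly for any series, drifting or not.
#'
#' @param rr RR intervals in ms.
#' @return list `sd1`, `sd2` (ms).
#' @export
hrv_poincare <- function(rr) {
  rr <- as_rr(rr)
  a <- rr[-length(rr)]; b <- rr[-1]
  list(sd1 = sqrt(mean(((b - a) / sqrt(2))^2)),
       sd2 = pop_sd((b + a) / sqrt(2)))
}

# Welch PSD of the evenly resampled tachogram; returns freq (Hz) and
# one-sided density (ms^2/Hz) such that sum(psd) * df ~ variance
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, max(64L, 2L^floor(log2(n / 2))))
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  norm <- fs * sum(w^2)
  nf <- seg_len %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / norm
    half <- sp[seq_len(nf + 1L)]
    half[-c(1L, if (seg_len %% 2L == 0L) nf + 1L)] <-
      2 * half[-c(1L, if (seg_len %% 2L == 0L) nf + 1L)]   # one-sided
    acc <- acc + half
  }
  list(freq = (0:nf) * fs / seg_len, psd = acc / length(starts))
}

#' Spectral band power of an RR series
#'
#' The irregularly sampled tachogram is resampled to an evenly spaced series
#' at `resample_hz` by linear interpolation (time axis from the cumulative
#' interval sum), the mean removed, and a Hann-windowed Welch periodogram
#' integrated over the requested band: VLF 0.0033-0.04 Hz or LF 0.04-0.15 Hz
#' (Task-Force band edges). Records shorter than `2 / f_low` of the band
#' error out; VLF on ~90 s records is flagged low-confidence by a warning.
#'
#' @param rr RR intervals in ms.
#' @param band `"VLF"` or `"LF"`.
#' @param resample_hz tachogram resampling rate (default 4 Hz).
#' @return band power in ms^2.
#' @export
hrv_band_power <- function(rr, band = c("LF", "VLF"), resample_hz = 4) {
  band <- match.arg(band)
  rr <- as_rr(rr)
  edges <- switch(band, VLF = c(0.0033, 0.04), LF = c(0.04, 0.15))
  t_beat <- cumsum(rr) / 1000                         # seconds at beat ends
  dur <- t_beat[length(t_beat)] - t_beat[1]
  # hard floor: one cycle at the band's upper edge; below that the band is
  # simply not resolvable
  if (dur < 1 / edges[2])
    stop(sprintf("record of %.1f s too short for the %s band (need >= %.1f s)",
                 dur, band, 1 / edges[2]))
  # two cycles of the band's lower edge for full confidence (so VLF on the
  # typical ~90 s bedside record computes, but flagged)
  if (dur < 2 / edges[1])
    warning(sprintf("%s power on a %.0f s record is low-confidence (< %.0f s)",
                    band, dur, 2 / edges[1]))
  tg <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / resample_hz)
  x <- stats::approx(t_beat, rr, xout = tg)$y
  sp <- welch_psd(x, fs = resample_hz)
  df <- sp$freq[2] - sp$freq[1]
  inband <- sp$freq >= edges[1] & sp$freq <= edges[2]
  sum(sp$psd[inband]) * df
}

#' Sample entropy of an RR series
#'
#' SampEn(m, r, N) = -ln(A/B) where B counts template pairs of length `m`
#' within Chebyshev distance `r = r_frac * SD(rr)` and A counts pairs of
#' length `m + 1`; self-matches are excluded. Returns `NA` with a warning
#' when A or B is zero (undefined, not infinite).
#'
#' @param rr RR intervals in ms.
#' @param m embedding dimension (default 2).
#' @param r_frac tolerance as a fraction of the sample SD (default 0.2).
#' @return sample entropy (dimensionless) or `NA`.
#' @export
sampen <- function(rr, m = 2L, r_frac = 0.2) {
  rr <- as_rr(rr)
  m <- check_count(m, "m")
  check_scalar_num(r_frac, "r_frac", positive = TRUE)
  n <- length(rr)
  if (n < m + 2L) stop_invalid("series too short for the embedding dimension")
  r <- r_frac * stats::sd(rr)
  if (r == 0) r <- .Machine$double.eps        # constant series: all match

  # both template lengths use the same i range 1..(n - m) so that a constant
  # series gives A = B exactly (standard SampEn convention)
  count_pairs <- function(mm) {
    nt <- n - m
    # running Chebyshev distance between all template pairs, built one
    # coordinate at a time to stay O(n^2) in memory-friendly chunks
    total <- 0
    for (i in seq_len(nt - 1L)) {
      js <- (i + 1L):nt
      dmax <- abs(rr[i] - rr[js])
      for (k in seq_len(mm - 1L)) {
        dmax <- pmax(dmax, abs(rr[i + k] - rr[js + k]))
      }
      total <- total + sum(dmax <= r)
    }
    total
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (A == 0 || B == 0) {
    warning("sample entropy undefined: no template matches at one length")
    return(NA_real_)
  }
  -log(A / B)
}

#' Higuchi fractal dimension of an RR series
#'
#' Computes Higuchi's average curve length L(k) for scales k = 1..k_max and
#' returns the negative slope of the least-squares fit of ln L(k) on ln k.
#' Smooth curves give FD near 1; white noise gives FD near 2.
#'
#' @param rr RR intervals (or any bounded series).
#' @param k_max largest scale (default 10, >= 2).
#' @return fractal dimension (dimensionless).
#' @export
higuchi_fd <- function(rr, k_max = 10L) {
  rr <- as.numeric(rr)
  if (any(!is.finite(rr))) stop_invalid("series must be finite")
  k_max <- check_count(k_max, "k_max")
  if (k_max < 2L) stop_invalid("k_max must be >= 2 (need at least two scales)")
  n <- length(rr)
  if (n <= k_max + 1L) stop_invalid("series too short for k_max")
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m0 in seq_len(k)) {
      idx <- seq.int(m0, n, by = k)
      nk <- length(idx) - 1L
      if (nk < 1L) { Lm[m0] <- NA; next }
      Lm[m0] <- sum(abs(diff(rr[idx]))) * (n - 1) / (nk * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  fit <- stats::lm.fit(cbind(1, log(seq_len(k_max))), log(Lk))
  -unname(fit$coefficients[2])
}

#' Full HRV summary
#'
#' Convenience wrapper computing every metric the toolkit exposes on one
#' RR-interval series.
#'
#' @param rr RR intervals in ms.
#' @param vlf include VLF power (warns on short records).
#' @return named list: `sdrr`, `rmssd`, `pnn50`, `sd1`, `sd2`, `lf_power`,
#'   optionally `vlf_power`, `sampen`, `higuchi_fd`.
#' @export
hrv_summary <- function(rr, vlf = FALSE) {
  td <- hrv_time_domain(rr)
  pc <- hrv_poincare(rr)
  out <- c(td, pc,
           list(lf_power = hrv_band_power(rr, "LF")))
  if (vlf) out$vlf_power <- hrv_band_power(rr, "VLF")
  out$sampen <- sampen(rr)
  out$higuchi_fd <- higuchi_fd(rr)
  out
}
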