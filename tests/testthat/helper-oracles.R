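# Independent brute-force oracles. These deliberately avoid the package's
# code paths: two explicit loops, scalar arithmetic, no shared helpers.

# sigma/mean over every full window, two-loop version of spatial_contrast
naive_contrast <- function(frame, window) {
  h <- nrow(frame); w <- ncol(frame)
  half <- (window - 1) %/% 2
  K <- matrix(NA_real_, h, w)
  for (i in (half + 1):(h - half)) {
    for (j in (half + 1):(w - half)) {
      patch <- frame[(i - half):(i + half), (j - half):(j + half)]
      mu <- sum(patch) / length(patch)
      if (mu > 0) {
        v <- sum((patch - mu)^2) / length(patch)
        K[i, j] <- sqrt(v) / mu
      }
    }
  }
  K
}

# naive O(n^2) sample entropy, scalar loops, self-matches excluded;
# both template lengths range over i = 1..(n - m)
naive_sampen <- function(x, m = 2, r) {
  n <- length(x)
  count <- function(mm) {
    total <- 0
    for (i in 1:(n - m - 1)) {
      for (j in (i + 1):(n - m)) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) total <- total + 1
      }
    }
    total
  }
  -log(count(m + 1) / count(m))
}

# AUC by exhaustive concordant-pair counting (positives score LOWER)
naive_auc_below <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p < q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

pop_sd_test <- function(x) sqrt(mean((x - mean(x))^2))

model_forward_test <- function(spec, T_exp, tau) {
  if (spec$model == "fercher_briers") contrast_fb(T_exp, tau)
  else contrast_bandyo(T_exp, tau, spec$beta, spec$literal_form)
}

# mean of a normal truncated to [lo, hi]
trunc_norm_mean <- function(mu, sigma, lo, hi) {
  if (sigma == 0) return(mu)
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# build a speckle_stack-shaped object from an array without simulating
fake_stack <- function(frames, frame_rate = 15, exposure = 0.005) {
  structure(
    list(frames = frames,
         config = acquisition_config(exposure_time = exposure,
                                     frame_rate = frame_rate,
                                     sensor_shape = dim(frames)[2:3]),
         timestamps = (seq_len(dim(frames)[1]) - 1) / frame_rate,
         phantom_label = "fake", seed = 0L),
    class = "speckle_stack")
}
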