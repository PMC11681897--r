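test_that("time-domain metrics match hand computations", {
  c800 <- rep(800, 50)
  td <- hrv_time_domain(c800)
  expect_equal(unlist(td), c(sdrr = 0, rmssd = 0, pnn50 = 0))

  alt <- rep(c(800, 860), 50)                 # every successive diff is 60 ms
  td2 <- hrv_time_domain(alt)
  expect_equal(td2$rmssd, 60)
  expect_equal(td2$pnn50, 100)

  td3 <- hrv_time_domain(c(800, 810, 790, 800))
  expect_equal(td3$rmssd, sqrt((100 + 400 + 100) / 3), tolerance = 1e-12)
  expect_equal(td3$sdrr, sd(c(800, 810, 790, 800)))

  expect_error(hrv_time_domain(800), class = "lsci_invalid_parameter")
  expect_error(hrv_time_domain(c(800, -5)), class = "lsci_invalid_parameter")
})

test_that("poincare: sd1 = rmssd/sqrt(2) identity, degenerate and iid behavior", {
  set.seed(1)
  for (i in 1:10) {
    rr <- 800 + cumsum(rnorm(200, sd = 10))   # drifting series included
    rr <- pmax(rr, 300)
    expect_equal(hrv_poincare(rr)$sd1, hrv_time_domain(rr)$rmssd / sqrt(2),
                 tolerance = 1e-9)
  }
  pc0 <- hrv_poincare(rep(800, 20))
  expect_equal(c(pc0$sd1, pc0$sd2), c(0, 0))

  rr <- simulate_rr_series(800, 50, 2e4, seed = 2)
  pc <- hrv_poincare(rr)
  sdrr <- hrv_time_domain(rr)$sdrr
  expect_lt(abs(pc$sd1 - sdrr) / sdrr, 0.10)
  expect_lt(abs(pc$sd2 - sdrr) / sdrr, 0.10)
})

test_that("band power: sine calibration, constant series, flat spectrum", {
  # 0.1 Hz modulation of amplitude A on a 300-s tachogram -> LF power ~ A^2/2
  A <- 40
  n <- 400                                    # ~300 s of 750-ms beats
  tbeat <- cumsum(rep(750, n)) / 1000
  rr <- 750 + A * sin(2 * pi * 0.1 * tbeat)
  lf <- hrv_band_power(rr, "LF")
  vlf <- suppressWarnings(hrv_band_power(rr, "VLF"))
  expect_lt(abs(lf - A^2 / 2) / (A^2 / 2), 0.15)
  expect_lt(vlf, 0.05 * lf)

  expect_lt(hrv_band_power(rep(800, 500), "LF"), 1e-12)

  # white-noise RR: spectrum flat well below the beat Nyquist (~0.625 Hz),
  # so per-Hz power in the LF band matches an equal-width neighboring band
  rr <- simulate_rr_series(800, 50, 4000, seed = 9)
  lf <- hrv_band_power(rr, "LF")               # 0.04-0.15 Hz
  vlf2 <- hrv_band_power(rr, "VLF")            # 0.0033-0.04 Hz
  dens_lf <- lf / (0.15 - 0.04)
  dens_vlf <- vlf2 / (0.04 - 0.0033)
  expect_lt(abs(dens_lf - dens_vlf) / dens_lf, 0.2)

  expect_error(hrv_band_power(rep(800, 6), "LF"), "too short")
  expect_warning(hrv_band_power(rep(c(700, 900), 60), "VLF"), "low-confidence")
})

test_that("sampen: degenerate cases and naive O(n^2) oracle agreement", {
  expect_equal(sampen(rep(800, 60)), 0)
  # strictly periodic alternation with r below half the gap: still all matches
  alt <- rep(c(800, 860), 30)
  expect_equal(sampen(alt, r_frac = 0.2), 0)   # r = 0.2*30.25 < 30

  rr <- simulate_rr_series(800, 50, 500, seed = 4)
  r <- 0.2 * sd(rr)
  got <- sampen(rr)
  oracle <- naive_sampen(as.numeric(rr), m = 2, r = r)
  expect_lt(abs(got - oracle) / oracle, 1e-9)  # same counts, different route
  expect_gt(got, 0.5)                          # iid series is irregular

  expect_warning(out <- sampen(c(1, 500, 3, 800, 2, 950), m = 2, r_frac = 0.01),
                 "undefined")
  expect_true(is.na(out))
})

test_that("higuchi fractal dimension: ramp ~ 1, white noise ~ 2, guards", {
  expect_lt(abs(higuchi_fd(seq(700, 900, length.out = 1000)) - 1), 0.01)
  set.seed(5)
  expect_lt(abs(higuchi_fd(rnorm(1000)) - 2), 0.1)
  expect_error(higuchi_fd(1:100, k_max = 1), class = "lsci_invalid_parameter")
  expect_error(higuchi_fd(1:5, k_max = 10), class = "lsci_invalid_parameter")
})

test_that("metrics respond correctly to adding a constant to every interval", {
  rr <- as.numeric(simulate_rr_series(800, 40, 400, seed = 6))
  rr2 <- rr + 150
  td <- hrv_time_domain(rr); td2 <- hrv_time_domain(rr2)
  expect_equal(td2$sdrr, td$sdrr)
  expect_equal(td2$rmssd, td$rmssd)
  expect_equal(td2$pnn50, td$pnn50)
  expect_equal(hrv_poincare(rr2)$sd1, hrv_poincare(rr)$sd1)
  # adding a constant changes the beat times (the physical time axis), so
  # band power is only approximately invariant after resampling
  expect_equal(hrv_band_power(rr2, "LF"), hrv_band_power(rr, "LF"),
               tolerance = 0.15)
  expect_equal(sampen(rr2), sampen(rr))        # r scales with SD, SD unchanged
})

test_that("parameter recovery: generator dispersion recovered by the metrics", {
  rr <- simulate_rr_series(900, 35, 1e4, seed = 7)
  expect_lt(abs(hrv_time_domain(rr)$sdrr - 35) / 35, 0.05)
  expect_lt(abs(mean(rr) - 900) / 900, 0.01)
})

test_that("hrv_summary aggregates all metrics", {
  rr <- simulate_rr_series(800, 40, 500, seed = 8)
  hs <- hrv_summary(rr)
  expect_named(hs, c("sdrr", "rmssd", "pnn50", "sd1", "sd2", "lf_power",
                     "sampen", "higuchi_fd"))
  expect_true(all(vapply(hs, is.finite, logical(1))))
  expect_true(hs$higuchi_fd >= 1 && hs$higuchi_fd <= 2.1)
})
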