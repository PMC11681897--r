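test_that("make_phantom lays out tau maps as requested and validates input", {
  ph <- make_phantom("uniform", 0.005, c(64, 64))
  expect_true(all(ph$tau_map == 0.005))
  expect_equal(dim(ph$tau_map), c(64L, 64L))

  ph2 <- make_phantom("two_region", c(0.002, 0.008), c(64, 128))
  expect_true(all(ph2$tau_map[, 1:64] == 0.002))
  expect_true(all(ph2$tau_map[, 65:128] == 0.008))

  phv <- make_phantom("vessel", c(0.001, 0.02), c(64, 32))
  expect_setequal(unique(as.vector(phv$tau_map)), c(0.001, 0.02))

  expect_error(make_phantom("uniform", -1, c(8, 8)), class = "lsci_invalid_parameter")
  expect_error(make_phantom("uniform", 0.005, c(0, 8)), class = "lsci_invalid_parameter")
  expect_error(make_phantom("uniform", 0.005, c(8, 8), beta = 1.5),
               class = "lsci_invalid_parameter")
})

test_that("same seed gives bit-identical simulator output, different seed differs", {
  ph <- make_phantom("uniform", 0.005, c(16, 16))
  a <- simulate_speckle_stack(ph, n_frames = 3, seed = 7)
  b <- simulate_speckle_stack(ph, n_frames = 3, seed = 7)
  c <- simulate_speckle_stack(ph, n_frames = 3, seed = 8)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))

  co1 <- simulate_cohort(5, 5, seed = 3)
  co2 <- simulate_cohort(5, 5, seed = 3)
  expect_identical(co1, co2)

  rr1 <- simulate_rr_series(800, 50, 50, seed = 5)
  rr2 <- simulate_rr_series(800, 50, 50, seed = 5)
  expect_identical(as.numeric(rr1), as.numeric(rr2))
})

test_that("static fully developed speckle has exponential intensities and K near 1", {
  fr <- static_speckle_frame(c(512, 512), seed = 1)   # 2.6e5 pixels
  I <- as.vector(fr)
  ks <- suppressWarnings(stats::ks.test(I, "pexp", rate = 1 / mean(I)))
  expect_gt(ks$p.value, 0.01)
  K <- pop_sd_test(I) / mean(I)
  expect_lt(abs(K - 1), 0.02)

  # sqrt(beta) scaling of the static contrast
  fr8 <- static_speckle_frame(c(512, 512), beta = 0.8, seed = 2)
  K8 <- pop_sd_test(as.vector(fr8)) / mean(fr8)
  expect_lt(abs(K8 - sqrt(0.8)), 0.02 * sqrt(0.8))
})

test_that("under-resolved exposure sampling warns, n_substeps floor enforced", {
  ph <- make_phantom("uniform", 0.0005, c(8, 8))      # T/tau = 10 > 32/4
  expect_warning(simulate_speckle_stack(ph, n_frames = 1, seed = 1),
                 "under-resolved")
  expect_error(simulate_speckle_stack(ph, n_frames = 1, n_substeps = 4, seed = 1),
               class = "lsci_invalid_parameter")
  expect_error(simulate_speckle_stack(ph, n_frames = 1),
               class = "lsci_invalid_parameter")    # seed mandatory
})

test_that("empirical K decreases monotonically as tau_c decreases at fixed T", {
  taus <- c(0.02, 0.005, 0.002, 0.0008)
  ks <- vapply(seq_along(taus), function(i) {
    ph <- make_phantom("uniform", taus[i], c(48, 48))
    st <- suppressWarnings(
      simulate_speckle_stack(ph, n_frames = 8, n_substeps = 64, seed = 100 + i))
    mean(vapply(1:8, function(f)
      mean_contrast(spatial_contrast(st$frames[f, , ], 7)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("cohort generator hits its truncated-normal expectations and invariants", {
  params <- cohort_reference_params()
  co <- simulate_cohort(20, 20, seed = 101)
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 40)
  expect_true(all(co$SBP >= co$DBP))
  expect_true(all(co$SpO2 <= 100 & co$SpO2 > 0))
  expect_equal(co$SI, co$HR / co$SBP)
  expect_equal(co$ROI_diff, co$ROI1 - co$ROI2)

  # sample means within 2 SE of the generator's analytic expectation
  for (grp in c("study", "control")) {
    sub <- co[co$group == grp, ]
    for (i in seq_len(nrow(params))) {
      v <- params$variable[i]
      mu <- params[[paste0(grp, "_mean")]][i]
      sg <- params[[paste0(grp, "_sd")]][i]
      if (is.na(mu)) next
      target <- trunc_norm_mean(mu, sg, params$lower[i], params$upper[i])
      expect_lt(abs(mean(sub[[v]]) - target), 2 * sg / sqrt(20) + 1e-12,
                label = sprintf("%s %s mean", grp, v))
    }
  }

  # variables with negligible truncation also match the nominal table means
  for (v in c("SBP", "HR", "ROI1")) {
    i <- match(v, params$variable)
    expect_lt(abs(mean(co[co$group == "study", v]) - params$study_mean[i]),
              2 * params$study_sd[i] / sqrt(20))
  }
})

test_that("large-n cohort reproduces the SBP effect size and error shrinks with n", {
  co <- simulate_cohort(1e4, 1e4, seed = 11)
  s <- co[co$group == "study", ]; c0 <- co[co$group == "control", ]
  d <- cohens_d(mean(s$SBP), sd(s$SBP), nrow(s),
                mean(c0$SBP), sd(c0$SBP), nrow(c0))
  expect_lt(abs(d - 1.9), 0.1)

  # aggregate normalized mean error over several variables shrinks with n
  vars <- c("SBP", "HR", "ROI1", "RR")
  targets <- c(91.9, 112.9, 33674.6, 21.9)
  sds <- c(18.6, 24.4, 15748.0, 3.2)
  errs <- vapply(c(20, 200, 2000), function(n) {
    cc <- simulate_cohort(n, 1, seed = 500 + n)
    s <- cc[cc$group == "study", ]
    mean(abs(vapply(seq_along(vars), function(i)
      (mean(s[[vars[i]]]) - targets[i]) / sds[i], numeric(1))))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("degenerate SD = 0 cohort collapses to the means", {
  params <- cohort_reference_params()
  params$study_sd[] <- 0
  params$control_sd[is.finite(params$control_sd)] <- 0
  co <- simulate_cohort(4, 4, params = params, seed = 1)
  s <- co[co$group == "study", ]
  expect_true(all(s$SBP == 91.9))
  expect_true(all(s$HR == 112.9))
  expect_equal(unique(s$SI), 112.9 / 91.9)
})

test_that("inconsistent cohort params (SBP mean < DBP mean) error", {
  params <- cohort_reference_params()
  params$study_mean[params$variable == "SBP"] <- 50
  expect_error(simulate_cohort(5, 5, params = params, seed = 1),
               class = "lsci_invalid_parameter")
})

test_that("rr series generator: constants, moments and AR(1) autocorrelation", {
  rr0 <- simulate_rr_series(800, 0, 100, seed = 1)
  expect_true(all(rr0 == 800))

  rr <- simulate_rr_series(800, 50, 1e4, seed = 2)
  expect_lt(abs(sd(rr) - 50) / 50, 0.03)

  rra <- simulate_rr_series(800, 50, 1e4, model = "ar1", ar_coeff = 0.9, seed = 3)
  ac1 <- cor(rra[-1], rra[-length(rra)])
  expect_lt(abs(ac1 - 0.9), 0.05)

  expect_warning(simulate_rr_series(200, 50, 10, seed = 1), "truncation")
})
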