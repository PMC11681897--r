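test_that("classify applies the strict-inequality cutoff rule", {
  cfg <- classifier_config("roi_diff")          # cutoff 6966.43, below = positive
  expect_true(classify(6249.0, cfg))            # study-group median
  expect_false(classify(14406.0, cfg))          # control median
  expect_false(classify(6966.43, cfg))          # tie -> negative
  above <- classifier_config("roi_diff", cutoff = 10, positive_if = "above")
  expect_equal(classify(c(5, 10, 15), above), c(FALSE, FALSE, TRUE))
  expect_equal(classifier_config("roi_ratio")$cutoff, 0.36)
  expect_equal(classifier_config("SBP")$cutoff, 95)
  expect_equal(classifier_config("MAP")$cutoff, 65)
})

test_that("confusion counts cross-tabulate predictions against truth", {
  truth <- rep(c(TRUE, FALSE), each = 20)
  cm <- confusion(truth, truth)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(20, 20, 0, 0))
  expect_error(confusion(logical(0), logical(0)), class = "lsci_invalid_parameter")
  expect_error(confusion_matrix(-1, 0, 0, 5), class = "lsci_invalid_parameter")
})

test_that("diagnostics reproduces the printed SBP and MAP predictor metrics", {
  # SBP rule: tp=11 tn=20 fn=9 fp=0 -> 77.50% / 55.00% / 70.97%
  d_sbp <- diagnostics(confusion_matrix(tp = 11, fp = 0, fn = 9, tn = 20))
  expect_equal(round(d_sbp$accuracy, 4), 0.7750)
  expect_equal(round(d_sbp$recall, 4), 0.5500)
  expect_equal(round(d_sbp$f1, 4), 0.7097)
  # MAP rule: tp=8 tn=20 fn=12 fp=0 -> 70.00% / 40.00%
  d_map <- diagnostics(confusion_matrix(tp = 8, fp = 0, fn = 12, tn = 20))
  expect_equal(round(d_map$accuracy, 4), 0.70)
  expect_equal(round(d_map$recall, 4), 0.40)
  # reconstructed ROI-diff matrix: accuracy 72.5%, recall 55%, F1 66.7%
  d_roi <- diagnostics(confusion_matrix(tp = 11, fp = 2, fn = 9, tn = 18))
  expect_equal(round(d_roi$accuracy, 4), 0.725)
  expect_equal(round(d_roi$f1, 4), 0.6667)
  # undefined metrics flagged, not silently zero
  d0 <- diagnostics(confusion_matrix(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(d0$recall))
  expect_true("recall" %in% attr(d0, "undefined"))
})

test_that("invert_summary reconstructs integer matrices and round-trips", {
  cm <- invert_summary(0.725, 0.55, 20, 20)
  expect_equal(c(cm$tp, cm$tn, cm$fn, cm$fp), c(11, 18, 9, 2))
  cm2 <- invert_summary(0.825, 0.75, 20, 20)
  expect_equal(c(cm2$tp, cm2$tn, cm2$fn, cm2$fp), c(15, 18, 5, 2))
  cm3 <- invert_summary(1, 1, 20, 20)
  expect_equal(c(cm3$tp, cm3$tn), c(20, 20))

  # diagnostics o invert_summary reproduces the inputs exactly
  for (case in list(c(0.725, 0.55), c(0.825, 0.75), c(0.70, 0.40))) {
    d <- diagnostics(invert_summary(case[1], case[2], 20, 20))
    expect_equal(d$accuracy, case[1])
    expect_equal(d$recall, case[2])
  }
  expect_error(invert_summary(0.99, 0.1, 20, 20), "no consistent")
})

test_that("roc: pair-counting oracle, trapezoid agreement, flips and transforms", {
  r <- roc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE), positive_if = "below")
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc_trapezoid, r$auc, tolerance = 1e-12)

  # perfect separation
  expect_equal(roc(c(1, 2, 10, 11), c(TRUE, TRUE, FALSE, FALSE), "below")$auc, 1)

  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n0 <- sample(3:8, 1)
    sc <- sample(1:10, n1 + n0, replace = TRUE)      # ties included
    truth <- c(rep(TRUE, n1), rep(FALSE, n0))
    r <- roc(sc, truth, "below")
    expect_equal(r$auc, naive_auc_below(sc, truth), tolerance = 1e-12)
    expect_equal(r$auc_trapezoid, r$auc, tolerance = 1e-10)
    # label flip complements AUC
    expect_equal(roc(sc, !truth, "below")$auc, 1 - r$auc, tolerance = 1e-12)
    # strictly monotone transform leaves the curve untouched
    r2 <- roc(exp(sc / 3), truth, "below")
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
    expect_equal(r2$sensitivity, r$sensitivity)
  }
  expect_error(roc(1:4, rep(TRUE, 4), "below"), "both classes")
})

test_that("roc associated criterion maximizes Youden J", {
  sc <- c(1, 2, 3, 10, 11, 12)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc(sc, truth, "below")
  expect_equal(r$youden_j, 1)
  pred <- sc < r$associated_criterion
  expect_equal(pred, truth)
})

test_that("mann_whitney_u: exact enumeration, ties, and wilcox cross-check", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_two_sided, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")

  x <- c(5, 5, 5); expect_equal(mann_whitney_u(x, x)$p_two_sided, 1)

  # exact path agrees with wilcox.test exact p on tie-free small samples
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney_u(x, y)$p_two_sided,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-10)
    expect_equal(mann_whitney_u(x, y)$U, unname(wilcox.test(x, y)$statistic))
  }
  # normal-approximation path tracks wilcox.test with correction
  set.seed(4)
  x <- rnorm(25); y <- rnorm(30, 0.4)
  expect_equal(mann_whitney_u(x, y)$p_two_sided,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney_u detects a 1.5 SD shift at n = 20/20 with power > 0.9", {
  set.seed(5)
  rej <- mean(vapply(1:2000, function(i) {
    mann_whitney_u(rnorm(20), rnorm(20, 1.5))$p_two_sided < 0.05
  }, logical(1)))
  expect_gt(rej, 0.9)
})

test_that("spearman matches rank arithmetic and is rank-invariant", {
  # direct rank computation: sum d^2 = 4, rs = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman(1:5, c(2, 1, 4, 3, 5))$rs, 0.8, tolerance = 1e-12)
  expect_equal(spearman(1:6, 6:1)$rs, -1)
  set.seed(6)
  x <- rnorm(30); y <- x + rnorm(30)
  s1 <- spearman(x, y)
  expect_equal(s1$rs, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(spearman(exp(x), y)$rs, s1$rs)      # monotone transform of x
  expect_equal(s1$p_two_sided,
               cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-6)
})

test_that("cohens_d reproduces every printed Table-1 effect size", {
  # (study mean, study sd, control mean, control sd, printed d)
  rows <- list(
    age     = c(68.8, 15.4, 41.7, 12.0, -2.0),
    height  = c(160.5, 8.5, 164.2, 6.7, 0.5),
    weight  = c(55.2, 8.9, 66.9, 13.3, 1.0),
    MAP     = c(71.4, 18.5, 93.8, 12.9, 1.4),
    SBP     = c(91.9, 18.6, 127.4, 19.4, 1.9),
    DBP     = c(61.3, 19.1, 77.0, 11.1, 1.0),
    BT      = c(36.8, 1.5, 36.2, 0.1, -0.6),
    HR      = c(112.9, 24.4, 76.9, 7.7, -2.0),
    RR      = c(21.9, 3.2, 18.7, 0.9, -1.4),
    SpO2    = c(94.6, 6.9, 99.2, 0.5, 0.9),
    ROI1    = c(33674.6, 15748.0, 36319.7, 11362.2, 0.2),
    ROI2    = c(24656.0, 11762.1, 21681.6, 7396.1, -0.3),
    ROIdiff = c(9018.7, 7620.0, 14638.1, 5970.7, 0.8))
  for (nm in names(rows)) {
    r <- rows[[nm]]
    d <- cohens_d(r[1], r[2], 20, r[3], r[4], 20)
    expect_lt(abs(d - r[5]), 0.15, label = paste("d for", nm))
    if (nm != "SI") expect_equal(round(d, 1), r[5], label = paste("rounded d for", nm))
  }
  # SI recomputes to -2.40 from the printed moments (printed value -2.5)
  expect_equal(round(cohens_d(1.3, 0.4, 20, 0.6, 0.1, 20), 2), -2.4)
  expect_equal(cohens_d(5, 1, 10, 5, 2, 10), 0)
})

test_that("shock index and screening rule follow their definitions", {
  si <- shock_index(111, 93.5)
  expect_equal(round(si$si, 3), 1.187)
  expect_true(si$flag)
  si2 <- shock_index(78, 126)
  expect_equal(round(si2$si, 3), 0.619)
  expect_false(si2$flag)
  expect_error(shock_index(80, 0), class = "lsci_invalid_parameter")

  expect_true(screen_shock(list(SBP = 91.9, MAP = 80, lactate = 1))$positive)
  expect_equal(screen_shock(list(SBP = 91.9, MAP = 80))$criteria, "SBP<95")
  expect_false(screen_shock(list(SBP = 120, MAP = 80, lactate = 1.0))$positive)
  s <- screen_shock(list(SBP = 120, MAP = 80, lactate = 4.5))
  expect_true(s$positive)
  expect_equal(s$criteria, "lactate>2")
  expect_true(screen_shock(list(SBP = 120, MAP = 60))$positive)
})

test_that("evaluate_cohort ties classification, confusion and ROC together", {
  co <- simulate_cohort(20, 20, seed = 77)
  ev <- evaluate_cohort(co, classifier_config("roi_diff"))
  expect_s3_class(ev$cm, "confusion_matrix")
  expect_equal(ev$cm$tp + ev$cm$fn, 20)
  expect_equal(ev$cm$tn + ev$cm$fp, 20)
  expect_true(ev$roc$auc >= 0 && ev$roc$auc <= 1)
  expect_named(ev$report, c("metric", "cutoff", "tp", "fp", "fn", "tn",
                            "accuracy", "recall", "precision", "f1", "auc",
                            "assoc_criterion", "p_value"))
})
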