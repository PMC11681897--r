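#' Classifier configuration (metric, cutoff, direction)
#'
#' Default cutoffs are the ROC-derived associated criteria and the hospital
#' screening thresholds: ROI diff 6966.43 (below = positive), ROI diff/ROI2
#' 0.36 (below = positive), SBP 95 mmHg (below), MAP 65 mmHg (below).
#'
#' @param metric one of `"roi_diff"`, `"roi_ratio"`, `"MAP"`, `"SBP"`.
#' @param cutoff threshold in the metric's units; `NULL` picks the default
#'   above.
#' @param positive_if `"below"` or `"above"`: which side of the cutoff is
#'   called shock-positive.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(metric = c("roi_diff", "roi_ratio", "MAP", "SBP"),
                              cutoff = NULL,
                              positive_if = c("below", "above")) {
  metric <- match.arg(metric)
  positive_if <- match.arg(positive_if)
  if (is.null(cutoff))
    cutoff <- switch(metric, roi_diff = 6966.43, roi_ratio = 0.36,
                     MAP = 65, SBP = 95)
  check_scalar_num(cutoff, "cutoff")
  structure(list(metric = metric, cutoff = cutoff, positive_if = positive_if),
            class = "classifier_config")
}

#' Classify metric values against a cutoff
#'
#' A value is labeled positive (shock) iff it is strictly below the cutoff
#' (or strictly above, per `positive_if`); ties at the cutoff are negative.
#'
#' @param values numeric metric values.
#' @param config a [classifier_config()].
#' @return logical vector, `TRUE` = positive.
#' @export
#' @examples
#' classify(c(6249, 14406), classifier_config("roi_diff"))
classify <- function(values, config = classifier_config()) {
  if (!inherits(config, "classifier_config"))
    stop_invalid("config must be a classifier_config")
  if (any(!is.finite(values))) stop_invalid("values must be finite")
  if (config$positive_if == "below") values < config$cutoff
  else values > config$cutoff
}

#' Cross-tabulate predictions against truth
#'
#' @param pred,truth logical vectors (`TRUE` = positive) of equal length.
#' @return object of class `confusion_matrix` with integer fields `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth) || anyNA(pred) || anyNA(truth))
    stop_invalid("pred and truth must be equal-length logicals without NA")
  if (!length(pred)) stop_invalid("empty input")
  confusion_matrix(tp = sum(pred & truth), fp = sum(pred & !truth),
                   fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Construct a confusion matrix from counts
#' @param tp,fp,fn,tn non-negative integer counts, total > 0.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) == 0)
    stop_invalid("counts must be non-negative integers with positive total")
  structure(stats::setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/total`, recall `tp/(tp+fn)`, precision `tp/(tp+fp)` and
#' F1 `2*precision*recall/(precision+recall)`. A metric whose denominator is
#' zero is returned as `NA` with its name listed in the `undefined`
#' attribute — never silently zero.
#'
#' @param cm a `confusion_matrix`.
#' @return named list `accuracy`, `recall`, `precision`, `f1` (fractions),
#'   with attribute `undefined`.
#' @export
#' @examples
#' diagnostics(confusion_matrix(tp = 11, fp = 0, fn = 9, tn = 20))
diagnostics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop_invalid("cm must be a confusion_matrix")
  undef <- character(0)
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  acc <- (cm$tp + cm$tn) / total
  rec <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else { undef <- c(undef, "recall"); NA_real_ }
  prec <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else { undef <- c(undef, "precision"); NA_real_ }
  f1 <- if (is.finite(rec) && is.finite(prec) && rec + prec > 0)
    2 * prec * rec / (prec + rec)
  else { undef <- c(undef, "f1"); NA_real_ }
  structure(list(accuracy = acc, recall = rec, precision = prec, f1 = f1),
            undefined = undef)
}

#' Reconstruct a confusion matrix from summary accuracy and recall
#'
#' Inverts the published summary of a two-class evaluation back to integer
#' counts: `tp = round(recall * n_pos)`, `tn = round(accuracy * total) - tp`,
#' `fn = n_pos - tp`, `fp = n_neg - tn`. Errors if no integer matrix is
#' consistent with the inputs within rounding tolerance 0.5.
#'
#' @param accuracy,recall fractions in `[0, 1]`.
#' @param n_pos,n_neg class sizes.
#' @return a `confusion_matrix` with attribute `residuals` (the rounding
#'   residuals for accuracy and recall).
#' @export
#' @examples
#' invert_summary(0.725, 0.55, 20, 20)    # tp=11 tn=18 fn=9 fp=2
invert_summary <- function(accuracy, recall, n_pos, n_neg) {
  check_scalar_num(accuracy, "accuracy"); check_scalar_num(recall, "recall")
  n_pos <- check_count(n_pos, "n_pos"); n_neg <- check_count(n_neg, "n_neg")
  total <- n_pos + n_neg
  tp_raw <- recall * n_pos
  tp <- round(tp_raw)
  tn_raw <- accuracy * total - tp
  tn <- round(tn_raw)
  res <- c(recall = tp_raw - tp, accuracy = tn_raw - tn)
  fn <- n_pos - tp
  fp <- n_neg - tn
  if (abs(res["recall"]) > 0.5 + 1e-9 || abs(res["accuracy"]) > 0.5 + 1e-9 ||
      tp < 0 || tn < 0 || fn < 0 || fp < 0)
    stop(sprintf(
      "no consistent integer confusion matrix; nearest candidate tp=%d tn=%d fn=%d fp=%d (residuals %.3f, %.3f)",
      tp, tn, fn, fp, res["recall"], res["accuracy"]))
  cm <- confusion_matrix(tp = tp, fp = fp, fn = fn, tn = tn)
  attr(cm, "residuals") <- res
  cm
}

#' Empirical ROC curve, AUC and the Youden-optimal associated criterion
#'
#' Sweeps every distinct score as a candidate cutoff with the package's
#' classification rule (strictly below / above = positive), records
#' sensitivity and specificity at each, and computes AUC two ways that must
#' agree: the trapezoid rule over the empirical curve and the Mann-Whitney
#' probability estimate `U/(n1*n2)` with ties counted one half. The
#' associated criterion is the threshold maximizing Youden's
#' J = sensitivity + specificity - 1; the p-value tests AUC = 0.5 via the
#' normal approximation on the U statistic (tie-corrected).
#'
#' @param scores numeric metric values.
#' @param truth logical, `TRUE` = diseased/positive class.
#' @param positive_if `"below"` (low score = positive, the perfusion
#'   convention) or `"above"`.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity` (aligned arrays), `auc`, `associated_criterion`,
#'   `youden_j`, `p_value`.
#' @export
#' @examples
#' roc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE), positive_if = "below")$auc
roc <- function(scores, truth, positive_if = c("below", "above")) {
  positive_if <- match.arg(positive_if)
  truth <- as.logical(truth)
  if (length(scores) != length(truth) || any(!is.finite(scores)) || anyNA(truth))
    stop_invalid("scores/truth must be finite and aligned")
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")

  # orient so that LOWER oriented score = positive
  s <- if (positive_if == "below") scores else -scores
  thr <- sort(unique(s))
  cand <- c(thr, max(thr) + 1)            # include all-positive rule
  sens <- spec <- numeric(length(cand))
  for (i in seq_along(cand)) {
    pred <- s < cand[i]
    sens[i] <- sum(pred & truth) / n1
    spec[i] <- sum(!pred & !truth) / n0
  }
  fpr <- 1 - spec   # first candidate gives (0,0), last gives (1,1)
  auc_trap <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)

  # Mann-Whitney estimate: P(score_pos < score_neg) + 0.5 P(tie)
  xp <- s[truth]; xn <- s[!truth]
  r <- rank(c(xp, xn))
  U_pos <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs where pos > neg
  auc_u <- 1 - U_pos / (n1 * n0)

  j <- sens + spec - 1
  best <- which.max(j)
  crit <- cand[best]
  if (positive_if == "above") crit <- -crit

  # tie-corrected normal approximation on U for AUC != 0.5
  N <- n1 + n0
  ties <- table(s)
  tie_term <- sum(ties^3 - ties)
  sigU <- sqrt(n1 * n0 / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  z <- if (sigU > 0) (U_pos - n1 * n0 / 2) / sigU else 0
  p <- 2 * stats::pnorm(-abs(z))

  thr_out <- if (positive_if == "above") -cand else cand
  structure(list(thresholds = thr_out, sensitivity = sens, specificity = spec,
                 auc = auc_u, auc_trapezoid = auc_trap,
                 associated_criterion = crit, youden_j = j[best],
                 p_value = p),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f, associated criterion = %g (J = %.3f), p = %.4f\n",
              x$auc, x$associated_criterion, x$youden_j, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' U from rank sums with midranks for ties. The two-sided p-value is exact
#' (full enumeration of arrangements) when `n1 + n2 <= 12` and there are no
#' ties; otherwise it uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (for sample `x`), `p_two_sided`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_two_sided    # 1/3
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_invalid("samples must be finite")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0

  if (n1 + n2 <= 12 && !has_ties) {
    # exact: enumerate all choose(N, n1) placements of x-ranks
    N <- n1 + n2
    combos <- utils::combn(N, n1)
    Us <- colSums(combos) - n1 * (n1 + 1) / 2
    stat <- min(U, n1 * n2 - U)
    p <- mean(pmin(Us, n1 * n2 - Us) <= stat + 1e-12)
    return(list(U = U, p_two_sided = min(1, p), method = "exact"))
  }
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  mu <- n1 * n2 / 2
  sigU <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  if (sigU == 0) return(list(U = U, p_two_sided = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sigU        # continuity correction
  if (U == mu) z <- 0
  list(U = U, p_two_sided = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks; two-sided p from the t approximation
#' with n - 2 degrees of freedom.
#'
#' @param x,y paired samples.
#' @return list with `rs`, `p_two_sided`, `n`.
#' @export
#' @examples
#' spearman(1:5, c(2, 1, 4, 3, 5))$rs    # 0.7
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("x and y must be paired with n >= 3")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1) return(list(rs = rs, p_two_sided = 0, n = n))
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  list(rs = rs, p_two_sided = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Cohen's d effect size from group summaries
#'
#' Pooled-SD standardized mean difference,
#' `d = (mean_b - mean_a) / sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2))`.
#' With equal group sizes this is the simple average-of-variances form. The
#' sign convention is second group minus first (call with the study group
#' first and the control group second to match the clinical table
#' convention).
#'
#' @param mean_a,sd_a,n_a first (study) group summary.
#' @param mean_b,sd_b,n_b second (control) group summary.
#' @return Cohen's d (scalar).
#' @export
#' @examples
#' cohens_d(91.9, 18.6, 20, 127.4, 19.4, 20)    # 1.87 -> prints as 1.9
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  n_a <- check_count(n_a, "n_a", min = 2L); n_b <- check_count(n_b, "n_b", min = 2L)
  if (sd_a < 0 || sd_b < 0) stop_invalid("SDs must be >= 0")
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (pooled == 0) {
    if (mean_a == mean_b) return(0)
    stop("pooled SD is zero with unequal means: d undefined")
  }
  (mean_b - mean_a) / pooled
}

#' Shock index
#'
#' `SI = HR / SBP`; values above 0.9 indicate a high probability of shock.
#'
#' @param hr heart rate, bpm.
#' @param sbp systolic blood pressure, mmHg (> 0).
#' @return list `si`, `flag` (`TRUE` when SI > 0.9); vectorized.
#' @export
#' @examples
#' shock_index(111, 93.5)     # SI 1.187, flagged
shock_index <- function(hr, sbp) {
  if (any(!is.finite(hr)) || any(!is.finite(sbp))) stop_invalid("hr/sbp must be finite")
  if (any(sbp <= 0)) stop_invalid("sbp must be > 0")
  si <- hr / sbp
  list(si = si, flag = si > 0.9)
}

#' Clinical shock screening rule
#'
#' Disjunctive screen on a cohort record: positive when any of
#' SBP < 95 mmHg, MAP < 65 mmHg, or lactate > 2 mmol/L holds; a missing
#' lactate simply cannot fire its criterion.
#'
#' @param record one cohort row (list or 1-row data.frame) with fields `SBP`,
#'   `MAP` and optionally `lactate`.
#' @return list `positive` (logical) and `criteria` (character vector of the
#'   criteria that fired).
#' @export
#' @examples
#' screen_shock(list(SBP = 91.9, MAP = 71.4, lactate = 1.0))
screen_shock <- function(record) {
  fired <- character(0)
  if (!is.null(record$SBP) && is.finite(record$SBP) && record$SBP < 95)
    fired <- c(fired, "SBP<95")
  if (!is.null(record$MAP) && is.finite(record$MAP) && record$MAP < 65)
    fired <- c(fired, "MAP<65")
  if (!is.null(record$lactate) && is.finite(record$lactate) && record$lactate > 2)
    fired <- c(fired, "lactate>2")
  list(positive = length(fired) > 0, criteria = fired)
}

#' Evaluate a classifier over a cohort table
#'
#' Runs [classify()] on the chosen metric column, cross-tabulates against the
#' group labels (study = shock-positive truth), and reports the confusion
#' matrix, diagnostics and ROC summary in one record.
#'
#' @param cohort a `cohort_table` (or data.frame with `group` and the metric
#'   column; `roi_diff`/`roi_ratio` map to `ROI_diff` / `ROI_diff/ROI2`).
#' @param config a [classifier_config()].
#' @return list with `config`, `cm` (`confusion_matrix`), `diagnostics`,
#'   `roc` (`roc_result`), and `report` (one-row data.frame matching the
#'   evaluation CSV schema).
#' @export
evaluate_cohort <- function(cohort, config = classifier_config()) {
  if (!is.data.frame(cohort)) stop_invalid("cohort must be a data.frame")
  vals <- switch(config$metric,
    roi_diff = cohort$ROI_diff,
    roi_ratio = cohort$ROI_diff / cohort$ROI2,
    MAP = cohort$MAP,
    SBP = cohort$SBP)
  if (is.null(vals)) stop_invalid("cohort lacks the metric column")
  truth <- cohort$group == "study"
  pred <- classify(vals, config)
  cm <- confusion(pred, truth)
  dg <- diagnostics(cm)
  rc <- roc(vals, truth, positive_if = config$positive_if)
  report <- data.frame(
    metric = config$metric, cutoff = config$cutoff,
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
    accuracy = dg$accuracy, recall = dg$recall, precision = dg$precision,
    f1 = dg$f1, auc = rc$auc, assoc_criterion = rc$associated_criterion,
    p_value = rc$p_value)
  list(config = config, cm = cm, diagnostics = dg, roc = rc, report = report)
}
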