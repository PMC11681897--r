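#' Reference two-group cohort parameters (shock vs control)
#'
#' Per-variable mean/SD pairs for a 20 + 20 clinical cohort of shock patients
#' (study group) and healthy controls, together with the physiologic
#' truncation bounds the generator applies. These are the package defaults
#' for [simulate_cohort()]. ROI1/ROI2 are fingernail / fingertip-skin mean
#' perfusion values in arbitrary units; lactate is only available for the
#' study group (controls are not drawn blood).
#'
#' @return data.frame with columns `variable`, `study_mean`, `study_sd`,
#'   `control_mean`, `control_sd`, `lower`, `upper`.
#' @export
cohort_reference_params <- function() {
  data.frame(
    variable     = c("age", "height", "weight", "MAP", "SBP", "DBP", "BT",
                     "HR", "RR", "SpO2", "lactate", "ROI1", "ROI2"),
    study_mean   = c(68.8, 160.5, 55.2, 71.4, 91.9, 61.3, 36.8,
                     112.9, 21.9, 94.6, 4.5, 33674.6, 24656.0),
    study_sd     = c(15.4, 8.5, 8.9, 18.5, 18.6, 19.1, 1.5,
                     24.4, 3.2, 6.9, 3.8, 15748.0, 11762.1),
    control_mean = c(41.7, 164.2, 66.9, 93.8, 127.4, 77.0, 36.2,
                     76.9, 18.7, 99.2, NA, 36319.7, 21681.6),
    control_sd   = c(12.0, 6.7, 13.3, 12.9, 19.4, 11.1, 0.1,
                     7.7, 0.9, 0.5, NA, 11362.2, 7396.1),
    lower        = c(18, 120, 30, 20, 20, 20, 30,
                     20, 4, 1e-6, 0, 1e-6, 1e-6),
    upper        = c(105, 210, 200, 300, 300, 250, 43,
                     250, 60, 100, 30, Inf, Inf),
    stringsAsFactors = FALSE)
}

# truncated-normal draw by rejection; degenerate sd = 0 returns the mean
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Simulate a two-group clinical cohort
#'
#' Draws each physiological variable from a truncated normal at physiologic
#' bounds (see [cohort_reference_params()]), independently per subject.
#' Derived quantities are recomputed per subject rather than drawn: the shock
#' index `SI = HR/SBP` and the shock statistic `ROI_diff = ROI1 - ROI2`.
#' Subjects whose drawn DBP exceeds SBP are redrawn pairwise so the record
#' invariant `SBP >= DBP` always holds.
#'
#' @param n_study,n_control group sizes (>= 1).
#' @param params parameter table in the [cohort_reference_params()] layout;
#'   set a variable's SDs to 0 for degenerate (all-equal) draws.
#' @param seed integer seed.
#' @return A `data.frame` of class `cohort_table` with columns `subject_id`,
#'   `group` (`"study"`/`"control"`), `SBP`, `DBP`, `MAP`, `HR`, `RR`,
#'   `SpO2`, `BT`, `SI`, `lactate`, `ROI1`, `ROI2`, `ROI_diff`, `age`,
#'   `height`, `weight`.
#' @export
#' @examples
#' co <- simulate_cohort(20, 20, seed = 42)
#' aggregate(SBP ~ group, co, mean)
simulate_cohort <- function(n_study, n_control,
                            params = cohort_reference_params(),
                            seed) {
  n_study <- check_count(n_study, "n_study")
  n_control <- check_count(n_control, "n_control")
  if (missing(seed)) stop_invalid("seed is required")
  seed <- check_count(seed, "seed", min = 0L)
  req <- c("variable", "study_mean", "study_sd", "control_mean", "control_sd",
           "lower", "upper")
  if (!all(req %in% names(params))) stop_invalid("params is missing columns")
  rownames(params) <- params$variable
  if (any(!is.na(params$study_sd) & params$study_sd < 0) ||
      any(!is.na(params$control_sd) & params$control_sd < 0))
    stop_invalid("all SDs must be >= 0")
  if (params["SBP", "study_mean"] < params["DBP", "study_mean"] ||
      params["SBP", "control_mean"] < params["DBP", "control_mean"])
    stop_invalid("inconsistent params: SBP mean below DBP mean")

  set.seed(seed)
  draw_group <- function(n, which) {
    mcol <- paste0(which, "_mean"); scol <- paste0(which, "_sd")
    d <- function(v) {
      p <- params[v, ]
      if (is.na(p[[mcol]])) return(rep(NA_real_, n))
      rtrunc_norm(n, p[[mcol]], p[[scol]], p$lower, p$upper)
    }
    g <- data.frame(
      SBP = d("SBP"), DBP = d("DBP"), MAP = d("MAP"), HR = d("HR"),
      RR = d("RR"), SpO2 = d("SpO2"), BT = d("BT"),
      lactate = d("lactate"), ROI1 = d("ROI1"), ROI2 = d("ROI2"),
      age = d("age"), height = d("height"), weight = d("weight"))
    bad <- which(g$DBP > g$SBP)
    while (length(bad)) {
      g$SBP[bad] <- rtrunc_norm(length(bad), params[["SBP", mcol]],
                                params[["SBP", scol]],
                                params["SBP", "lower"], params["SBP", "upper"])
      g$DBP[bad] <- rtrunc_norm(length(bad), params[["DBP", mcol]],
                                params[["DBP", scol]],
                                params["DBP", "lower"], params["DBP", "upper"])
      bad <- bad[g$DBP[bad] > g$SBP[bad]]
    }
    g$SI <- g$HR / g$SBP
    g$ROI_diff <- g$ROI1 - g$ROI2
    g
  }

  study <- draw_group(n_study, "study")
  control <- draw_group(n_control, "control")
  out <- rbind(cbind(group = "study", study),
               cbind(group = "control", control))
  out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out)
  cols <- c("subject_id", "group", "SBP", "DBP", "MAP", "HR", "RR", "SpO2",
            "BT", "SI", "lactate", "ROI1", "ROI2", "ROI_diff",
            "age", "height", "weight")
  out <- out[, cols]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate an RR-interval series
#'
#' Fixture generator for the HRV metrics: either i.i.d. Gaussian intervals
#' (truncated at a 200 ms physiologic floor) or a stationary AR(1) process
#' with marginal SD `sd_rr` and lag-1 autocorrelation `ar_coeff`.
#'
#' @param mean_rr,sd_rr target mean and SD of the intervals, ms.
#' @param n number of intervals (>= 2).
#' @param model `"iid_gaussian"` or `"ar1"`.
#' @param ar_coeff AR(1) coefficient, `|ar_coeff| < 1` (ignored for iid).
#' @param seed integer seed.
#' @return An object of class `rr_series`: numeric vector of intervals (ms)
#'   with attribute `t0 = 0`.
#' @export
#' @examples
#' rr <- simulate_rr_series(800, 50, 300, seed = 7)
#' sd(rr)
simulate_rr_series <- function(mean_rr, sd_rr, n,
                               model = c("iid_gaussian", "ar1"),
                               ar_coeff = 0.5, seed) {
  model <- match.arg(model)
  check_scalar_num(mean_rr, "mean_rr", positive = TRUE)
  check_scalar_num(sd_rr, "sd_rr")
  if (sd_rr < 0) stop_invalid("sd_rr must be >= 0")
  n <- check_count(n, "n", min = 2L)
  if (missing(seed)) stop_invalid("seed is required")
  seed <- check_count(seed, "seed", min = 0L)
  if (mean_rr <= 5 * sd_rr)
    warning("mean_rr <= 5 * sd_rr: the 200 ms floor truncation will distort moments")

  set.seed(seed)
  rr <- switch(model,
    iid_gaussian = rtrunc_norm(n, mean_rr, sd_rr, lower = 200),
    ar1 = {
      if (abs(ar_coeff) >= 1) stop_invalid("|ar_coeff| must be < 1")
      e_sd <- sd_rr * sqrt(1 - ar_coeff^2)
      x <- numeric(n)
      x[1] <- stats::rnorm(1, 0, sd_rr)
      for (i in 2:n) x[i] <- ar_coeff * x[i - 1] + stats::rnorm(1, 0, e_sd)
      pmax(mean_rr + x, 200)
    })
  structure(rr, t0 = 0, class = "rr_series")
}
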