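#' Simulate a clinical-shaped demonstration cohort
#'
#' A synthetic cohort shaped like a liver-metastases follow-up study:
#' yearly time scale, repeated tumor recurrences (up to four) that can be
#' interrupted by death, gamma-frailty heterogeneity, independent
#' censoring, and three binary baseline covariates (multiple tumors,
#' tumor larger than 2 cm, and a spare marker).  The covariates are pure
#' noise by design -- the generator does not link hazards to covariates --
#' so they exercise the model structure, not real effects.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @return A [simulate_cohort()]-style list with covariates attached to
#'   each history.
#' @export
demo_cohort <- function(n = 263L, seed = 1L) {
  scn <- scenario(n = n, frailty = "gamma", lambda01 = 0.45,
                  lambda02 = 0.6, lambda0D = 0.12, lambda_c = 0.1,
                  horizon = 3, max_events = 4L)
  cohort <- simulate_cohort(scn, seed = seed)
  multiple <- stats::rbinom(n, 1L, 0.4)
  large <- stats::rbinom(n, 1L, 0.5)
  for (i in seq_len(n)) {
    cohort$histories[[i]]$covariates <-
      list(multiple_tumors = multiple[i], tumor_gt2cm = large[i])
  }
  cohort$scenario <- scn
  cohort
}

#' End-to-end demonstration supermodel
#'
#' Runs the full pipeline on [demo_cohort()]: yearly landmark grid, 3-year
#' prediction window, categories no recurrence / one recurrence / multiple
#' recurrences / death, Aalen-Johansen pseudo-observations, and a cubic
#' supermodel over three binary covariates (prior recurrence at the
#' landmark, multiple tumors, tumor > 2 cm) with sandwich covariances.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param landmarks landmark grid (years).
#' @param window prediction window (years).
#' @param estimator `"aj"` or `"km"` (KM drops the death category and
#'   treats death as censoring).
#' @param degree polynomial smoother degree.
#' @return A list: `fit` (the `landmark_gee`), `coefficients`
#'   ([coef_table()] output), `predictions` (stacked
#'   [predict_probabilities()] over the grid for a reference profile),
#'   `cohort`, `landmark_data`.
#' @export
demo_supermodel <- function(n = 263L, seed = 1L, landmarks = 0:5,
                            window = 3, estimator = c("aj", "km"),
                            degree = 3L) {
  estimator <- match.arg(estimator)
  cohort <- demo_cohort(n = n, seed = seed)
  terminal <- if (estimator == "aj") "present" else "absent"
  ld <- build_landmark_dataset(cohort$histories, landmarks = landmarks,
                               window = window, k_max = 2L,
                               terminal = terminal)
  dpos <- compute_dpos(ld, estimator = estimator)
  covs <- as.data.frame(ld)
  covs$prior_recurrence <- as.integer(covs$prior_events >= 1L)
  fit <- fit_landmark_supermodel(
    dpos, data = covs,
    formula = ~ prior_recurrence + multiple_tumors + tumor_gt2cm,
    degree = degree
  )
  profile <- data.frame(prior_recurrence = 0L, multiple_tumors = 0L,
                        tumor_gt2cm = 0L)
  preds <- predict_probabilities(fit, newdata = profile,
                                 s = seq(min(landmarks), max(landmarks),
                                         by = 0.25))
  list(fit = fit, coefficients = coef_table(fit), predictions = preds,
       cohort = cohort, landmark_data = ld)
}
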