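#' Kendall's rank correlation (tau-a) by inversion counting
#'
#' Counts discordant pairs as inversions of `y` after sorting by `x`, using
#' bottom-up merging with vectorized cross-counts, so large samples
#' (n = 1e5) are handled in O(n log n) comparisons.  Intended for
#' continuous draws where ties have probability zero; ties, if present,
#' are broken by order and tau-a is returned.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return Kendall's tau in `[-1, 1]`.
#' @examples
#' kendall_tau(1:10, (1:10)^2)    # 1
#' kendall_tau(c(1, 2, 3), c(1, 3, 2))  # 1/3
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  yy <- y[order(x, y)]
  inv <- count_inversions(yy)
  npairs <- as.numeric(n) * (n - 1) / 2
  (npairs - 2 * inv) / npairs
}

# Number of pairs i < j with v[i] > v[j].  Leaf blocks are counted by a
# vectorized all-pairs comparison; sorted blocks are then merged upward,
# counting cross-block inversions with findInterval.
count_inversions <- function(v, leaf = 64L) {
  n <- length(v)
  inv <- 0
  starts <- seq(1L, n, by = leaf)
  for (a in starts) {
    b <- min(a + leaf - 1L, n)
    blk <- v[a:b]
    if (length(blk) > 1L) {
      cmp <- outer(blk, blk, `>`)
      inv <- inv + sum(cmp[upper.tri(cmp)])
      v[a:b] <- sort(blk)
    }
  }
  width <- leaf
  while (width < n) {
    a <- 1L
    while (a + width <= n) {
      mid <- a + width - 1L
      b <- min(a + 2L * width - 1L, n)
      left <- v[a:mid]
      right <- v[(mid + 1L):b]
      inv <- inv + as.numeric(length(left)) * length(right) -
        sum(as.numeric(findInterval(right, left)))
      v[a:b] <- sort(c(left, right))
      a <- b + 1L
    }
    width <- 2L * width
  }
  inv
}

# Candidate censored-proportion summaries for a replication: the tables'
# exact definition is not fixed, so several are reported.
censoring_summaries <- function(latent, horizon) {
  tcols <- grep("^t[0-9]+$", names(latent), value = TRUE)
  t_last <- latent[[tcols[length(tcols)]]]
  c(
    censor_before_horizon = mean(latent$c <= horizon),
    censor_before_events = mean(latent$c < pmin(t_last, horizon)),
    censor_observed_endpoint =
      mean(latent$c < latent$tD & latent$c <= horizon)
  )
}

#' Monte Carlo evaluation of dynamic predicted values against truth
#'
#' Replicates the evaluation design: per replication, simulate a cohort,
#' compute the dynamic predicted value of each category at landmark
#' `s = 0` with window `w = horizon`, take the same replication's
#' empirical latent-time proportions as the true values, and aggregate
#' the per-category bias (mean of predicted minus true) and RMSE across
#' replications.  Both estimators are evaluated on identical cohorts
#' (paired), isolating estimator differences.
#'
#' The dynamic predicted value is, by default, the full-sample
#' nonparametric estimate (`predicted = "plugin"`).  The expectation of
#' the pseudo-observations coincides with it exactly on the KM route
#' (away from degenerate support) and in the uncensored or two-state AJ
#' cases, but under heavy censoring the jackknifed multi-state AJ mean is
#' a strictly noisier version of the same quantity;
#' `predicted = "dpo_mean"` selects it explicitly.
#'
#' @param scn a [scenario()].
#' @param n_reps number of replications (`>= 2`).
#' @param estimators subset of `c("aj", "km")`; KM requires a scenario
#'   without terminal events.
#' @param k_max top pooled category for estimation and truth.
#' @param seed integer seed for the whole run.
#' @param summaries if `TRUE`, also average the per-replication true
#'   proportions, candidate censored-proportion definitions and latent
#'   Kendall's tau estimates.
#' @param predicted `"plugin"` (full-sample estimate) or `"dpo_mean"`
#'   (column mean of the jackknife pseudo-observations).
#' @return An object of class `simulation_report`.
#' @export
run_scenario <- function(scn, n_reps = 1000L, estimators = c("aj", "km"),
                         k_max = 2L, seed = NULL, summaries = TRUE,
                         predicted = c("plugin", "dpo_mean")) {
  predicted <- match.arg(predicted)
  stopifnot(inherits(scn, "scenario"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  estimators <- match.arg(estimators, c("aj", "km"), several.ok = TRUE)
  terminal <- if (scn$lambda0D > 0) "present" else "absent"
  if (terminal == "present" && "km" %in% estimators) {
    stop("the KM route has no terminal state; use estimators = \"aj\" ",
         "for scenarios with lambda0D > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  labs <- category_labels(k_max, terminal)
  ncat <- length(labs)
  pred <- lapply(estimators, function(e) matrix(NA_real_, n_reps, ncat))
  names(pred) <- estimators
  truth <- matrix(NA_real_, n_reps, ncat)
  cens <- matrix(NA_real_, n_reps, 3L)
  taus <- matrix(NA_real_, n_reps, 3L)
  warn_count <- 0L
  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(scn)
    ld <- build_landmark_dataset(cohort$histories, landmarks = 0,
                                 window = scn$horizon, k_max = k_max,
                                 terminal = terminal)
    rs <- ld$risksets[[1L]]
    for (e in estimators) {
      pred[[e]][r, ] <- withCallingHandlers(
        if (predicted == "plugin") {
          if (e == "aj") aj_state_occupation(rs)
          else ordered_event_probabilities(rs)
        } else {
          colMeans((if (e == "aj") dpo_aj(rs) else dpo_km(rs))$theta)
        },
        warning = function(w) {
          warn_count <<- warn_count + 1L
          invokeRestart("muffleWarning")
        })
    }
    truth[r, ] <- true_category_probabilities(cohort$latent, scn$horizon,
                                              k_max, terminal)
    if (summaries) {
      cens[r, ] <- censoring_summaries(cohort$latent, scn$horizon)
      lt <- cohort$latent
      taus[r, 1L] <- kendall_tau(lt$t1, lt$t2 - lt$t1)
      if (terminal == "present") {
        taus[r, 2L] <- kendall_tau(lt$t1, lt$tD)
        taus[r, 3L] <- kendall_tau(lt$t2 - lt$t1, lt$tD)
      }
    }
  }
  per_est <- lapply(estimators, function(e) {
    err <- pred[[e]] - truth
    bias <- colMeans(err)
    rmse <- sqrt(colMeans(err^2))
    # MC standard errors: of the mean for bias; delta method for RMSE
    mc_se_bias <- apply(err, 2L, stats::sd) / sqrt(n_reps)
    mc_se_rmse <- apply(err^2, 2L, stats::sd) /
      (2 * pmax(rmse, .Machine$double.eps) * sqrt(n_reps))
    list(bias = stats::setNames(bias, labs),
         rmse = stats::setNames(rmse, labs),
         mc_se_bias = stats::setNames(mc_se_bias, labs),
         mc_se_rmse = stats::setNames(mc_se_rmse, labs))
  })
  names(per_est) <- estimators
  structure(
    list(scenario = scn, n_reps = n_reps, k_max = k_max,
         terminal = terminal, predicted = predicted, estimators = per_est,
         mean_true = stats::setNames(colMeans(truth), labs),
         censored_proportions = if (summaries) {
           stats::setNames(colMeans(cens),
                           c("censor_before_horizon",
                             "censor_before_events",
                             "censor_observed_endpoint"))
         },
         kendall_tau = if (summaries) {
           stats::setNames(colMeans(taus, na.rm = TRUE),
                           c("t1_gap", "t1_tD", "gap_tD"))
         },
         km_warnings = warn_count),
    class = "simulation_report"
  )
}

#' @export
print.simulation_report <- function(x, digits = 4, ...) {
  cat("<simulation_report> ", x$n_reps, " replications, n = ",
      x$scenario$n, ", terminal ", x$terminal, "\n", sep = "")
  cat("  mean true proportions: ",
      paste(names(x$mean_true),
            format(round(x$mean_true, digits), nsmall = digits),
            sep = "=", collapse = "  "), "\n", sep = "")
  for (e in names(x$estimators)) {
    est <- x$estimators[[e]]
    cat("  [", e, "] bias: ",
        paste(format(round(est$bias, digits), nsmall = digits),
              collapse = "  "), "\n", sep = "")
    cat("  [", e, "] rmse: ",
        paste(format(round(est$rmse, digits), nsmall = digits),
              collapse = "  "), "\n", sep = "")
  }
  if (!is.null(x$kendall_tau) && !all(is.na(x$kendall_tau))) {
    cat("  mean Kendall tau (t1, t2-t1): ",
        format(round(x$kendall_tau[["t1_gap"]], 3)), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy export of a simulation report
#'
#' @param x a `simulation_report`.
#' @param ... unused.
#' @return A data.frame with one row per (estimator, category) carrying
#'   bias, RMSE and their Monte Carlo standard errors.
#' @export
as.data.frame.simulation_report <- function(x, ...) {
  rows <- lapply(names(x$estimators), function(e) {
    est <- x$estimators[[e]]
    data.frame(
      estimator = e, category = names(est$bias),
      true_proportion = unname(x$mean_true),
      bias = unname(est$bias), rmse = unname(est$rmse),
      mc_se_bias = unname(est$mc_se_bias),
      mc_se_rmse = unname(est$mc_se_rmse),
      n_reps = x$n_reps, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-category RMSE ratio of the AJ route to the KM route
#'
#' Elementwise `RMSE(AJ) / RMSE(KM)` from a paired report (both estimators
#' evaluated on identical replications).  A 0/0 ratio is reported as 1;
#' a zero KM RMSE with nonzero AJ RMSE is an error.
#'
#' @param report a `simulation_report` containing both estimators, or the
#'   AJ report when `km_report` is supplied separately (it must come from
#'   identical seeds).
#' @param km_report optional separate KM report.
#' @return A data.frame `category, rmse_aj, rmse_km, ratio`.
#' @export
rmse_ratio_table <- function(report, km_report = NULL) {
  stopifnot(inherits(report, "simulation_report"))
  if (is.null(km_report)) {
    if (!all(c("aj", "km") %in% names(report$estimators))) {
      stop("report must contain both estimators (or pass km_report)",
           call. = FALSE)
    }
    aj <- report$estimators$aj$rmse
    km <- report$estimators$km$rmse
  } else {
    stopifnot(inherits(km_report, "simulation_report"),
              report$n_reps == km_report$n_reps)
    aj <- report$estimators$aj$rmse
    km <- km_report$estimators$km$rmse
  }
  ratio <- numeric(length(aj))
  for (k in seq_along(aj)) {
    if (km[k] < 1e-12) {
      # both estimators are exact (uncensored data): 0/0 reported as 1
      if (aj[k] < 1e-12) ratio[k] <- 1
      else stop("KM RMSE is zero but AJ RMSE is not for category ",
                names(aj)[k], call. = FALSE)
    } else {
      ratio[k] <- aj[k] / km[k]
    }
  }
  data.frame(category = names(aj), rmse_aj = unname(aj),
             rmse_km = unname(km), ratio = ratio,
             stringsAsFactors = FALSE)
}
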