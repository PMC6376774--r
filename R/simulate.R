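#' Define a frailty-exponential simulation scenario
#'
#' The generator draws, per subject, a frailty `u` (constant 1, or gamma
#' with shape and rate 0.5 so that `E(u) = 1` and `var(u) = 2`), then
#' latent first-event time `t1 ~ Exp(u * lambda01)`, i.i.d. gaps between
#' subsequent events `~ Exp(u * lambda02)` (events capped at `max_events`),
#' a latent terminal time `tD ~ Exp(u * lambda0D)` (disabled when
#' `lambda0D = 0`) and an independent censoring time `c ~ Exp(lambda_c)`
#' (no censoring when `lambda_c = 0`).  The shared frailty induces all
#' pairwise dependence among a subject's times; for gamma(0.5, 0.5) frailty
#' the Kendall's tau of any pair is `var(u) / (var(u) + 2) = 0.5`.
#'
#' Defaults are the baseline evaluation conditions: n = 100 subjects, no
#' frailty heterogeneity, unit event hazards, no terminal event, censoring
#' hazard 0.5, horizon 1, at most two repeated events.
#'
#' @param n number of subjects (`>= 2`).
#' @param frailty `"none"` (u = 1) or `"gamma"`.
#' @param frailty_shape,frailty_rate gamma frailty parameters.
#' @param lambda01 baseline hazard of the first event.
#' @param lambda02 baseline hazard of the gaps between later events.
#' @param lambda0D baseline hazard of the terminal event (0 disables it).
#' @param lambda_c censoring hazard (0 disables censoring).
#' @param horizon evaluation time for "true" category probabilities.
#' @param max_events cap on the number of repeated events per subject
#'   (`>= 2`).
#' @return An object of class `scenario`.
#' @export
scenario <- function(n = 100L, frailty = c("none", "gamma"),
                     frailty_shape = 0.5, frailty_rate = 0.5,
                     lambda01 = 1, lambda02 = 1, lambda0D = 0,
                     lambda_c = 0.5, horizon = 1, max_events = 2L) {
  frailty <- match.arg(frailty)
  n <- as.integer(n)
  max_events <- as.integer(max_events)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (max_events < 2L) stop("max_events must be >= 2", call. = FALSE)
  haz <- c(lambda01 = lambda01, lambda02 = lambda02, lambda0D = lambda0D,
           lambda_c = lambda_c)
  if (any(haz < 0) || anyNA(haz)) {
    stop("hazards must be nonnegative", call. = FALSE)
  }
  if (lambda01 <= 0 || lambda02 <= 0) {
    stop("event hazards must be positive", call. = FALSE)
  }
  if (frailty == "gamma" && (frailty_shape <= 0 || frailty_rate <= 0)) {
    stop("gamma frailty parameters must be positive", call. = FALSE)
  }
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  structure(
    list(n = n, frailty = frailty, frailty_shape = frailty_shape,
         frailty_rate = frailty_rate, lambda01 = lambda01,
         lambda02 = lambda02, lambda0D = lambda0D, lambda_c = lambda_c,
         horizon = horizon, max_events = max_events),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> n =", x$n, "; frailty",
      if (x$frailty == "none") "none (u = 1)"
      else paste0("gamma(", x$frailty_shape, ", ", x$frailty_rate, ")"),
      "\n  lambda01 =", x$lambda01, ", lambda02 =", x$lambda02,
      ", lambda0D =", x$lambda0D, ", lambda_c =", x$lambda_c,
      "\n  horizon =", x$horizon, ", max_events =", x$max_events, "\n")
  invisible(x)
}

#' Simulate a cohort of recurrent/terminal event histories
#'
#' Draws latent potential times per subject according to the scenario and
#' derives the observed histories: recurrent events before
#' `min(tD, c)` are observed; the endpoint is the earlier of the terminal
#' and censoring times (a subject with neither is followed indefinitely,
#' `censor = Inf`).
#'
#' @param scn a [scenario()].
#' @param seed optional integer seed; identical scenario and seed give an
#'   identical cohort.
#' @return A list with `histories` (list of [event_history]) and `latent`
#'   (data.frame of the latent quadruple: `id`, `u`, event time columns
#'   `t1..t<max_events>`, `tD`, `c`).
#' @export
simulate_cohort <- function(scn, seed = NULL) {
  stopifnot(inherits(scn, "scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scn$n
  u <- if (scn$frailty == "gamma") {
    stats::rgamma(n, shape = scn$frailty_shape, rate = scn$frailty_rate)
  } else {
    rep(1, n)
  }
  t1 <- stats::rexp(n, rate = u * scn$lambda01)
  gaps <- matrix(stats::rexp(n * (scn$max_events - 1L),
                             rate = u * scn$lambda02),
                 nrow = n)
  tmat <- if (scn$max_events == 2L) {
    cbind(t1, t1 + gaps[, 1L])
  } else {
    cbind(t1, t1 + t(apply(gaps, 1L, cumsum)))
  }
  colnames(tmat) <- paste0("t", seq_len(scn$max_events))
  tD <- if (scn$lambda0D > 0) stats::rexp(n, rate = u * scn$lambda0D)
        else rep(Inf, n)
  cc <- if (scn$lambda_c > 0) stats::rexp(n, rate = scn$lambda_c)
        else rep(Inf, n)
  ids <- sprintf("s%03d", seq_len(n))
  latent <- data.frame(id = ids, u = u, tmat, tD = tD, c = cc,
                       stringsAsFactors = FALSE)
  histories <- lapply(seq_len(n), function(i) {
    end <- min(tD[i], cc[i])
    ev <- tmat[i, ]
    event_history(
      id = ids[i],
      recurrent = ev[ev < end],
      terminal = if (tD[i] <= cc[i]) tD[i] else Inf,
      censor = if (cc[i] < tD[i]) cc[i] else Inf
    )
  })
  names(histories) <- ids
  list(histories = histories, latent = latent)
}

#' True windowed category probabilities from latent times
#'
#' Empirical category proportions at the horizon computed from the latent
#' (uncensored) potential times, ignoring censoring: with a terminal state,
#' a subject with `tD <= horizon` is in category `"D"`, otherwise in the
#' event-count category `min(#{t_j <= horizon}, k_max)`; without, event
#' counts only.  These per-replication empirical proportions are the
#' "true values" against which dynamic predicted values are compared.
#'
#' @param latent latent-times data.frame from [simulate_cohort()].
#' @param horizon window end (events counted in `(0, horizon]`).
#' @param k_max top pooled category.
#' @param terminal `"absent"` or `"present"`.
#' @return Named probability vector over the categories, summing to 1.
#' @export
true_category_probabilities <- function(latent, horizon, k_max = 2L,
                                        terminal = c("absent", "present")) {
  terminal <- match.arg(terminal)
  tcols <- grep("^t[0-9]+$", names(latent), value = TRUE)
  tm <- as.matrix(latent[tcols])
  counts <- pmin(rowSums(tm <= horizon), k_max)
  labs <- category_labels(k_max, terminal)
  if (terminal == "present") {
    dead <- latent$tD <= horizon
    cat_idx <- ifelse(dead, k_max + 2L, counts + 1L)
  } else {
    cat_idx <- counts + 1L
  }
  p <- tabulate(cat_idx, nbins = length(labs)) / nrow(latent)
  names(p) <- labs
  p
}

#' Write a simulated cohort to delimited text
#'
#' Writes the events file (and covariates file when present) of
#' [write_event_histories()] plus the latent-truth file
#' (`id, u, t1..t<max_events>, tD, c`).
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  events_path <- file.path(dir, paste0(prefix, "_events.csv"))
  latent_path <- file.path(dir, paste0(prefix, "_latent.csv"))
  has_cov <- any(vapply(cohort$histories,
                        function(h) length(h$covariates) > 0, TRUE))
  cov_path <- if (has_cov) file.path(dir, paste0(prefix, "_covariates.csv"))
  write_event_histories(cohort$histories, events_path, cov_path)
  utils::write.table(cohort$latent, latent_path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(c(events_path, latent_path, cov_path))
}
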