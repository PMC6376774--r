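# Shared fixtures and independent oracles (survival::survfit) used across
# the test files.  All fixtures are generated in code.

# Build the single riskset at landmark s from a list of histories.
make_riskset <- function(histories, s = 0, window = 1, k_max = 2L,
                         terminal = "absent") {
  build_landmark_dataset(histories, s, window = window, k_max = k_max,
                         terminal = terminal)$risksets[[1L]]
}

# Simulate a cohort and return its riskset at s = 0 (terminal mode inferred
# from the scenario unless overridden).
random_riskset <- function(n = 30, lambda_c = 0.7, lambda0D = 0,
                           frailty = "none", k_max = 2L, window = 1,
                           terminal = NULL, lambda02 = 1, seed = NULL) {
  scn <- scenario(n = n, frailty = frailty, lambda02 = lambda02,
                  lambda0D = lambda0D, lambda_c = lambda_c)
  co <- simulate_cohort(scn, seed = seed)
  if (is.null(terminal)) terminal <- if (lambda0D > 0) "present" else "absent"
  make_riskset(co$histories, window = window, k_max = k_max,
               terminal = terminal)
}

# Kaplan-Meier oracle via survival::survfit.
oracle_km_survival <- function(time, status, eval_time) {
  f <- survival::survfit(survival::Surv(time, status) ~ 1)
  sm <- summary(f, times = eval_time, extend = TRUE)
  sm$surv
}

# Multi-state Aalen-Johansen state-occupation oracle via survfit on
# counting-process data; states 0..k_max (+ D).
oracle_aj_occupation <- function(rs) {
  n <- length(rs$id)
  K <- rs$k_max
  rows <- list()
  for (i in seq_len(n)) {
    ev <- rs$post_times[[i]]
    ki <- min(length(ev), K)
    ent <- c(0, if (ki) ev[seq_len(ki)])
    ext <- c(if (ki) ev[seq_len(ki)], rs$end_time[i])
    to <- c(if (ki) as.character(seq_len(ki)),
            if (rs$terminal == "present" && rs$end_type[i] == "terminal" &&
                is.finite(rs$end_time[i])) "D" else "cens")
    for (q in seq_along(ent)) {
      rows[[length(rows) + 1L]] <-
        data.frame(id = rs$id[i], tstart = ent[q], tstop = ext[q],
                   to = to[q], istate = as.character(q - 1L),
                   stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  states <- c(as.character(0:K), if (rs$terminal == "present") "D")
  df$to <- factor(df$to, levels = c("cens", states))
  df$istate <- factor(df$istate, levels = states)
  f <- survival::survfit(
    survival::Surv(tstart, tstop, to) ~ 1, data = df, id = id,
    istate = istate)
  sm <- summary(f, times = rs$window, extend = TRUE)
  p <- as.vector(sm$pstate)
  names(p) <- sm$states
  unname(p[states])
}

# Brute-force leave-one-out pseudo-observations computed entirely through
# the survfit oracle (delete each subject, re-run the product-integral from
# scratch).
oracle_dpo_aj <- function(rs) {
  n <- length(rs$id)
  full <- oracle_aj_occupation(rs)
  t(vapply(seq_len(n), function(i) {
    loo <- oracle_aj_occupation(dynpseudo:::riskset_drop(rs, i))
    n * full - (n - 1) * loo
  }, numeric(length(full))))
}

# Hand-built histories used by several data-model tests.
fixture_histories <- function() {
  list(
    event_history("A", recurrent = 0.5, censor = 1.2),
    event_history("B", terminal = 2.0),
    event_history("C", recurrent = c(0.3, 0.7), censor = 5),
    event_history("D", terminal = 0.4)
  )
}
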