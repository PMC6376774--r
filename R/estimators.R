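#' Kaplan-Meier survival probability at a time point
#'
#' Product-limit estimate of `S(eval_time)` from right-censored durations.
#' Ties between events and censorings at the same time are handled by the
#' usual convention: risk sets are taken just before each event time, so
#' subjects censored at an event time still count as at risk there.  When
#' `eval_time` lies beyond the largest observed time the last value is
#' carried forward with a warning.
#'
#' @param time nonnegative durations (may include `Inf` for never-ending
#'   follow-up).
#' @param status 1/TRUE = event, 0/FALSE = censored.
#' @param eval_time time at which to evaluate the survival function.
#' @return The estimated survival probability, a single number in `[0, 1]`.
#' @examples
#' km_survival(c(1, 2, 3), c(1, 1, 1), 2.5)    # 1/3
#' km_survival(c(1, 2, 3), c(0, 1, 1), 2.5)    # 0.5
#' @export
km_survival <- function(time, status, eval_time) {
  if (length(time) == 0L) stop("empty duration vector", call. = FALSE)
  if (length(time) != length(status)) {
    stop("time and status lengths differ", call. = FALSE)
  }
  status <- as.integer(as.logical(status))
  if (anyNA(time) || any(time < 0)) {
    stop("durations must be nonnegative and non-missing", call. = FALSE)
  }
  if (is.finite(eval_time) && eval_time > max(time)) {
    warning("eval_time ", eval_time, " beyond last observed time ",
            max(time), "; carrying last value forward", call. = FALSE)
  }
  ev <- time[status == 1L & time <= eval_time]
  if (!length(ev)) return(1)
  st <- sort(time)
  dt <- sort(unique(ev))
  d <- tabulate(match(ev, dt), nbins = length(dt))
  # Y(t-) = number with duration >= t (includes same-time censorings)
  Y <- length(time) - findInterval(dt, st, left.open = TRUE)
  prod(1 - d / Y)
}

#' Full product-limit curve as a tidy table
#'
#' Step-function representation of the Kaplan-Meier estimator with one row
#' per distinct event time, suitable for writing to delimited text.
#'
#' @inheritParams km_survival
#' @return A data.frame `time, estimate, n_risk, n_event`.
#' @export
km_curve <- function(time, status) {
  status <- as.integer(as.logical(status))
  ev <- time[status == 1L]
  dt <- sort(unique(ev))
  st <- sort(time)
  if (!length(dt)) {
    return(data.frame(time = numeric(), estimate = numeric(),
                      n_risk = integer(), n_event = integer()))
  }
  d <- tabulate(match(ev, dt), nbins = length(dt))
  Y <- length(time) - findInterval(dt, st, left.open = TRUE)
  data.frame(time = dt, estimate = cumprod(1 - d / Y),
             n_risk = Y, n_event = d)
}

# Durations and statuses for the k-th post-landmark event times T*_k,
# k = 1..k_max, within a riskset: subjects with fewer than k observed
# post-landmark events are censored at their (relative) end time; a
# terminal endpoint is treated as censoring here (the ordered-event
# construction has no death state).  Row i depends on subject i only, so
# leave-one-out estimation drops rows.
ordered_duration_matrix <- function(rs) {
  n <- length(rs$id)
  k_max <- rs$k_max
  nev <- lengths(rs$post_times)
  Tm <- matrix(rs$end_time, n, k_max)
  Sm <- matrix(0L, n, k_max)
  for (k in seq_len(k_max)) {
    has <- which(nev >= k)
    Tm[has, k] <- vapply(has, function(i) rs$post_times[[i]][k], 0)
    Sm[has, k] <- 1L
  }
  list(time = Tm, status = Sm)
}

# F vector from the ordered-event KM curves, optionally leaving out one
# subject (row) of the precomputed duration matrices.
ordered_probs_impl <- function(dm, w, k_max, labs, drop = 0L) {
  rows <- if (drop > 0L) -drop else TRUE
  S <- vapply(seq_len(k_max), function(k) {
    km_survival(dm$time[rows, k], dm$status[rows, k], w)
  }, 0)
  F <- c(S[1L], if (k_max > 1L) diff(S), 1 - S[k_max])
  names(F) <- labs
  F
}

#' Windowed event-count probabilities from ordered-event Kaplan-Meier curves
#'
#' Estimates the probability of exactly `k` recurrent events in
#' `(s, s + w]` for an at-risk subject via survival differences of the
#' ordered event times: `F_0 = S*_1(w)`, `F_k = S*_{k+1}(w) - S*_k(w)` and
#' `F_kmax = 1 - S*_kmax(w)`, where `S*_k` is the Kaplan-Meier curve of the
#' k-th post-landmark event time (durations measured from the landmark;
#' subjects without event `k` are censored at their end of observation, and
#' a terminal endpoint is treated as censoring).
#'
#' Under heavy censoring the estimated curves can cross, producing slightly
#' negative interior probabilities; these are returned as computed (with a
#' warning), because the downstream pseudo-observations tolerate
#' out-of-range values and clipping would bias the regression.
#'
#' @param rs a `landmark_riskset` (one element of
#'   [build_landmark_dataset()]'s output).
#' @return Named probability vector over the event-count categories.
#' @export
ordered_event_probabilities <- function(rs) {
  stopifnot(inherits(rs, "landmark_riskset"))
  F <- ordered_probs_impl(ordered_duration_matrix(rs), rs$window, rs$k_max,
                          category_labels(rs$k_max, "absent"))
  if (any(F < 0)) {
    warning("KM-difference estimate produced negative category ",
            "probability (crossing curves); values not clipped",
            call. = FALSE)
  }
  F
}

# Flat per-subject transition / state-sojourn representation of a riskset
# for the progressive chain 0 -> 1 -> ... -> k_max (k_max absorbing for
# event counting), optionally with an absorbing death state D reachable
# from every transient state.  Each subject's rows depend on that subject
# only, so the leave-one-out estimates below are honest re-estimations on
# the reduced data.
aj_structure <- function(rs) {
  k_max <- rs$k_max
  with_d <- rs$terminal == "present"
  n_states <- k_max + 1L + with_d
  n <- length(rs$id)
  nev <- pmin(lengths(rs$post_times), k_max)
  ev <- lapply(seq_len(n), function(i) rs$post_times[[i]][seq_len(nev[i])])

  tr_time <- unlist(ev, use.names = FALSE)
  tr_subj <- rep(seq_len(n), nev)
  tr_from <- unlist(lapply(nev, function(k) seq_len(k) - 1L),
                    use.names = FALSE)
  tr_to <- tr_from + 1L
  if (is.null(tr_time)) tr_time <- numeric(0)
  if (is.null(tr_from)) tr_from <- tr_to <- integer(0)
  if (with_d) {
    dead <- which(rs$end_type == "terminal" & is.finite(rs$end_time))
    tr_time <- c(tr_time, rs$end_time[dead])
    tr_subj <- c(tr_subj, dead)
    tr_from <- c(tr_from, nev[dead])
    tr_to <- c(tr_to, rep(n_states - 1L, length(dead)))
  }
  ord <- order(tr_time)
  tr_time <- tr_time[ord]
  tr_subj <- tr_subj[ord]
  tr_from <- tr_from[ord]
  tr_to <- tr_to[ord]

  # sojourn in state q on [entry, exit); exit at next transition or end;
  # entry and exit times stored sorted per state (with aligned subject
  # tags) so leave-one-out subsets stay sorted
  so_subj <- rep(seq_len(n), nev + 1L)
  so_state <- unlist(lapply(nev, function(k) 0:k), use.names = FALSE)
  so_entry <- unlist(lapply(seq_len(n), function(i) c(0, ev[[i]])),
                     use.names = FALSE)
  so_exit <- unlist(lapply(seq_len(n), function(i) {
    c(ev[[i]], rs$end_time[i])
  }), use.names = FALSE)
  entries <- exits <- vector("list", n_states)
  for (q in seq_len(n_states) - 1L) {
    sel <- which(so_state == q)
    oe <- sel[order(so_entry[sel])]
    ox <- sel[order(so_exit[sel])]
    entries[[q + 1L]] <- list(t = so_entry[oe], subj = so_subj[oe])
    exits[[q + 1L]] <- list(t = so_exit[ox], subj = so_subj[ox])
  }

  list(n = n, n_states = n_states,
       labs = category_labels(k_max, rs$terminal),
       tr_time = tr_time, tr_subj = tr_subj, tr_from = tr_from,
       tr_to = tr_to, entries = entries, exits = exits)
}

# State-occupation row (all mass in state 0 at the landmark) at eval_time,
# by product-integration of the empirical transition hazard increments.
# `drop` excludes one subject (leave-one-out); `want_path` additionally
# returns the full cumulative transition matrices at every jump time.
aj_occupation_impl <- function(st, eval_time, drop = 0L,
                               want_path = FALSE) {
  n_states <- st$n_states
  keep <- st$tr_time <= eval_time & st$tr_time > 0
  if (drop > 0L) keep <- keep & st$tr_subj != drop
  tt <- st$tr_time[keep]   # already sorted
  tf <- st$tr_from[keep]
  tto <- st$tr_to[keep]
  p <- c(1, rep(0, n_states - 1L))
  names(p) <- st$labs
  if (!length(tt)) {
    if (want_path) {
      P0 <- diag(n_states)
      dimnames(P0) <- list(st$labs, st$labs)
      attr(p, "path") <- list(jump_times = numeric(0), matrices = list(),
                              P = P0)
    }
    return(p)
  }

  # Y_q(u-) = #{entry_q < u} - #{exit_q < u} per transition, from the
  # presorted per-state sojourn times with the dropped subject filtered out
  m <- length(tt)
  Yval <- integer(m)
  for (q in unique(tf)) {
    rows <- which(tf == q)
    ent <- st$entries[[q + 1L]]
    ext <- st$exits[[q + 1L]]
    et <- ent$t; xt <- ext$t
    if (drop > 0L) {
      et <- et[ent$subj != drop]
      xt <- xt[ext$subj != drop]
    }
    Yval[rows] <- findInterval(tt[rows], et, left.open = TRUE) -
      findInterval(tt[rows], xt, left.open = TRUE)
  }
  if (any(Yval <= 0L)) {
    stop("internal error: transition from an empty state")
  }

  tie <- anyDuplicated(tt) > 0L
  if (!tie && !want_path) {
    # generic continuous-time case: one transition per jump time
    for (r in seq_len(m)) {
      q <- tf[r] + 1L
      delta <- p[q] / Yval[r]
      p[q] <- p[q] - delta
      p[tto[r] + 1L] <- p[tto[r] + 1L] + delta
    }
    return(p)
  }

  new_grp <- c(TRUE, tt[-1L] != tt[-m])
  gid <- cumsum(new_grp)
  us <- tt[new_grp]
  if (want_path) {
    P <- diag(n_states)
    dimnames(P) <- list(st$labs, st$labs)
    mats <- vector("list", length(us))
  }
  pos <- 1L
  for (j in seq_along(us)) {
    idx <- pos
    while (pos < m && gid[pos + 1L] == j) pos <- pos + 1L
    idx <- idx:pos
    pos <- pos + 1L
    pold <- p
    if (want_path) dA <- matrix(0, n_states, n_states)
    for (r in idx) {
      q <- tf[r] + 1L
      h <- 1 / Yval[r]
      p[tto[r] + 1L] <- p[tto[r] + 1L] + pold[q] * h
      p[q] <- p[q] - pold[q] * h
      if (want_path) {
        dA[q, tto[r] + 1L] <- dA[q, tto[r] + 1L] + h
        dA[q, q] <- dA[q, q] - h
      }
    }
    if (want_path) {
      P <- P %*% (diag(n_states) + dA)
      mats[[j]] <- P
    }
  }
  if (want_path) {
    attr(p, "path") <- list(jump_times = us, matrices = mats, P = P)
  }
  p
}

#' Aalen-Johansen state-occupation probabilities at the window end
#'
#' Estimates the probability that an at-risk subject occupies each
#' event-count state (and, when a terminal state is modeled, the death
#' state) at `s + w`, via the product-integral of the empirical transition
#' hazard increments over the progressive multi-state chain
#' `0 -> 1 -> ... -> k_max` (`-> D` from every transient state when
#' `terminal = "present"`).  All subjects occupy state 0 at the landmark,
#' so the returned vector is row 0 of the cumulative transition matrix
#' `P(s, s + w)`.  With no censoring this equals the empirical proportion
#' of subjects in each state, whether or not the process is Markov.
#'
#' @param rs a `landmark_riskset`.
#' @param details if `TRUE`, also return the full matrix path (jump times
#'   and cumulative transition matrices) as attribute `"path"`.
#' @return Named probability vector over the state labels.
#' @export
aj_state_occupation <- function(rs, details = FALSE) {
  stopifnot(inherits(rs, "landmark_riskset"))
  st <- aj_structure(rs)
  aj_occupation_impl(st, rs$window, want_path = details)
}
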