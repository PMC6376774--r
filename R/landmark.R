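#' Build a landmark dataset from event histories
#'
#' For each landmark time `s` on the grid, the at-risk subjects (those with
#' `min(terminal, censor) > s`, strictly) are kept and their event clocks are
#' reset: the relabeled event times are the recurrent events strictly after
#' `s`, measured from `s`, and the number of events at or before `s` is
#' carried as `prior_events`.  Windowed event categories are later counted in
#' the half-open interval `(s, s + window]`.
#'
#' Conventions for boundary cases (the nonparametric target probabilities are
#' only defined once these are fixed): a recurrent event at exactly time `s`
#' counts toward `prior_events`, not the window; a terminal or censoring time
#' exactly equal to `s` removes the subject from the risk set.
#'
#' @param histories list of [event_history] objects.
#' @param landmarks strictly increasing numeric vector of landmark times.
#' @param window prediction window `w > 0`; categories refer to
#'   `(s, s + w]`.
#' @param k_max integer `>= 1`; event counts `>= k_max` are pooled into a
#'   top category labeled `"<k_max>+"`.
#' @param terminal `"absent"` (terminal events treated as censoring) or
#'   `"present"` (a death category `"D"` is added).
#'
#' @return An object of class `landmark_dataset`: a list with the grid
#'   settings and one `landmark_riskset` per landmark.
#' @export
build_landmark_dataset <- function(histories, landmarks, window, k_max = 2L,
                                   terminal = c("absent", "present")) {
  terminal <- match.arg(terminal)
  landmarks <- as.numeric(landmarks)
  if (length(landmarks) == 0L) stop("empty landmark grid", call. = FALSE)
  if (is.unsorted(landmarks, strictly = TRUE)) {
    stop("landmark grid must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("window must be a single positive number", call. = FALSE)
  }
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)

  ends <- vapply(histories, function(h) min(h$terminal, h$censor), 0)
  risksets <- lapply(landmarks, function(s) {
    keep <- which(ends > s)
    if (length(keep) < 2L) {
      stop("fewer than 2 subjects at risk at landmark ", s,
           " (jackknife undefined)", call. = FALSE)
    }
    hs <- histories[keep]
    id <- vapply(hs, `[[`, "", "id")
    prior <- vapply(hs, function(h) sum(h$recurrent <= s), 0L)
    post <- lapply(hs, function(h) h$recurrent[h$recurrent > s] - s)
    end_time <- ends[keep] - s
    end_type <- vapply(hs, function(h) {
      if (h$terminal <= h$censor) "terminal" else "censor"
    }, "")
    covs <- lapply(hs, `[[`, "covariates")
    cov_df <- NULL
    if (any(lengths(covs) > 0)) {
      cov_df <- do.call(rbind, lapply(covs, function(x) {
        as.data.frame(x, stringsAsFactors = FALSE)
      }))
      rownames(cov_df) <- NULL
    }
    structure(
      list(landmark = s, window = window, k_max = k_max, terminal = terminal,
           id = unname(id), prior_events = unname(prior),
           post_times = unname(post), end_time = unname(end_time),
           end_type = unname(end_type), covariates = cov_df),
      class = "landmark_riskset"
    )
  })
  structure(
    list(landmarks = landmarks, window = window, k_max = k_max,
         terminal = terminal, risksets = risksets),
    class = "landmark_dataset"
  )
}

#' @export
print.landmark_riskset <- function(x, ...) {
  cat("<landmark_riskset> s =", x$landmark, ": n_s =", length(x$id),
      "at risk; window =", x$window, "; k_max =", x$k_max,
      "; terminal", x$terminal, "\n")
  invisible(x)
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("<landmark_dataset> ", length(x$landmarks), " landmark(s): ",
      paste(x$landmarks, collapse = ", "), "; window = ", x$window,
      "; k_max = ", x$k_max, "; terminal ", x$terminal, "\n", sep = "")
  n_s <- vapply(x$risksets, function(r) length(r$id), 0L)
  cat("  at risk: ", paste(n_s, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Drop subject j (index into rs$id) from a riskset; used by the jackknife.
riskset_drop <- function(rs, j) {
  rs$id <- rs$id[-j]
  rs$prior_events <- rs$prior_events[-j]
  rs$post_times <- rs$post_times[-j]
  rs$end_time <- rs$end_time[-j]
  rs$end_type <- rs$end_type[-j]
  if (!is.null(rs$covariates)) {
    rs$covariates <- rs$covariates[-j, , drop = FALSE]
  }
  rs
}

#' Flatten a landmark dataset to one row per (subject, landmark)
#'
#' Relabeled post-landmark event times (measured from the landmark) appear in
#' columns `t1, t2, ...`, NA-padded to the maximum observed count; covariates
#' and `prior_events` are carried per row.  All exported rows are at risk at
#' their landmark by construction; the `at_risk` column is retained for
#' interoperability.
#'
#' @param x a `landmark_dataset`.
#' @param ... unused.
#' @return A data.frame with columns `id`, `landmark`, `at_risk`,
#'   `prior_events`, `end_time`, `end_type`, covariates, `t1..tK`.
#' @export
as.data.frame.landmark_dataset <- function(x, ...) {
  kmax_obs <- max(0L, unlist(lapply(x$risksets, function(r) {
    lengths(r$post_times)
  })))
  rows <- lapply(x$risksets, function(r) {
    n <- length(r$id)
    tmat <- matrix(NA_real_, n, kmax_obs)
    for (i in seq_len(n)) {
      k <- length(r$post_times[[i]])
      if (k) tmat[i, seq_len(k)] <- r$post_times[[i]]
    }
    df <- data.frame(id = r$id, landmark = r$landmark, at_risk = TRUE,
                     prior_events = r$prior_events, end_time = r$end_time,
                     end_type = r$end_type, stringsAsFactors = FALSE)
    if (!is.null(r$covariates)) df <- cbind(df, r$covariates)
    if (kmax_obs > 0L) {
      colnames(tmat) <- paste0("t", seq_len(kmax_obs))
      df <- cbind(df, tmat)
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a landmark dataset as delimited text
#'
#' The flat representation of [as.data.frame.landmark_dataset()] is written
#' with a small commented header recording `window`, `k_max` and the
#' terminal mode, so that [read_landmark_dataset()] reproduces the object
#' field for field.
#'
#' @param x a `landmark_dataset`.
#' @param path output file.
#' @return `write_landmark_dataset`: invisibly, `path`.
#' @export
write_landmark_dataset <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# landmark_dataset",
    paste0("# window: ", format(x$window, digits = 17)),
    paste0("# k_max: ", x$k_max),
    paste0("# terminal: ", x$terminal)
  ), con)
  df <- as.data.frame(x)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmark_dataset
#' @param path input file written by [write_landmark_dataset()].
#' @return `read_landmark_dataset`: a `landmark_dataset`.
#' @export
read_landmark_dataset <- function(path) {
  hdr <- readLines(path, n = 4L)
  if (!identical(hdr[1L], "# landmark_dataset")) {
    stop("not a landmark_dataset file: ", path, call. = FALSE)
  }
  get <- function(i, key) {
    sub(paste0("^# ", key, ": "), "", hdr[i])
  }
  window <- as.numeric(get(2L, "window"))
  k_max <- as.integer(get(3L, "k_max"))
  terminal <- get(4L, "terminal")
  df <- utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                          stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  covcols <- setdiff(names(df), c("id", "landmark", "at_risk", "prior_events",
                                  "end_time", "end_type", tcols))
  landmarks <- sort(unique(df$landmark))
  risksets <- lapply(landmarks, function(s) {
    sub <- df[df$landmark == s, , drop = FALSE]
    post <- lapply(seq_len(nrow(sub)), function(i) {
      v <- as.numeric(sub[i, tcols])
      v[!is.na(v)]
    })
    structure(
      list(landmark = s, window = window, k_max = k_max, terminal = terminal,
           id = sub$id, prior_events = as.integer(sub$prior_events),
           post_times = post, end_time = sub$end_time,
           end_type = sub$end_type,
           covariates = if (length(covcols)) {
             out <- sub[, covcols, drop = FALSE]
             rownames(out) <- NULL
             out
           } else NULL),
      class = "landmark_riskset"
    )
  })
  structure(
    list(landmarks = landmarks, window = window, k_max = k_max,
         terminal = terminal, risksets = risksets),
    class = "landmark_dataset"
  )
}

# Category labels for a given k_max / terminal mode: "0", "1", ..., "k+"
# (pooled top category), plus "D" when a terminal state is modeled.
category_labels <- function(k_max, terminal = c("absent", "present")) {
  terminal <- match.arg(terminal)
  labs <- c(as.character(seq(0L, k_max - 1L)), paste0(k_max, "+"))
  if (k_max == 1L) labs <- c("0", "1+")
  if (terminal == "present") labs <- c(labs, "D")
  labs
}
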