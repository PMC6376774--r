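#' Subject-level event history
#'
#' Container for one subject's recurrent-event times, terminal-event time,
#' censoring time and (baseline) covariates.  Observation of the subject ends
#' at `min(terminal, censor)`; recurrent events can only be observed before
#' that endpoint.  A terminal time of `Inf` means "no terminal event observed
#' or considered"; a censoring time of `Inf` means the subject is followed
#' indefinitely (useful for fully observed synthetic data).
#'
#' @param id subject identifier (coerced to character).
#' @param recurrent numeric vector of recurrent-event times, strictly
#'   increasing and positive.  May be empty.
#' @param terminal terminal-event time, or `Inf` when absent.
#' @param censor censoring time, or `Inf` when the subject is never censored.
#' @param covariates named list (or one-row data.frame) of baseline covariate
#'   values frozen at time 0.
#'
#' @return An object of class `event_history`.
#' @examples
#' event_history("A", recurrent = c(0.5), censor = 1.2)
#' @export
event_history <- function(id, recurrent = numeric(), terminal = Inf,
                          censor = Inf, covariates = list()) {
  id <- as.character(id)
  recurrent <- as.numeric(recurrent)
  terminal <- as.numeric(terminal)
  censor <- as.numeric(censor)
  if (length(id) != 1L || is.na(id)) {
    stop("`id` must be a single non-missing identifier", call. = FALSE)
  }
  if (length(terminal) != 1L || length(censor) != 1L ||
      is.na(terminal) || is.na(censor) || terminal < 0 || censor < 0) {
    stop("terminal and censoring times must be single nonnegative values (id ",
         id, ")", call. = FALSE)
  }
  if (anyNA(recurrent) || any(recurrent <= 0)) {
    stop("recurrent times must be positive and non-missing for ", id,
         call. = FALSE)
  }
  if (is.unsorted(recurrent, strictly = TRUE)) {
    stop("nonmonotone times for ", id, call. = FALSE)
  }
  end <- min(terminal, censor)
  if (length(recurrent) && max(recurrent) > end) {
    stop("recurrent time after observation end for ", id, call. = FALSE)
  }
  if (is.data.frame(covariates)) covariates <- as.list(covariates)
  structure(
    list(id = id, recurrent = recurrent, terminal = terminal,
         censor = censor, covariates = covariates),
    class = "event_history"
  )
}

#' @export
print.event_history <- function(x, ...) {
  end <- min(x$terminal, x$censor)
  cat("<event_history> ", x$id, ": ", length(x$recurrent),
      " recurrent event(s)",
      if (length(x$recurrent)) paste0(" at ",
                                      paste(signif(x$recurrent, 4),
                                            collapse = ", ")),
      "; end ",
      if (is.infinite(end)) "never (followed indefinitely)"
      else paste0(signif(end, 4), " (",
                  if (x$terminal <= x$censor) "terminal" else "censor", ")"),
      "\n", sep = "")
  invisible(x)
}

#' Read subject event histories from delimited text
#'
#' The events table must have columns `id`, `time`, `type` with
#' `type` one of `"recurrent"`, `"terminal"`, `"censor"`; each subject must
#' have exactly one terminal-or-censor row, which marks the end of
#' observation.  An optional covariates table (`id`, then one column per
#' covariate) is joined by `id`.
#'
#' @param events path to a delimited file, or a data.frame, with columns
#'   `id`, `time`, `type`.
#' @param covariates optional path or data.frame with column `id` and one
#'   column per baseline covariate.
#' @param sep field separator used when paths are given.
#'
#' @return A list of [event_history] objects.
#' @export
read_event_histories <- function(events, covariates = NULL, sep = ",") {
  if (is.character(events)) {
    events <- utils::read.table(events, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  }
  need <- c("id", "time", "type")
  if (!all(need %in% names(events))) {
    stop("events table must have columns id, time, type", call. = FALSE)
  }
  bad <- setdiff(unique(events$type), c("recurrent", "terminal", "censor"))
  if (length(bad)) {
    stop("unknown event type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cov_tab <- NULL
  if (!is.null(covariates)) {
    if (is.character(covariates)) {
      covariates <- utils::read.table(covariates, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE)
    }
    if (!"id" %in% names(covariates)) {
      stop("covariates table must have an id column", call. = FALSE)
    }
    cov_tab <- covariates
    cov_tab$id <- as.character(cov_tab$id)
    if (anyDuplicated(cov_tab$id)) {
      stop("duplicate covariate rows for id ",
           cov_tab$id[duplicated(cov_tab$id)][1L], call. = FALSE)
    }
  }
  events$id <- as.character(events$id)
  ids <- unique(events$id)
  if (!is.null(cov_tab)) {
    missing_cov <- setdiff(ids, cov_tab$id)
    if (length(missing_cov)) {
      stop("no covariate row for id ", missing_cov[1L], call. = FALSE)
    }
  }
  histories <- lapply(ids, function(i) {
    sub <- events[events$id == i, , drop = FALSE]
    endpoint <- sub[sub$type != "recurrent", , drop = FALSE]
    if (nrow(endpoint) != 1L) {
      stop(if (nrow(endpoint) > 1L) "duplicate endpoint rows for "
           else "missing endpoint row for ", i, call. = FALSE)
    }
    covs <- list()
    if (!is.null(cov_tab)) {
      covs <- as.list(cov_tab[match(i, cov_tab$id),
                              setdiff(names(cov_tab), "id"), drop = FALSE])
    }
    tryCatch(
      event_history(
        id = i,
        recurrent = sub$time[sub$type == "recurrent"],
        terminal = if (endpoint$type == "terminal") endpoint$time else Inf,
        censor = if (endpoint$type == "censor") endpoint$time else Inf,
        covariates = covs
      ),
      error = function(e) stop(conditionMessage(e), call. = FALSE)
    )
  })
  names(histories) <- ids
  histories
}

#' Write event histories to delimited text
#'
#' Inverse of [read_event_histories()]: writes the long-format events file
#' and, when any subject carries covariates, a covariates file.
#'
#' @param histories list of [event_history] objects.
#' @param events_path output path for the events table.
#' @param covariates_path optional output path for the covariates table.
#' @param sep field separator.
#' @return Invisibly, the paths written.
#' @export
write_event_histories <- function(histories, events_path,
                                  covariates_path = NULL, sep = ",") {
  rows <- lapply(histories, function(h) {
    end_type <- if (h$terminal <= h$censor) "terminal" else "censor"
    data.frame(
      id = h$id,
      time = c(h$recurrent, min(h$terminal, h$censor)),
      type = c(rep("recurrent", length(h$recurrent)), end_type),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, events_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(covariates_path)) {
    covs <- lapply(histories, function(h) {
      c(list(id = h$id), h$covariates)
    })
    cov_tab <- do.call(rbind, lapply(covs, function(x) {
      as.data.frame(x, stringsAsFactors = FALSE)
    }))
    utils::write.table(cov_tab, covariates_path, sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  invisible(c(events_path, covariates_path))
}
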