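new_dpo_matrix <- function(theta, rs, estimator) {
  structure(
    list(theta = theta, id = rs$id, landmark = rs$landmark,
         window = rs$window, k_max = rs$k_max, terminal = rs$terminal,
         estimator = estimator),
    class = "dpo_matrix"
  )
}

#' @export
print.dpo_matrix <- function(x, ...) {
  cat("<dpo_matrix> s =", x$landmark, ": n_s =", nrow(x$theta),
      "subjects x", ncol(x$theta), "categories (",
      paste(colnames(x$theta), collapse = ", "), "); estimator",
      x$estimator, "\n")
  invisible(x)
}

#' Dynamic pseudo-observations from ordered-event Kaplan-Meier estimates
#'
#' Leave-one-out jackknife pseudo-observations for the windowed event-count
#' probabilities of [ordered_event_probabilities()]:
#' `theta_ik = n_s * F_k - (n_s - 1) * F_k^(-i)`, with each leave-one-out
#' estimate recomputed honestly on the data without subject `i` (no
#' analytic update formulas).  The zero-event column is computed explicitly
#' (not by one-minus-rest), so the row-sum-to-one identity is a genuine
#' check on the estimator.  With no censoring every entry is the exact 0/1
#' category indicator, and the column means reproduce the full-sample
#' Kaplan-Meier-based estimates exactly.
#'
#' @param rs a `landmark_riskset` with at least 2 subjects.
#' @return A `dpo_matrix`: pseudo-observations (rows = subjects, columns =
#'   event-count categories) plus landmark metadata.
#' @export
dpo_km <- function(rs) {
  stopifnot(inherits(rs, "landmark_riskset"))
  n <- length(rs$id)
  if (n < 2L) stop("jackknife undefined: fewer than 2 subjects at risk",
                   call. = FALSE)
  labs <- category_labels(rs$k_max, "absent")
  dm <- ordered_duration_matrix(rs)
  full <- ordered_probs_impl(dm, rs$window, rs$k_max, labs)
  if (any(full < 0)) {
    warning("KM-difference estimate produced negative category ",
            "probability (crossing curves); values not clipped",
            call. = FALSE)
  }
  theta <- matrix(NA_real_, n, length(full),
                  dimnames = list(rs$id, labs))
  for (i in seq_len(n)) {
    loo <- suppressWarnings(
      ordered_probs_impl(dm, rs$window, rs$k_max, labs, drop = i))
    theta[i, ] <- n * full - (n - 1) * loo
  }
  new_dpo_matrix(theta, rs, "km")
}

#' Dynamic pseudo-observations from Aalen-Johansen state occupation
#'
#' Leave-one-out jackknife pseudo-observations over
#' [aj_state_occupation()], each leave-one-out estimate being a full
#' product-integral re-estimation on the data without that subject.  When
#' the riskset was built with `terminal = "present"`, a death column `"D"`
#' is produced alongside the event-count columns.  Column means coincide
#' with the full-sample estimates exactly in the two-state reduction and
#' under no censoring; in the general censored multi-state case they
#' differ by a small higher-order term (the product-integral is not a
#' linear statistic), which is why the expectation of these
#' pseudo-observations -- not the plug-in estimate -- is the dynamic
#' predicted value.
#'
#' @inheritParams dpo_km
#' @return A `dpo_matrix`.
#' @export
dpo_aj <- function(rs) {
  stopifnot(inherits(rs, "landmark_riskset"))
  n <- length(rs$id)
  if (n < 2L) stop("jackknife undefined: fewer than 2 subjects at risk",
                   call. = FALSE)
  st <- aj_structure(rs)
  full <- aj_occupation_impl(st, rs$window)
  theta <- matrix(NA_real_, n, length(full),
                  dimnames = list(rs$id, names(full)))
  for (i in seq_len(n)) {
    loo <- aj_occupation_impl(st, rs$window, drop = i)
    theta[i, ] <- n * full - (n - 1) * loo
  }
  new_dpo_matrix(theta, rs, "aj")
}

#' Compute pseudo-observations at every landmark of a dataset
#'
#' Convenience wrapper applying [dpo_aj()] or [dpo_km()] to each riskset of
#' a `landmark_dataset`.
#'
#' @param ld a `landmark_dataset`.
#' @param estimator `"aj"` or `"km"` (the KM route requires
#'   `terminal = "absent"`).
#' @return A list of `dpo_matrix` objects, one per landmark.
#' @export
compute_dpos <- function(ld, estimator = c("aj", "km")) {
  estimator <- match.arg(estimator)
  if (estimator == "km" && ld$terminal == "present") {
    stop("KM-based pseudo-observations require terminal = \"absent\"",
         call. = FALSE)
  }
  f <- if (estimator == "aj") dpo_aj else dpo_km
  lapply(ld$risksets, f)
}

#' Stack per-landmark pseudo-observations into a long table
#'
#' Subjects contribute one block per landmark at which they are at risk;
#' blocks are keyed by `(id, landmark)` for clustering in the supermodel
#' estimating equations.
#'
#' @param dpos list of `dpo_matrix` objects computed with identical window,
#'   `k_max`, terminal mode and estimator.
#' @return A data.frame `id, landmark, estimator, theta_<label>...` with
#'   attributes `window`, `k_max`, `terminal`, `estimator`, `categories`.
#' @export
stack_dpos <- function(dpos) {
  if (inherits(dpos, "dpo_matrix")) dpos <- list(dpos)
  stopifnot(length(dpos) >= 1L,
            all(vapply(dpos, inherits, TRUE, "dpo_matrix")))
  ref <- dpos[[1L]]
  same <- vapply(dpos, function(d) {
    identical(d$window, ref$window) && identical(d$k_max, ref$k_max) &&
      identical(d$terminal, ref$terminal) &&
      identical(d$estimator, ref$estimator)
  }, TRUE)
  if (!all(same)) {
    stop("pseudo-observation matrices have inconsistent settings ",
         "(window / k_max / terminal / estimator)", call. = FALSE)
  }
  blocks <- lapply(dpos, function(d) {
    df <- data.frame(id = d$id, landmark = d$landmark,
                     estimator = d$estimator, stringsAsFactors = FALSE)
    th <- as.data.frame(d$theta)
    names(th) <- paste0("theta_", colnames(d$theta))
    rownames(th) <- NULL
    cbind(df, th)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "window") <- ref$window
  attr(out, "k_max") <- ref$k_max
  attr(out, "terminal") <- ref$terminal
  attr(out, "estimator") <- ref$estimator
  attr(out, "categories") <- colnames(ref$theta)
  out
}

#' Write stacked pseudo-observations to delimited text
#'
#' @param dpos a list of `dpo_matrix` objects or the output of
#'   [stack_dpos()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_dpos <- function(dpos, path) {
  tab <- if (is.data.frame(dpos)) dpos else stack_dpos(dpos)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
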