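#' Inverse generalized-logit link
#'
#' Maps per-category linear predictors (reference category omitted) to the
#' full probability vector, reference first:
#' `p_c = exp(eta_c) / (1 + sum(exp(eta)))`, `p_ref = 1 / (1 + sum(exp(eta)))`.
#' Overflow is guarded by shifting by the maximum predictor.
#'
#' @param eta numeric vector of linear predictors for the non-reference
#'   categories.
#' @return Probability vector of length `length(eta) + 1`, reference first,
#'   summing to 1.
#' @examples
#' inverse_glogit(c(0, 0))      # (1/3, 1/3, 1/3)
#' inverse_glogit(log(2))       # (1/3, 2/3)
#' @export
inverse_glogit <- function(eta) {
  m <- max(0, eta)
  e <- exp(eta - m)
  denom <- exp(-m) + sum(e)
  c(exp(-m), e) / denom
}

basis_names <- function(h) {
  vapply(0:h, function(b) {
    if (b == 0L) "1" else if (b == 1L) "s" else paste0("s^", b)
  }, "")
}

# Assemble the observation blocks for the estimating equations from a list
# of dpo_matrix objects and a covariate table keyed by id (and landmark,
# when covariates vary across landmarks).
build_gee_obs <- function(dpos, data, formula) {
  ref <- dpos[[1L]]
  cats <- colnames(ref$theta)
  nonref <- cats[-1L]
  blocks <- lapply(dpos, function(d) {
    n <- nrow(d$theta)
    if (is.null(data)) {
      if (length(all.vars(formula)) > 0L) {
        stop("a covariate table is required for formula ",
             deparse(formula), call. = FALSE)
      }
      df <- data.frame(row.names = seq_len(n))
    } else {
      if (!"id" %in% names(data)) {
        stop("covariate table must have an id column", call. = FALSE)
      }
      if ("landmark" %in% names(data)) {
        idx <- match(paste(d$id, d$landmark),
                     paste(as.character(data$id), data$landmark))
      } else {
        idx <- match(d$id, as.character(data$id))
      }
      if (anyNA(idx)) {
        stop("missing covariate row for id ", d$id[which(is.na(idx))[1L]],
             " at landmark ", d$landmark, call. = FALSE)
      }
      df <- data[idx, , drop = FALSE]
    }
    vars <- all.vars(formula)
    missing_cols <- setdiff(vars, names(df))
    if (length(missing_cols)) {
      stop("missing covariate column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    X <- stats::model.matrix(formula, df)
    if (nrow(X) != n) {
      stop("covariate rows with missing values at landmark ", d$landmark,
           call. = FALSE)
    }
    list(Theta = d$theta[, -1L, drop = FALSE], X = X,
         s = rep(d$landmark, n), id = d$id)
  })
  list(
    Theta = do.call(rbind, lapply(blocks, `[[`, "Theta")),
    X = do.call(rbind, lapply(blocks, `[[`, "X")),
    s = unlist(lapply(blocks, `[[`, "s")),
    id = unlist(lapply(blocks, `[[`, "id")),
    categories = cats, nonref = nonref
  )
}

# Fisher scoring for the multinomial quasi-score
#   U(beta) = sum_i D_i' Vw_i^{-1} (thetahat_i - theta_i),
# with D_i = V_i Z*_i (canonical generalized-logit link), V_i the
# multinomial covariance at the fitted probabilities, and Vw the working
# covariance: V itself ("multinomial") or its diagonal ("binary").
fit_gee_core <- function(obs, h, center, working,
                         vcov_type = c("model", "sandwich"),
                         tol_score = 1e-8, tol_beta = 1e-10,
                         max_iter = 100L) {
  vcov_type <- match.arg(vcov_type)
  Theta <- obs$Theta
  X <- obs$X
  N <- nrow(Theta)
  Cm1 <- ncol(Theta)
  p <- ncol(X)
  fb <- outer(obs$s - center, 0:h, `^`)
  q0 <- p * (h + 1L)
  V <- matrix(0, N, q0)
  for (b in 0:h) V[, b * p + seq_len(p)] <- X * fb[, b + 1L]
  expanded_names <- as.vector(outer(colnames(X), basis_names(h),
                                    function(cv, bn) paste(bn, cv, sep = ":")))
  qrV <- qr(V)
  if (qrV$rank < q0) {
    bad <- expanded_names[qrV$pivot[seq(qrV$rank + 1L, q0)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  q <- q0 * Cm1

  eval_score <- function(beta) {
    B <- matrix(beta, q0, Cm1)
    Eta <- V %*% B
    m <- pmax(apply(Eta, 1L, max), 0)
    E <- exp(Eta - m)
    Th <- E / (exp(-m) + rowSums(E))
    Th <- pmin(pmax(Th, 1e-10), 1 - 1e-10)
    R <- Theta - Th
    U <- numeric(q)
    A <- matrix(0, q, q)
    contrib <- matrix(0, N, q)
    for (i in seq_len(N)) {
      th <- Th[i, ]
      Vi <- diag(th, nrow = Cm1) - tcrossprod(th)
      if (working == "multinomial") {
        wr <- R[i, ]
        M <- Vi
      } else {
        winv <- 1 / pmax(diag(Vi), 1e-10)
        wr <- drop(Vi %*% (winv * R[i, ]))
        M <- Vi %*% (winv * Vi)
      }
      v <- V[i, ]
      ui <- kronecker(wr, v)
      U <- U + ui
      contrib[i, ] <- ui
      A <- A + kronecker(M, tcrossprod(v))
    }
    list(U = U, A = A, contrib = contrib)
  }

  beta <- numeric(q)
  sc <- eval_score(beta)
  norm0 <- max(abs(sc$U))
  iter <- 0L
  converged <- norm0 < tol_score
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    delta <- tryCatch(solve(sc$A, sc$U), error = function(e) {
      stop("Fisher information singular at iteration ", iter,
           " (score norm ", format(norm0), ")", call. = FALSE)
    })
    step <- 1
    repeat {
      cand <- beta + step * delta
      sc_new <- eval_score(cand)
      norm_new <- max(abs(sc_new$U))
      if (norm_new <= norm0 || step < 2^-20) break
      step <- step / 2
    }
    rel <- max(abs(step * delta)) / max(1, max(abs(cand)))
    beta <- cand
    sc <- sc_new
    norm0 <- norm_new
    if (norm0 < tol_score || rel < tol_beta) converged <- TRUE
  }
  if (!converged) {
    stop("estimating equations did not converge in ", max_iter,
         " iterations; final score norm ", format(norm0), call. = FALSE)
  }

  A <- sc$A
  bread <- solve(A)
  if (vcov_type == "sandwich") {
    G <- rowsum(sc$contrib, group = obs$id)
    meat <- crossprod(G)
    vc <- bread %*% meat %*% bread
  } else {
    meat <- NULL
    vc <- bread
  }
  vc <- (vc + t(vc)) / 2

  index <- data.frame(
    category = rep(obs$nonref, each = q0),
    basis = rep(rep(0:h, each = p), Cm1),
    covariate = rep(colnames(X), (h + 1L) * Cm1),
    stringsAsFactors = FALSE
  )
  nm <- paste(index$category,
              rep(rep(basis_names(h), each = p), Cm1),
              index$covariate, sep = ":")
  names(beta) <- nm
  dimnames(vc) <- list(nm, nm)
  list(beta = beta, vcov = vc, vcov_type = vcov_type, A = A, meat = meat,
       index = index, iterations = iter, score_norm = norm0,
       converged = converged)
}

new_landmark_gee <- function(core, obs, formula, h, center, landmarks,
                             working, estimator, model) {
  structure(
    c(core,
      list(formula = formula, degree = h, center = center,
           landmarks = landmarks, working = working, estimator = estimator,
           model = model, categories = obs$categories,
           reference = obs$categories[1L], n_obs = nrow(obs$Theta),
           n_subjects = length(unique(obs$id)))),
    class = "landmark_gee"
  )
}

#' Fit a fixed-landmark multinomial model to pseudo-observations
#'
#' Regresses the dynamic pseudo-observations of one landmark on covariates
#' through a generalized-logit link, solving the multinomial estimating
#' equation by Fisher scoring with step-halving.  The reference category is
#' the zero-event category (its pseudo-observations enter only through the
#' sum-to-one constraint).  The covariance is the model-based inverse
#' Fisher information.
#'
#' @param dpo a `dpo_matrix` from [dpo_aj()] or [dpo_km()].
#' @param data covariate table with an `id` column, one row per subject
#'   (`NULL` for an intercept-only model).
#' @param formula right-hand-side formula over columns of `data`.
#' @param working `"multinomial"` uses the full multinomial covariance as
#'   working covariance (primary formulation); `"binary"` uses its diagonal
#'   (the multivariate-binary workaround, identical point estimates up to
#'   working-weight differences).
#' @return An object of class `landmark_gee`.
#' @export
fit_landmark_gee <- function(dpo, data = NULL, formula = ~1,
                             working = c("multinomial", "binary")) {
  stopifnot(inherits(dpo, "dpo_matrix"))
  working <- match.arg(working)
  obs <- build_gee_obs(list(dpo), data, formula)
  core <- fit_gee_core(obs, h = 0L, center = dpo$landmark,
                       working = working, vcov_type = "model")
  new_landmark_gee(core, obs, formula, 0L, dpo$landmark, dpo$landmark,
                   working, dpo$estimator, "fixed")
}

#' Fit a landmark supermodel with polynomial coefficient smoothers
#'
#' Stacks pseudo-observation blocks over a landmark grid and lets every
#' regression coefficient vary with landmark time through the polynomial
#' basis `1, s, ..., s^degree` (landmark times are centered at the grid
#' midpoint by default to condition the cubic basis; use
#' [uncenter_coefficients()] to report on the raw scale).  Subjects
#' contribute one block per at-risk landmark; the estimating equations use
#' working independence across a subject's blocks and the covariance is the
#' robust sandwich estimator clustered by subject.
#'
#' @param dpos list of `dpo_matrix` objects over at least 2 landmarks (same
#'   window, `k_max`, terminal mode, estimator).
#' @param data covariate table with an `id` column and, when covariates are
#'   landmark-dependent (for example a prior-event-count indicator), a
#'   `landmark` column; matched to blocks by `(id, landmark)`.
#' @param formula right-hand-side formula over columns of `data`.
#' @param degree polynomial smoother degree `h >= 0`; must be less than the
#'   number of landmarks.
#' @param center `TRUE` (center landmark times at the grid midpoint),
#'   `FALSE`, or a number giving the centering constant.
#' @inheritParams fit_landmark_gee
#' @return An object of class `landmark_gee`.
#' @export
fit_landmark_supermodel <- function(dpos, data = NULL, formula = ~1,
                                    degree = 3L, center = TRUE,
                                    working = c("multinomial", "binary")) {
  working <- match.arg(working)
  if (inherits(dpos, "dpo_matrix")) dpos <- list(dpos)
  stopifnot(all(vapply(dpos, inherits, TRUE, "dpo_matrix")))
  landmarks <- vapply(dpos, `[[`, 0, "landmark")
  if (length(landmarks) < 2L) {
    stop("supermodel requires at least 2 landmarks", call. = FALSE)
  }
  h <- as.integer(degree)
  if (h < 0L) stop("degree must be >= 0", call. = FALSE)
  if (h >= length(landmarks)) {
    stop("smoother degree ", h, " unidentifiable with ",
         length(landmarks), " landmarks", call. = FALSE)
  }
  stack_dpos(dpos)  # validates consistent settings
  c0 <- if (isTRUE(center)) mean(range(landmarks))
        else if (identical(center, FALSE)) 0
        else as.numeric(center)
  obs <- build_gee_obs(dpos, data, formula)
  core <- fit_gee_core(obs, h = h, center = c0, working = working,
                       vcov_type = "sandwich")
  new_landmark_gee(core, obs, formula, h, c0, sort(landmarks), working,
                   dpos[[1L]]$estimator, "supermodel")
}

#' @export
print.landmark_gee <- function(x, ...) {
  cat("<landmark_gee> ", x$model, " model, estimator ", x$estimator,
      ", link glogit\n", sep = "")
  cat("  categories: ", paste(x$categories, collapse = ", "),
      " (reference ", x$reference, ")\n", sep = "")
  cat("  landmarks: ", paste(x$landmarks, collapse = ", "),
      if (x$model == "supermodel")
        paste0("; smoother degree ", x$degree, " (centered at ",
               signif(x$center, 4), ")"),
      "\n", sep = "")
  cat("  ", length(x$beta), " coefficients; ", x$n_obs, " blocks from ",
      x$n_subjects, " subjects; converged in ", x$iterations,
      " iterations (score norm ", format(x$score_norm, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' @export
coef.landmark_gee <- function(object, ...) object$beta

#' @export
vcov.landmark_gee <- function(object, ...) object$vcov

#' Tidy coefficient table of a landmark fit
#'
#' One row per (category, smoother basis degree, covariate) with the
#' estimate and its standard error (model-based for fixed-landmark fits,
#' robust sandwich for supermodels).
#'
#' @param fit a `landmark_gee`.
#' @return A data.frame `category, basis_degree, covariate, estimate, se`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "landmark_gee"))
  data.frame(
    category = fit$index$category,
    basis_degree = fit$index$basis,
    covariate = fit$index$covariate,
    estimate = unname(fit$beta),
    se = sqrt(pmax(diag(fit$vcov), 0)),
    stringsAsFactors = FALSE
  )
}

#' Report supermodel coefficients on the raw landmark-time scale
#'
#' Supermodel polynomial bases are built in `s - center`; this expands the
#' fitted polynomials back to powers of raw `s`:
#' `beta_raw_b = sum_{b' >= b} choose(b', b) (-center)^(b'-b) beta_b'`.
#'
#' @param fit a supermodel `landmark_gee`.
#' @return A data.frame like [coef_table()] (estimates only; standard
#'   errors are not transformed).
#' @export
uncenter_coefficients <- function(fit) {
  stopifnot(inherits(fit, "landmark_gee"))
  tab <- coef_table(fit)
  cmid <- fit$center
  h <- fit$degree
  out <- tab[c("category", "basis_degree", "covariate")]
  out$estimate <- NA_real_
  for (cat in unique(tab$category)) {
    for (cv in unique(tab$covariate)) {
      sel <- which(tab$category == cat & tab$covariate == cv)
      sel <- sel[order(tab$basis_degree[sel])]
      bvals <- tab$estimate[sel]
      raw <- vapply(0:h, function(b) {
        sum(vapply(b:h, function(bp) {
          choose(bp, b) * (-cmid)^(bp - b) * bvals[bp + 1L]
        }, 0))
      }, 0)
      out$estimate[sel] <- raw
    }
  }
  out$se <- NA_real_
  out
}

#' Predicted category probabilities with delta-method intervals
#'
#' Evaluates the fitted generalized-logit model at landmark time `s` for a
#' covariate profile, returning all category probabilities (reference
#' included), their delta-method standard errors and Wald confidence
#' intervals truncated to `[0, 1]`.  Supermodels refuse to extrapolate
#' outside the fitted landmark range; fixed-landmark fits require `s` equal
#' to their landmark.
#'
#' @param fit a `landmark_gee`.
#' @param newdata one-row data.frame with the covariate profile (`NULL` for
#'   intercept-only fits).
#' @param s landmark time(s) at which to predict.
#' @param level confidence level.
#' @return A data.frame `s, category, estimate, se, lower, upper`; the
#'   probabilities sum to 1 at every `s`.
#' @export
predict_probabilities <- function(fit, newdata = NULL, s = fit$landmarks,
                                  level = 0.95) {
  stopifnot(inherits(fit, "landmark_gee"))
  if (fit$model == "fixed") {
    if (!all(s == fit$landmarks[1L])) {
      stop("fixed-landmark fit can only predict at s = ", fit$landmarks[1L],
           call. = FALSE)
    }
  } else {
    rng <- range(fit$landmarks)
    if (any(s < rng[1L] | s > rng[2L])) {
      stop("refusing to extrapolate outside the fitted landmark range [",
           rng[1L], ", ", rng[2L], "]", call. = FALSE)
    }
  }
  if (is.null(newdata)) {
    df <- data.frame(row.names = 1L)
  } else {
    stopifnot(is.data.frame(newdata), nrow(newdata) == 1L)
    df <- newdata
  }
  x <- drop(stats::model.matrix(fit$formula, df))
  h <- fit$degree
  Cm1 <- length(fit$categories) - 1L
  q0 <- length(fit$beta) / Cm1
  B <- matrix(fit$beta, q0, Cm1)
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(s, function(si) {
    fbv <- (si - fit$center)^(0:h)
    v <- as.vector(outer(x, fbv))
    eta <- drop(crossprod(B, v))
    prob <- inverse_glogit(eta)
    # d p / d eta over the full vector (reference first)
    dpdeta <- -outer(prob, prob[-1L])
    for (d in seq_len(Cm1)) {
      dpdeta[d + 1L, d] <- dpdeta[d + 1L, d] + prob[d + 1L]
    }
    J <- kronecker(dpdeta, t(v))
    se <- sqrt(pmax(diag(J %*% fit$vcov %*% t(J)), 0))
    data.frame(s = si, category = fit$categories,
               estimate = prob, se = se,
               lower = pmax(prob - zcrit * se, 0),
               upper = pmin(prob + zcrit * se, 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
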