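test_that("inverse generalized-logit has the closed-form values", {
  expect_equal(inverse_glogit(c(0, 0)), rep(1 / 3, 3))
  expect_equal(inverse_glogit(log(2)), c(1 / 3, 2 / 3))
  expect_equal(sum(inverse_glogit(c(2, -1, 0.5))), 1)
  # reference probability tends to 1 as predictors fall
  expect_equal(inverse_glogit(c(-800, -900))[1L], 1)
  # overflow guard
  expect_equal(inverse_glogit(c(800, 700)), c(0, 1, 0), tolerance = 1e-30)
})

test_that("intercept-only fitted means equal pseudo-observation means", {
  set.seed(47)
  rs <- random_riskset(n = 50, lambda_c = 0.5, lambda0D = 0.3)
  d <- dpo_aj(rs)
  fit <- fit_landmark_gee(d)
  p <- predict_probabilities(fit, s = rs$landmark)
  expect_equal(p$estimate, unname(colMeans(d$theta)), tolerance = 1e-8)
  expect_equal(p$category, c("0", "1", "2+", "D"))
  expect_equal(sum(p$estimate), 1, tolerance = 1e-12)
})

test_that("uncensored two-category fit equals binomial logistic regression", {
  set.seed(53)
  scn <- scenario(n = 90, lambda_c = 0)
  co <- simulate_cohort(scn)
  x <- rbinom(90, 1, 0.5)
  z <- rnorm(90)
  rs <- make_riskset(co$histories, k_max = 1L)
  d <- dpo_km(rs)
  dat <- data.frame(id = d$id, x = x, z = z)
  fit <- fit_landmark_gee(d, dat, ~ x + z)
  ref <- glm(round(d$theta[, 2L]) ~ x + z, family = binomial)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("group-wise fits match a saturated joint parameterization", {
  set.seed(59)
  rs <- random_riskset(n = 80, lambda_c = 0.4, frailty = "gamma")
  d <- dpo_aj(rs)
  g <- rbinom(length(d$id), 1, 0.5)
  dat <- data.frame(id = d$id, g = g)
  joint <- fit_landmark_gee(d, dat, ~g)
  p0 <- predict_probabilities(joint, data.frame(g = 0), s = rs$landmark)
  p1 <- predict_probabilities(joint, data.frame(g = 1), s = rs$landmark)
  # fitting the groups separately (on the same pseudo-observations)
  # gives the same group probabilities
  for (gv in 0:1) {
    keep <- which(g == gv)
    d_g <- d
    d_g$theta <- d$theta[keep, , drop = FALSE]
    d_g$id <- d$id[keep]
    fit_g <- fit_landmark_gee(d_g)
    pg <- predict_probabilities(fit_g, s = rs$landmark)
    pj <- if (gv == 0) p0 else p1
    expect_equal(pj$estimate, pg$estimate, tolerance = 1e-6)
  }
})

test_that("probabilities are invariant to relabeling non-reference categories", {
  set.seed(61)
  rs <- random_riskset(n = 60, lambda_c = 0.5, lambda0D = 0.3)
  d <- dpo_aj(rs)
  fit <- fit_landmark_gee(d)
  p <- predict_probabilities(fit, s = rs$landmark)
  # permute the non-reference columns of the pseudo-observation matrix
  perm <- c(1L, 4L, 2L, 3L)
  d2 <- d
  d2$theta <- d$theta[, perm]
  fit2 <- fit_landmark_gee(d2)
  p2 <- predict_probabilities(fit2, s = rs$landmark)
  expect_equal(p2$estimate[match(p$category, p2$category)], p$estimate,
               tolerance = 1e-8)
})

test_that("degree-0 supermodel equals a pooled fixed-landmark fit", {
  set.seed(67)
  scn <- scenario(n = 60, lambda_c = 0.4, lambda0D = 0.3)
  co <- simulate_cohort(scn)
  ld <- build_landmark_dataset(co$histories, c(0, 0.25), window = 1,
                               k_max = 2L, terminal = "present")
  dpos <- compute_dpos(ld, "aj")
  sup <- fit_landmark_supermodel(dpos, degree = 0L)
  # pooled fit: treat all stacked rows as one landmark's pseudo-observations
  pooled_theta <- rbind(dpos[[1L]]$theta, dpos[[2L]]$theta)
  pooled <- dpos[[1L]]
  pooled$theta <- pooled_theta
  pooled$id <- c(dpos[[1L]]$id, dpos[[2L]]$id)
  fixed <- fit_landmark_gee(pooled)
  expect_equal(unname(coef(sup)), unname(coef(fixed)), tolerance = 1e-8)
})

test_that("a saturated supermodel reproduces per-landmark fixed fits", {
  set.seed(71)
  scn <- scenario(n = 80, lambda_c = 0.4)
  co <- simulate_cohort(scn)
  ld <- build_landmark_dataset(co$histories, c(0, 0.4), window = 1,
                               k_max = 2L, terminal = "absent")
  dpos <- compute_dpos(ld, "aj")
  sup <- fit_landmark_supermodel(dpos, degree = 1L)  # saturated: 2 landmarks
  for (m in 1:2) {
    fixed <- fit_landmark_gee(dpos[[m]])
    ps <- predict_probabilities(sup, s = ld$landmarks[m])
    pf <- predict_probabilities(fixed, s = ld$landmarks[m])
    expect_equal(ps$estimate, pf$estimate, tolerance = 1e-7)
  }
})

test_that("supermodel guards identifiability and extrapolation", {
  set.seed(73)
  scn <- scenario(n = 40, lambda_c = 0.4)
  co <- simulate_cohort(scn)
  ld <- build_landmark_dataset(co$histories, c(0, 0.3), window = 1,
                               k_max = 2L)
  dpos <- compute_dpos(ld, "aj")
  expect_error(fit_landmark_supermodel(dpos, degree = 2L),
               "unidentifiable")
  expect_error(fit_landmark_supermodel(dpos[1], degree = 0L),
               "at least 2 landmarks")
  sup <- fit_landmark_supermodel(dpos, degree = 1L)
  expect_error(predict_probabilities(sup, s = 0.9), "extrapolate")
  fixed <- fit_landmark_gee(dpos[[1L]])
  expect_error(predict_probabilities(fixed, s = 0.3), "only predict")
})

test_that("rank-deficient designs are reported with the collinear column", {
  set.seed(79)
  rs <- random_riskset(n = 40, lambda_c = 0.4)
  d <- dpo_aj(rs)
  dat <- data.frame(id = d$id, x = rbinom(40, 1, 0.5))
  dat$x2 <- 2 * dat$x
  expect_error(fit_landmark_gee(d, dat, ~ x + x2), "collinear.*x2")
  expect_error(fit_landmark_gee(d, dat, ~ x + missing_col),
               "missing covariate column")
})

test_that("sandwich covariance reduces to the model-based form", {
  # with one block per subject and the residual outer products replaced by
  # the working covariance, the meat equals the bread inverse
  set.seed(83)
  rs <- random_riskset(n = 50, lambda_c = 0.5, lambda0D = 0.3)
  d <- dpo_aj(rs)
  fit <- fit_landmark_gee(d)
  # reconstruct A from fitted probabilities and check meat-under-V equals A
  p <- predict_probabilities(fit, s = rs$landmark)$estimate[-1L]
  Vhat <- diag(p, nrow = length(p)) - tcrossprod(p)
  A_expected <- length(d$id) * Vhat   # intercept-only: sum_i V_i
  expect_equal(unname(fit$A), unname(A_expected), tolerance = 1e-6)
  expect_equal(unname(fit$vcov), unname(solve(fit$A)), tolerance = 1e-10)
})

test_that("binary working covariance reproduces multinomial point estimates", {
  set.seed(89)
  rs <- random_riskset(n = 70, lambda_c = 0.5, lambda0D = 0.3)
  d <- dpo_aj(rs)
  dat <- data.frame(id = d$id, x = rbinom(70, 1, 0.5))
  f_multi <- fit_landmark_gee(d, dat, ~x, working = "multinomial")
  f_bin <- fit_landmark_gee(d, dat, ~x, working = "binary")
  expect_equal(coef(f_bin), coef(f_multi), tolerance = 1e-4)
})

test_that("supermodel coefficients un-center to an equivalent polynomial", {
  set.seed(97)
  scn <- scenario(n = 60, lambda_c = 0.4)
  co <- simulate_cohort(scn)
  ld <- build_landmark_dataset(co$histories, c(0, 0.2, 0.4, 0.6),
                               window = 1, k_max = 2L)
  dpos <- compute_dpos(ld, "aj")
  sup <- fit_landmark_supermodel(dpos, degree = 3L)
  raw <- uncenter_coefficients(sup)
  # evaluate both parameterizations at an arbitrary s
  s0 <- 0.37
  for (cat in unique(raw$category)) {
    sel <- raw$category == cat
    eta_raw <- sum(raw$estimate[sel] * s0^raw$basis_degree[sel])
    tab <- coef_table(sup)
    selc <- tab$category == cat
    eta_c <- sum(tab$estimate[selc] * (s0 - sup$center)^tab$basis_degree[selc])
    expect_equal(eta_raw, eta_c, tolerance = 1e-8)
  }
})
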