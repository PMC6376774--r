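test_that("event histories parse from long-format rows", {
  ev <- data.frame(
    id = c("A", "A", "B"),
    time = c(0.5, 1.2, 2.0),
    type = c("recurrent", "censor", "terminal"),
    stringsAsFactors = FALSE
  )
  hs <- read_event_histories(ev)
  expect_length(hs, 2L)
  expect_equal(hs$A$recurrent, 0.5)
  expect_equal(hs$A$censor, 1.2)
  expect_equal(hs$A$terminal, Inf)
  expect_equal(hs$B$recurrent, numeric(0))
  expect_equal(hs$B$terminal, 2.0)
})

test_that("invalid event tables are rejected with the offending id", {
  bad_order <- data.frame(id = "C", time = c(1.0, 0.5, 2),
                          type = c("recurrent", "recurrent", "censor"))
  expect_error(read_event_histories(bad_order), "nonmonotone.*C")
  two_ends <- data.frame(id = "E", time = c(1, 2),
                         type = c("censor", "terminal"))
  expect_error(read_event_histories(two_ends), "duplicate endpoint.*E")
  no_end <- data.frame(id = "F", time = 1, type = "recurrent")
  expect_error(read_event_histories(no_end), "missing endpoint.*F")
  unknown <- data.frame(id = "G", time = 1, type = "death")
  expect_error(read_event_histories(unknown), "unknown event type")
  ev <- data.frame(id = "A", time = 1, type = "censor")
  cov <- data.frame(id = "B", x = 1)
  expect_error(read_event_histories(ev, cov), "no covariate row for id A")
  expect_error(event_history("H", recurrent = c(2, 1), censor = 3),
               "nonmonotone")
  expect_error(event_history("H", recurrent = 2, censor = 1),
               "after observation end")
})

test_that("event history round-trips through delimited text", {
  hs <- fixture_histories()
  for (i in seq_along(hs)) hs[[i]]$covariates <- list(x = i %% 2)
  ev_path <- withr::local_tempfile(fileext = ".csv")
  cov_path <- withr::local_tempfile(fileext = ".csv")
  write_event_histories(hs, ev_path, cov_path)
  back <- read_event_histories(ev_path, cov_path)
  expect_length(back, length(hs))
  for (h in hs) {
    b <- back[[h$id]]
    expect_equal(b$recurrent, h$recurrent)
    expect_equal(b$terminal, h$terminal)
    expect_equal(b$censor, h$censor)
    expect_equal(b$covariates$x, h$covariates$x)
  }
})

test_that("landmark construction relabels times and applies risk-set rules", {
  ld <- build_landmark_dataset(fixture_histories(), c(0, 0.5, 1),
                               window = 1, k_max = 2)
  df <- as.data.frame(ld)
  # subject A censored at 1.2 > 1: at risk at every landmark
  a1 <- df[df$id == "A" & df$landmark == 1, ]
  expect_true(a1$at_risk)
  expect_equal(a1$prior_events, 1L)
  expect_true(is.na(a1$t1))              # no events after s = 1
  expect_equal(a1$end_time, 0.2)         # censored 0.2 after the landmark
  a0 <- df[df$id == "A" & df$landmark == 0, ]
  expect_equal(a0$t1, 0.5)
  # subject C at s = 0.5: one prior event (0.3), next event 0.7 -> 0.2 later
  c5 <- df[df$id == "C" & df$landmark == 0.5, ]
  expect_equal(c5$prior_events, 1L)
  expect_equal(c5$t1, 0.2)
  # subject D dead at 0.4: not at risk at 0.5 or 1
  expect_false(any(df$id == "D" & df$landmark >= 0.5))
  expect_true(any(df$id == "D" & df$landmark == 0))
})

test_that("boundary events at the landmark follow the stated conventions", {
  hs <- list(
    event_history("X", recurrent = 1, censor = 5),  # event exactly at s = 1
    event_history("Y", censor = 1),                  # censored exactly at s = 1
    event_history("Z", censor = 5)
  )
  ld <- build_landmark_dataset(hs, 1, window = 1, k_max = 2)
  rs <- ld$risksets[[1L]]
  expect_false("Y" %in% rs$id)           # endpoint at s removes from risk set
  x <- which(rs$id == "X")
  expect_equal(rs$prior_events[x], 1L)   # event at s counts as prior
  expect_length(rs$post_times[[x]], 0L)
})

test_that("risk sets shrink monotonely and relabeling is shift-consistent", {
  set.seed(42)
  scn <- scenario(n = 60, frailty = "gamma", lambda0D = 0.3, lambda_c = 0.4)
  co <- simulate_cohort(scn)
  grid <- c(0, 0.2, 0.5, 0.9)
  ld <- build_landmark_dataset(co$histories, grid, window = 1, k_max = 2,
                               terminal = "present")
  n_s <- vapply(ld$risksets, function(r) length(r$id), 0L)
  expect_true(all(diff(n_s) <= 0))
  for (rs in ld$risksets) {
    for (j in seq_along(rs$id)) {
      h <- co$histories[[rs$id[j]]]
      expect_identical(rs$post_times[[j]],
                       h$recurrent[h$recurrent > rs$landmark] - rs$landmark)
      expect_equal(rs$prior_events[j], sum(h$recurrent <= rs$landmark))
      expect_true(min(h$terminal, h$censor) > rs$landmark)
    }
  }
})

test_that("landmark datasets round-trip through delimited text", {
  set.seed(7)
  scn <- scenario(n = 20, lambda0D = 0.3, lambda_c = 0.5)
  co <- simulate_cohort(scn)
  for (i in seq_len(20)) co$histories[[i]]$covariates <- list(z = i %% 3)
  ld <- build_landmark_dataset(co$histories, c(0, 0.3), window = 1,
                               k_max = 2, terminal = "present")
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_dataset(ld, path)
  back <- read_landmark_dataset(path)
  expect_equal(back$window, ld$window)
  expect_equal(back$k_max, ld$k_max)
  expect_equal(back$terminal, ld$terminal)
  expect_equal(back$landmarks, ld$landmarks)
  for (m in seq_along(ld$risksets)) {
    a <- ld$risksets[[m]]; b <- back$risksets[[m]]
    expect_equal(b$id, a$id)
    expect_equal(b$prior_events, a$prior_events)
    expect_equal(b$post_times, a$post_times)
    expect_equal(b$end_time, a$end_time)
    expect_equal(b$end_type, a$end_type)
    expect_equal(b$covariates$z, a$covariates$z)
  }
})

test_that("degenerate landmark grids are rejected", {
  hs <- fixture_histories()
  expect_error(build_landmark_dataset(hs, numeric(0), window = 1),
               "empty")
  expect_error(build_landmark_dataset(hs, c(1, 0.5), window = 1),
               "increasing")
  expect_error(build_landmark_dataset(hs, 0, window = -1), "positive")
  # beyond every endpoint: fewer than 2 at risk
  expect_error(build_landmark_dataset(hs, 10, window = 1),
               "jackknife undefined")
})
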