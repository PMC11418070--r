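test_that("ANOVA decomposition matches hand cases and the brute-force oracle", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]: perfectly additive
  d <- anova_decompose(m)
  expect_equal(d$ms_error, 0)
  expect_equal(d$ss_rows, 4)
  expect_equal(d$ss_cols, 1)
  expect_equal(d$ss_total, 5)

  # identical columns: no rater effect
  m2 <- cbind(c(10, 40, 70), c(10, 40, 70))
  expect_equal(anova_decompose(m2)$ms_cols, 0)

  set.seed(21)
  for (i in 1:25) {
    m3 <- matrix(runif(18, 0, 100), 6, 3)
    d3 <- anova_decompose(m3)
    o <- naive_anova(m3)
    expect_equal(d3$ms_rows, o$ms_rows, tolerance = 1e-9)
    expect_equal(d3$ms_cols, o$ms_cols, tolerance = 1e-9)
    expect_equal(d3$ms_error, o$ms_error, tolerance = 1e-9)
    # partition identity
    expect_equal(d3$ss_rows + d3$ss_cols + d3$ss_error, d3$ss_total,
                 tolerance = 1e-6 * d3$ss_total)
  }
  expect_error(anova_decompose(matrix(1:2, 1, 2)), "at least 2")
  expect_error(anova_decompose(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("ANOVA mean squares agree with the linear-model fit", {
  set.seed(33)
  m <- matrix(rnorm(40, 50, 15), 10, 4)
  d <- anova_decompose(m)
  df <- data.frame(y = as.vector(m),
                   row = factor(rep(1:10, 4)),
                   col = factor(rep(1:4, each = 10)))
  tab <- anova(lm(y ~ row + col, data = df))
  expect_equal(d$ms_rows, tab["row", "Mean Sq"], tolerance = 1e-9)
  expect_equal(d$ms_cols, tab["col", "Mean Sq"], tolerance = 1e-9)
  expect_equal(d$ms_error, tab["Residuals", "Mean Sq"], tolerance = 1e-9)
})

test_that("ICC boundary values: perfect agreement and no item signal", {
  m <- cbind(c(10, 40, 70, 90), c(10, 40, 70, 90))
  expect_equal(icc(m, "ICC2_1"), 1)
  expect_equal(icc(m, "ICC3_1"), 1)
  # msr == mse and msc == mse gives a zero numerator
  d <- structure(list(ms_rows = 2, ms_cols = 2, ms_error = 2,
                      ss_rows = 2, ss_cols = 2, ss_error = 2, ss_total = 6,
                      n = 2, k = 2), class = "awrat_anova")
  expect_equal(icc(d, "ICC2_1"), 0)
  # constant matrix: degenerate denominator
  expect_error(icc(matrix(5, 3, 2)), "degenerate")
})

test_that("ICC simulation recovers the variance-component ratio", {
  # item sigma^2 400, rater sigma^2 25, error sigma^2 25 => ICC 400/450
  set.seed(55)
  n <- 500; k <- 3; reps <- 200
  est <- replicate(reps, {
    mu <- rnorm(n, 0, 20)
    b <- rnorm(k, 0, 5)
    m <- outer(mu, rep(1, k)) + outer(rep(1, n), b) +
      matrix(rnorm(n * k, 0, 5), n, k)
    icc(m, "ICC2_1")
  })
  expect_lt(abs(mean(est) - 400 / 450), 0.03)
})

test_that("ICC is invariant to shift and positive scaling; ICC3 >= ICC2 with rater bias", {
  set.seed(66)
  for (i in 1:25) {
    m <- outer(rnorm(12, 50, 15), rep(1, 3)) + matrix(rnorm(36, 0, 8), 12, 3)
    for (form in c("ICC2_1", "ICC3_1", "ICC1_1")) {
      v <- icc(m, form)
      expect_equal(icc(m + 7.3, form), v, tolerance = 1e-9)
      expect_equal(icc(m * 2.5, form), v, tolerance = 1e-9)
    }
    d <- anova_decompose(m)
    if (d$ms_cols >= d$ms_error)
      expect_gte(icc(d, "ICC3_1"), icc(d, "ICC2_1") - 1e-12)
  }
})

test_that("pair_sessions drops incomplete items, routes singles, enforces the gap", {
  obs <- simulate_observations(n_items = 10, n_observers = 5,
                               p_second_session = 1, seed = 3)
  # observer 5 only did one session
  obs <- obs[!(obs$observer_code == "OBS005" & obs$session == 2), ]
  # observer 1 missing 3 items in session 2
  drop <- obs$observer_code == "OBS001" & obs$session == 2 &
    obs$item_id %in% c("item001", "item002", "item003")
  obs$rating[drop] <- NA
  p <- pair_sessions(obs)
  expect_setequal(names(p$paired), c("OBS001", "OBS002", "OBS003", "OBS004"))
  expect_equal(nrow(p$paired$OBS001), 7)
  expect_equal(nrow(p$paired$OBS002), 10)
  expect_equal(p$unpaired, "OBS005")

  # timestamps closer than the minimum gap reject the pair
  obs$timestamp <- as.Date(ifelse(obs$session == 1, "2023-03-01",
                                  "2023-03-05"))
  p2 <- pair_sessions(obs, min_gap_days = 10)
  expect_length(p2$paired, 0)
  expect_setequal(p2$rejected_gap, c("OBS001", "OBS002", "OBS003", "OBS004"))

  # a third session is ambiguous
  extra <- obs[obs$observer_code == "OBS002" & obs$session == 1, ]
  extra$session <- 3
  expect_error(pair_sessions(rbind(obs, extra)), "more than two sessions")
})

test_that("intra-observer report summarises the threshold proportion", {
  set.seed(77)
  # identical re-ratings: every observer at ICC 1
  obs <- simulate_observations(n_items = 12, n_observers = 6,
                               sigma_session = 0, sigma_error = 0,
                               sigma_observer = 5, seed = 8)
  rep1 <- intra_observer_report(pair_sessions(obs)$paired)
  expect_equal(rep1$prop_ge_threshold, 1)
  expect_true(all(abs(rep1$table$icc - 1) < 1e-9))

  # one observer whose retest is pure noise (no item signal) falls below
  paired <- pair_sessions(obs)$paired
  paired$OBS001 <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  rep2 <- intra_observer_report(paired, threshold = 0.8)
  expect_equal(rep2$n_ge_threshold, 5)
  expect_equal(rep2$prop_ge_threshold, 5 / 6)
  expect_lt(rep2$icc_range[1], 0.8)
})

test_that("session-noise-only cohorts reach the predicted test-retest ICC", {
  # sigma_item 30 vs retest noise 5: expected about 900/925
  obs <- simulate_observations(n_items = 40, n_observers = 23,
                               sigma_item = 30, sigma_observer = 5,
                               sigma_session = 5, sigma_error = 0,
                               seed = 12)
  rep <- intra_observer_report(pair_sessions(obs)$paired)
  expect_equal(rep$n_observers, 23)
  expect_equal(rep$prop_ge_threshold, 1)
  expect_lt(abs(mean(rep$table$icc) - 900 / 925), 0.05)
})

test_that("inter-observer ICC uses first sessions and drops incomplete observers", {
  obs <- simulate_observations(n_items = 15, n_observers = 31,
                               sigma_observer = 0, sigma_session = 0,
                               sigma_error = 0, seed = 5)
  # two observers with a missing first-session value are excluded
  for (oc in c("OBS003", "OBS009")) {
    i <- which(obs$observer_code == oc & obs$session == 1)[1]
    obs$rating[i] <- NA
  }
  res <- inter_observer_icc(obs)
  expect_equal(res$n_observers, 29)
  expect_setequal(res$observers_dropped, c("OBS003", "OBS009"))
  expect_equal(res$icc, 1)  # no rater or residual noise: perfect agreement

  one <- obs[obs$observer_code == "OBS001", ]
  expect_error(inter_observer_icc(one), "insufficient data")
})

test_that("inter-observer ICC approaches the variance ratio at scale", {
  # item 200, rater bias 100, error 100 => absolute-agreement ICC 0.5
  obs <- simulate_observations(n_items = 400, n_observers = 20,
                               sigma_item = sqrt(200), sigma_observer = 10,
                               sigma_session = 0, sigma_error = 10,
                               item_mean = 50, p_second_session = 0, seed = 99)
  res <- inter_observer_icc(obs)
  expect_lt(abs(res$icc - 0.5), 0.08)
})
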