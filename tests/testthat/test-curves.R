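test_that("Kaplan-Meier estimate handles events, censoring and ties", {
  # no censoring: empirical survival
  km <- fit_km(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$jump_times, c(1, 2, 3))
  expect_equal(km$values, c(2 / 3, 1 / 3, 0))
  expect_equal(eval_km(km, c(0.5, 1, 2.5, 10)), c(1, 2 / 3, 1 / 3, 0))

  # single censored record: flat at 1
  km <- fit_km(5, 0)
  expect_length(km$jump_times, 0)
  expect_equal(eval_km(km, c(0, 5, 100)), rep(1, 3))

  # censoring between events: product-limit 2/3 * (1 - 1/1) = 0
  km <- fit_km(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$jump_times, c(1, 3))
  expect_equal(km$values, c(2 / 3, 0))

  expect_error(fit_km(numeric(0), numeric(0)), "no subjects")
  expect_error(fit_km(c(-1, 2), c(1, 1)), "negative")
})

test_that("risk-set mean utility curve follows the at-risk population", {
  # two subjects alive through T with constant utilities: flat mean
  d <- make_data(c(36, 36), c(0, 0), c(0.4, 0.8), horizon = 36)
  tr <- impute_utilities(d)
  u <- mean_utility_curve(d, 1, tr)
  expect_equal(eval_pw(u, c(0, 10, 36)), rep(0.6, 3))

  # departure at 10 removes a subject from the average afterwards
  d <- make_data(c(10, 36), c(1, 0), c(0.2, 0.8), horizon = 36)
  tr <- impute_utilities(d)
  u <- mean_utility_curve(d, 1, tr)
  expect_equal(eval_pw(u, c(0, 5, 10)), rep(0.5, 3))  # boundary inclusive
  expect_equal(eval_pw(u, c(10.5, 36)), rep(0.8, 2))

  expect_error(mean_utility_curve(d, 2, tr[0, ]), "missing trajectories")
})

test_that("q_statistic integrates weighted survival-utility products exactly", {
  km1 <- fit_km(rep(36, 4), rep(0, 4))
  flat <- data.frame(time = c(0, 36), value = 0.5)
  expect_equal(q_statistic(km1, flat, 1, 1, 36), 18)

  # lambda2 = 2 with a linear ramp: integral of (t/36)^2 over [0,36] = 12
  ramp <- data.frame(time = c(0, 36), value = c(0, 1))
  expect_equal(q_statistic(km1, ramp, 1, 2, 36), 12)

  # lambda2 = 0 reduces to restricted mean survival time
  tm <- c(3, 9, 14, 20, 36, 36); ev <- c(1, 0, 1, 1, 0, 0)
  km <- fit_km(tm, ev)
  expect_equal(q_statistic(km, flat, 1, 0, 36), rmst_oracle(tm, ev, 36))

  # negative utility is rejected for fractional lambda2, named segment
  neg <- data.frame(time = c(0, 36), value = c(-0.2, -0.2))
  expect_error(q_statistic(km1, neg, 1, 0.5, 36), "negative utility")
  expect_silent(q_statistic(km1, neg, 1, 2, 36))
})

test_that("q_statistic with lambda2 = 0 matches the RMST oracle on random data", {
  set.seed(41)
  flat <- data.frame(time = c(0, 24), value = 1)
  for (i in 1:300) {
    tm <- pmin(rexp(12, 0.1), 24)
    ev <- as.integer(tm < 24 & runif(12) < 0.8)
    q <- q_statistic(fit_km(tm, ev), flat, 1, 0, 24)
    expect_equal(q, rmst_oracle(tm, ev, 24), tolerance = 1e-10)
  }
})

test_that("exact segment integration agrees with a fine-grid trapezoid oracle", {
  set.seed(7)
  for (i in 1:8) {
    d <- random_small_data(10, horizon = 24)
    tr <- impute_utilities(d)
    km <- fit_km(d$subjects$time[d$subjects$arm == 1],
                 d$subjects$event[d$subjects$arm == 1])
    u <- mean_utility_curve(d, 1, tr)
    for (lam in list(c(1, 1), c(1, 2), c(2, 0.5), c(0, 1))) {
      expect_equal(q_statistic(km, u, lam[1], lam[2], 24),
                   trapezoid_oracle(km, u, lam[1], lam[2], 24),
                   tolerance = 1e-6)
    }
  }
})

test_that("Q scales linearly in utility and reduces to the time-average without deaths", {
  d <- make_data(c(20, 20, 20), c(0, 0, 0), c(0.3, 0.5, 0.7), horizon = 20)
  tr <- impute_utilities(d)
  km <- fit_km(d$subjects$time[d$subjects$arm == 1], rep(0, 3))
  u <- mean_utility_curve(d, 1, tr)
  q <- q_statistic(km, u, 1, 1, 20)
  # no deaths, lambda1 irrelevant: Q = integral of Ubar = 0.5 * 20
  expect_equal(q, 10)
  expect_equal(q_statistic(km, u, 0, 1, 20), q)
  # multiplying utilities by c > 1 multiplies Q by c (lambda2 = 1)
  d2 <- make_data(c(20, 20, 20), c(0, 0, 0), 1.3 * c(0.3, 0.5, 0.7),
                  horizon = 20)
  u2 <- mean_utility_curve(d2, 1, impute_utilities(d2))
  expect_equal(q_statistic(km, u2, 1, 1, 20), 1.3 * q)
})

test_that("T statistic is antisymmetric and zero for mirrored arms", {
  d <- make_data(c(36, 20), c(0, 1), c(0.8, 0.6), horizon = 36)
  expect_equal(t_statistic(d)$T, 0)

  # 4-subject worked example: constant utilities 0.8 vs 0.4, all alive to 10
  d <- make_data(c(10, 10), c(0, 0), c(0.8, 0.8),
                 c(10, 10), c(0, 0), c(0.4, 0.4), horizon = 10)
  tt <- t_statistic(d)
  expect_equal(tt$Q1, 8)
  expect_equal(tt$Q2, 4)
  expect_equal(tt$T, 4)

  set.seed(9)
  for (i in 1:20) {
    d <- random_small_data(7, horizon = 24)
    swapped <- d
    swapped$subjects$arm <- 3 - swapped$subjects$arm
    expect_equal(t_statistic(swapped)$T, -t_statistic(d)$T,
                 tolerance = 1e-12)
  }
})

test_that("engine and R curve composition agree on generated trials", {
  sc <- scenario_preset("scenario1")
  for (s in 1:6) {
    d <- generate_trial(sc, n1 = 25, n2 = 25, seed = s)
    tt <- t_statistic(d)
    tr <- impute_utilities(d)
    q <- vapply(1:2, function(g) {
      sg <- d$subjects[d$subjects$arm == g, ]
      q_statistic(fit_km(sg$time, sg$event),
                  mean_utility_curve(d, g, tr), 1, 1, d$horizon)
    }, numeric(1))
    expect_equal(tt$Q1, q[1], tolerance = 1e-10)
    expect_equal(tt$Q2, q[2], tolerance = 1e-10)
  }
})

test_that("dataset validation rejects malformed input", {
  subj <- data.frame(id = 1:2, arm = c(1, 2), time = c(10, 12),
                     event = c(1, 0))
  util <- data.frame(id = 1:2, time = c(0, 0), score = c(0.5, 0.6))
  expect_s3_class(hus_data(subj, util, horizon = 12), "hus_data")
  bad <- util; bad$time[1] <- 11  # after subject 1's follow-up
  expect_error(hus_data(subj, bad, horizon = 12), "after follow-up")
  expect_error(hus_data(subj, util, horizon = 5), "exceed")
  expect_error(hus_data(subj[c(1, 1), ], util, horizon = 12), "duplicate")
  bad <- util; bad$id[2] <- 99
  expect_error(hus_data(subj, bad, horizon = 12), "unknown subject")
})

test_that("datasets round-trip through CSV", {
  d <- generate_trial(scenario_preset("scenario0"), n1 = 12, n2 = 12,
                      seed = 5)
  pre <- file.path(tempdir(), "hustest")
  write_hus_data(d, pre)
  d2 <- read_hus_data(paste0(pre, "_subjects.csv"),
                      paste0(pre, "_utilities.csv"), horizon = 36,
                      surgery_time = 3)
  expect_equal(d2$subjects, d$subjects, tolerance = 1e-12)
  expect_equal(d2$utilities, d$utilities, tolerance = 1e-12)
  expect_equal(t_statistic(d2)$T, t_statistic(d)$T, tolerance = 1e-12)
})
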