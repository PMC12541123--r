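test_that("censoring calibration: closed forms and Monte-Carlo checks", {
  # no dropout
  expect_identical(calibrate_censoring(0.02, 36, 0), Inf)
  # dropout-before-horizon reading has the closed form I_T / p above T
  z <- calibrate_censoring(0.02, 36, 0.30, type = "dropout")
  expect_equal(z, (1 - exp(-0.02 * 36)) / 0.02 / 0.30, tolerance = 1e-9)
  expect_equal(z, 85.54, tolerance = 1e-3)
  # latent reading solves (1 - exp(-h z)) / (h z) = p
  zl <- calibrate_censoring(0.02, 36, 0.30, type = "latent")
  expect_equal((1 - exp(-0.02 * zl)) / (0.02 * zl), 0.30, tolerance = 1e-9)
  # total reading is infeasible below the administrative floor
  expect_error(calibrate_censoring(0.02, 36, 0.30, type = "total"),
               "not attainable")
  zt <- calibrate_censoring(0.02, 36, 0.60, type = "total")

  # Monte-Carlo: each reading hits its target rate
  set.seed(61)
  Ti <- rexp(2e5, 0.02)
  for (case in list(list(z = z, rate = function(xi)
                      mean(xi < Ti & xi < 36)),
                    list(z = zl, rate = function(xi) mean(xi < Ti)),
                    list(z = zt, rate = function(xi)
                      1 - mean(Ti < xi & Ti < 36)))) {
    xi <- runif(2e5, 0, case$z)
    target <- if (identical(case$z, zt)) 0.60 else 0.30
    expect_lt(abs(case$rate(xi) - target), 3 * sqrt(0.3 * 0.7 / 2e5) + 1e-3)
  }
})

test_that("hazard-ratio recovery from survival proportions", {
  expect_equal(hr_from_os_rates(0.849, 0.815), 0.80, tolerance = 0.005)
  expect_equal(hr_from_os_rates(0.7, 0.7), 1)
  expect_equal(hr_from_os_rates(0.25, 0.5), 2)
  expect_error(hr_from_os_rates(1.2, 0.5))
})

test_that("scenario presets carry the published parameterisation", {
  s1 <- scenario_preset("scenario1")
  expect_equal(s1$utility_knots[[1]], c(0.8, 0.5, 0.8))
  expect_equal(s1$utility_knots[[2]], c(0.8, 0.35, 0.7))
  expect_equal(s1$knot_times, c(0, 3, 36))
  expect_equal(s1$visits, c(1, 3, 36))
  expect_equal(s1$p_censoring, 0.30)
  s2 <- scenario_preset("scenario2")
  expect_equal(s2$p_censoring, 0.60)
  expect_equal(s2$p_missing, 0.60)
  expect_equal(s2$utility_knots[[2]], c(0.8, 0.4, 0.7))
  s0 <- scenario_preset("scenario0")
  expect_identical(s0$utility_knots[[1]], s0$utility_knots[[2]])
  pn <- scenario_preset("petneck_like")
  expect_equal(pn$hazard[1], -log(0.849) / 24)
  expect_equal(pn$hazard[1] / pn$hazard[2], 0.80, tolerance = 0.001)
  expect_equal(pn$horizon, 24)
  expect_null(pn$utility_knots)
  expect_error(generate_trial(pn, seed = 1), "utility knots")
  expect_error(scenario_preset("nope"))
})

test_that("the generator reproduces its data-generating mechanism", {
  sc <- scenario_preset("scenario1")
  # same seed, same dataset; different seed differs
  a <- generate_trial(sc, n1 = 30, n2 = 30, seed = 9)
  b <- generate_trial(sc, n1 = 30, n2 = 30, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_trial(sc, n1 = 30, n2 = 30, seed = 10)))

  # degenerate limit: no censoring, no missingness, hazard ~ 0
  s <- hus_scenario(hazard = c(1e-9, 1e-9),
                    utility_knots = sc$utility_knots,
                    p_censoring = 0, p_missing = 0)
  d <- generate_trial(s, n1 = 25, n2 = 25, seed = 4)
  expect_true(all(d$subjects$time == 36))
  expect_true(all(d$subjects$event == 0))
  expect_equal(nrow(d$utilities), 50 * 3)  # every subject, every visit

  # empirical KM of a big arm tracks exp(-h t) closely
  big <- hussurv:::generate_arm_matrices(sc, 1e5, 2, seed = 5)[[1]]
  km <- fit_km(big$time, big$event)
  grid <- seq(0.5, 35.5, by = 0.5)
  expect_lt(max(abs(eval_km(km, grid) - exp(-0.02 * grid))), 0.005)

  # utility scores: mean U0(t), sd 0.1, first visit never missing
  U <- big$U
  expect_false(anyNA(U[big$time >= 1, 1]))
  for (k in 1:3) {
    v <- sc$visits[k]
    x <- U[!is.na(U[, k]), k]
    u0 <- hussurv:::base_utility_scenario(sc, 1, v)
    expect_lt(abs(mean(x) - u0), 3 * 0.1 / sqrt(length(x)))
    expect_lt(abs(sd(x) - 0.1), 3 * 0.1 / sqrt(2 * length(x)))
  }
  # later-visit missingness among eligible subjects is ~ p_missing
  elig <- big$time >= 3
  miss_frac <- mean(is.na(U[elig, 2]))
  expect_lt(abs(miss_frac - 0.30), 3 * sqrt(0.3 * 0.7 / sum(elig)))
})

test_that("random streams are independent per mechanism", {
  sc <- scenario_preset("scenario1")
  a <- generate_trial(sc, n1 = 50, n2 = 50, seed = 12)
  # switching missingness off must not change survival or censoring draws
  s2 <- sc; s2$p_missing <- 0
  b <- generate_trial(s2, n1 = 50, n2 = 50, seed = 12)
  expect_identical(a$subjects, b$subjects)
  # recorded scores agree wherever both have them
  key <- function(d) paste(d$utilities$id, d$utilities$time)
  common <- intersect(key(a), key(b))
  expect_equal(a$utilities$score[match(common, key(a))],
               b$utilities$score[match(common, key(b))])
  expect_gt(nrow(b$utilities), nrow(a$utilities))
})
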