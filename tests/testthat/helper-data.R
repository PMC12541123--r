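# small builders and independent oracles used across the suite

make_data <- function(time1, event1, u1, time2 = time1, event2 = event1,
                      u2 = u1, horizon = max(c(time1, time2)),
                      surgery_time = NULL) {
  n1 <- length(time1); n2 <- length(time2)
  subj <- data.frame(id = seq_len(n1 + n2),
                     arm = rep(c(1, 2), c(n1, n2)),
                     time = c(time1, time2), event = c(event1, event2))
  stopifnot(length(u1) == n1, length(u2) == n2)
  util <- data.frame(id = subj$id, time = 0, score = c(u1, u2))
  hus_data(subj, util, horizon = horizon, surgery_time = surgery_time)
}

# random small dataset: constant per-subject utilities recorded at baseline
random_small_data <- function(n_per_arm = 8, horizon = 24) {
  tm <- pmin(rexp(2 * n_per_arm, 0.08), horizon)
  ev <- as.integer(tm < horizon & runif(2 * n_per_arm) < 0.7)
  subj <- data.frame(id = seq_len(2 * n_per_arm),
                     arm = rep(c(1, 2), each = n_per_arm),
                     time = tm, event = ev)
  util <- data.frame(id = subj$id, time = 0,
                     score = runif(2 * n_per_arm, 0.2, 0.9))
  hus_data(subj, util, horizon = horizon)
}

# restricted mean survival time oracle via survival::survfit
rmst_oracle <- function(time, event, horizon) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, rmean = horizon)
  unname(s$table["rmean"])
}

# fine-grid trapezoid integral of S(t)^l1 * Ubar(t)^l2 using the package's
# own curve evaluators but an independent integration rule
trapezoid_oracle <- function(km, util, lambda1, lambda2, horizon,
                             step = 1e-3) {
  g <- sort(unique(c(seq(0, horizon, by = step), horizon,
                     km$jump_times[km$jump_times < horizon],
                     util$t0[util$t0 < horizon], util$t1[util$t1 < horizon])))
  g <- g[g >= 0]
  mid <- (g[-1] + g[-length(g)]) / 2
  S <- eval_km(km, mid)
  u <- eval_pw(util, mid)
  sum(ifelse(S > 0, S^lambda1 * u^lambda2, 0) * diff(g))
}

random_theory_params <- function() {
  horizon <- runif(1, 10, 60)
  surgery <- runif(1, 0.05, 0.9) * horizon
  theory_params(surgery, horizon,
                hazards = runif(2, 0.002, 0.08),
                utility_knots = runif(3, 0.1, 1))
}
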