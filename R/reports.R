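#' Rejection-rate table for a scenario
#'
#' Simulates `reps` trials under a scenario at each requested arm size and
#' tabulates the rejection fraction of: the analytic (theoretical) HUS rule,
#' the bootstrap HUS test at one or more utility weights, the one-sided
#' log-rank superiority test, and hazard-ratio non-inferiority at one or more
#' margins. Each cell carries its Monte-Carlo standard error and full
#' provenance (seed, replications, `B`).
#'
#' @param scenario a [hus_scenario()].
#' @param n vector of per-arm sample sizes.
#' @param reps simulated trials per cell.
#' @param B bootstrap resamples per trial.
#' @param alpha one-sided level.
#' @param lambda2 utility weights for the bootstrap columns.
#' @param margins non-inferiority margins (set `NULL` to skip).
#' @param methods subset of
#'   `c("theoretical", "bootstrap", "logrank", "noninferiority")`.
#' @param phi a precomputed [estimate_phi()] for the theoretical column;
#'   estimated once (at `n = 200`, `phi_reps` replications) when needed and
#'   not supplied.
#' @param phi_reps replications for the internal phi estimate.
#' @param seed master seed; per-replication seeds are derived from it so the
#'   table is reproducible and independent of execution order.
#' @param out optional path prefix; writes `<out>.csv` and `<out>.json`.
#' @return data.frame with columns `n`, `method`, `setting`, `rate`, `mc_se`,
#'   `reps`, plus provenance attributes.
#' @export
run_rejection_table <- function(scenario, n, reps = 1000, B = 500,
                                alpha = 0.05, lambda2 = 1,
                                margins = c(0.05, 0.10),
                                methods = c("theoretical", "bootstrap",
                                            "logrank", "noninferiority"),
                                phi = NULL, phi_reps = 4000, seed = 1,
                                out = NULL) {
  stopifnot(inherits(scenario, "hus_scenario"), reps >= 1, length(n) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(margins)) methods <- setdiff(methods, "noninferiority")
  if ("theoretical" %in% methods && is.null(phi))
    phi <- estimate_phi(scenario, n_per_arm = 200, reps = phi_reps,
                        seed = seed + 1L)
  rows <- list()
  for (nn in n) {
    cols <- list()
    if ("theoretical" %in% methods) cols[["theoretical"]] <- numeric(reps)
    for (l2 in if ("bootstrap" %in% methods) lambda2 else numeric(0))
      cols[[paste0("bootstrap_l2_", l2)]] <- numeric(reps)
    if ("logrank" %in% methods) cols[["logrank_sup"]] <- numeric(reps)
    for (m in if ("noninferiority" %in% methods) margins else numeric(0))
      cols[[paste0("noninf_", m)]] <- numeric(reps)
    vT <- if ("theoretical" %in% methods) var_T_at(phi, nn, nn) else NA
    for (r in seq_len(reps)) {
      rseed <- (seed + 7919 * nn + r) %% .Machine$integer.max
      d <- generate_trial(scenario, n1 = nn, n2 = nn, seed = rseed)
      if ("theoretical" %in% methods) {
        tt <- t_statistic(d)
        cols[["theoretical"]][r] <- analytic_decision(tt$T, vT, alpha)
      }
      if ("bootstrap" %in% methods)
        for (l2 in lambda2)
          cols[[paste0("bootstrap_l2_", l2)]][r] <-
            hus_test(d, "bootstrap", lambda2 = l2, B = B, alpha = alpha,
                     seed = rseed + 1L)$reject
      if ("logrank" %in% methods)
        cols[["logrank_sup"]][r] <- logrank_superiority(d, alpha)$reject
      if ("noninferiority" %in% methods)
        for (m in margins)
          cols[[paste0("noninf_", m)]][r] <- hr_noninferiority(d, m)$reject
    }
    for (nm in names(cols)) {
      rate <- mean(cols[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        n = nn, method = nm, rate = rate,
        mc_se = sqrt(rate * (1 - rate) / reps), reps = reps)
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "provenance") <- list(
    scenario = scenario$name, seed = seed, B = B, alpha = alpha,
    package_version = as.character(utils::packageVersion("hussurv")))
  if (!is.null(out)) write_report(tab, out)
  tab
}

#' Analytic power curve over a sample-size grid
#'
#' @param phi a [estimate_phi()] result.
#' @param n_grid per-arm sample sizes.
#' @param alpha one-sided level.
#' @return data.frame `n, power`.
#' @export
run_power_curve <- function(phi, n_grid, alpha = 0.05) {
  stopifnot(inherits(phi, "phi_estimate"))
  data.frame(n = n_grid,
             power = vapply(n_grid, function(nn)
               hus_power(phi, nn, alpha = alpha)$power, numeric(1)))
}

# analytic per-arm event probability before the horizon under dropout
# censoring Unif(0, zeta)
event_prob_exp <- function(h, horizon, zeta) {
  if (!is.finite(zeta)) return(1 - exp(-h * horizon))
  up <- min(zeta, horizon)
  # P(T < min(xi, horizon)) with xi ~ U(0, zeta)
  integrate(function(t) h * exp(-h * t) * (1 - t / zeta), 0, up,
            rel.tol = 1e-10)$value
}

# approximate one-sided log-rank sample size per arm (Schoenfeld events
# formula under exponential survival and 1:1 allocation); labelled
# approximate wherever reported
logrank_n_approx <- function(h1, h2, horizon, p_censoring, power,
                             alpha = 0.05) {
  if (h1 == h2) return(NA_real_)
  d <- 4 * (qnorm(1 - alpha) + qnorm(power))^2 / log(h1 / h2)^2
  pe <- vapply(c(h1, h2), function(h)
    event_prob_exp(h, horizon,
                   calibrate_censoring(h, horizon, p_censoring)),
    numeric(1))
  ceiling(d / sum(pe))
}

#' Sample-size table across survival-difference cases
#'
#' For each hazard-ratio case (`h1 = ratio * h2`, keeping `h2` at the
#' scenario's arm-2 hazard), re-estimates the variance balance factors and
#' `T_true`, and tabulates the per-arm HUS sample size for each target power
#' next to an approximate overall-survival sample size from the exponential
#' one-sided log-rank events formula (reported as `NA` when the arms have
#' equal hazards, i.e. no OS power). The OS column is approximate by
#' construction and not comparable digit-for-digit with specialised
#' commercial software.
#'
#' @param scenario the base [hus_scenario()] (its utility knots are kept).
#' @param hazard_ratios vector of `h1/h2` cases.
#' @param powers target powers.
#' @param alpha one-sided level.
#' @param phi_n,phi_reps calibration-trial size and replications for each
#'   case's [estimate_phi()].
#' @param seed master seed.
#' @param out optional path prefix for CSV/JSON output.
#' @return data.frame `hazard_ratio, power, n_hus, n_os_approx, T_true`.
#' @export
run_samplesize_table <- function(scenario, hazard_ratios = 1,
                                 powers = c(0.7, 0.8, 0.9), alpha = 0.05,
                                 phi_n = 200, phi_reps = 4000, seed = 1,
                                 out = NULL) {
  stopifnot(inherits(scenario, "hus_scenario"))
  rows <- list()
  for (hr in hazard_ratios) {
    sc <- scenario
    sc$hazard <- c(hr * scenario$hazard[2], scenario$hazard[2])
    ph <- estimate_phi(sc, n_per_arm = phi_n, reps = phi_reps,
                       seed = (seed + round(1000 * hr)) %% .Machine$integer.max)
    for (w in powers) {
      n_hus <- if (ph$T_true > 0) hus_sample_size(ph, w, alpha)$n else NA
      n_os <- logrank_n_approx(sc$hazard[1], sc$hazard[2], sc$horizon,
                               sc$p_censoring, w, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        hazard_ratio = hr, power = w, n_hus = n_hus, n_os_approx = n_os,
        T_true = ph$T_true)
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "provenance") <- list(
    scenario = scenario$name, seed = seed, phi_n = phi_n,
    phi_reps = phi_reps, alpha = alpha,
    package_version = as.character(utils::packageVersion("hussurv")))
  if (!is.null(out)) write_report(tab, out)
  tab
}

write_report <- function(tab, out) {
  write.csv(tab, paste0(out, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(table = tab, provenance = attr(tab, "provenance")),
    paste0(out, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out)
}
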