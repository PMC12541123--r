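#' Analytic group parameters: piecewise-exponential survival, 3-knot utility
#'
#' Describes one treatment arm in the analytic framework used for power and
#' sample-size calculation: survival time with piecewise-constant hazards
#' `h1` on `[0, C]` and `h2` on `(C, T]`, and a piecewise-linear base utility
#' running from `A1` at baseline through `A2` at the surgery time `C` to `A3`
#' at the study horizon `T`.
#'
#' @param surgery_time landmark time `C` in months, `0 < C < T`.
#' @param horizon study horizon `T` in months.
#' @param hazards per-month hazards: length 1 (constant hazard, the common
#'   single-exponential case) or length 2 (`h1` on `[0, C]`, `h2` after).
#' @param utility_knots base utility values `c(A1, A2, A3)` at times
#'   `0, C, T`.
#' @return An object of class `theory_params`.
#' @export
theory_params <- function(surgery_time, horizon, hazards, utility_knots) {
  stopifnot(length(surgery_time) == 1, length(horizon) == 1,
            surgery_time > 0, horizon > surgery_time,
            length(hazards) %in% c(1, 2), all(hazards >= 0),
            length(utility_knots) == 3, all(is.finite(utility_knots)))
  if (length(hazards) == 1) hazards <- rep(hazards, 2)
  structure(list(C = surgery_time, T = horizon,
                 h1 = hazards[1], h2 = hazards[2],
                 A = as.numeric(utility_knots)),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf(
    "analytic arm: C = %g, T = %g, hazards (%g, %g)/month, utility %g -> %g -> %g\n",
    x$C, x$T, x$h1, x$h2, x$A[1], x$A[2], x$A[3]))
  invisible(x)
}

# survival, density and base utility implied by theory_params
surv_theory <- function(t, p)
  exp(-p$h1 * pmin(t, p$C) - p$h2 * pmax(t - p$C, 0))

dens_theory <- function(t, p)
  ifelse(t <= p$C, p$h1, p$h2) * surv_theory(t, p)

#' Base utility function of an analytic arm
#' @param t times in `[0, T]`.
#' @param params a [theory_params()] object.
#' @return `U0(t)`, linear from `A1` to `A2` on `[0, C]` and from `A2` to
#'   `A3` on `[C, T]`.
#' @export
base_utility <- function(t, params) {
  p <- params
  ifelse(t <= p$C,
         p$A[1] + (p$A[2] - p$A[1]) / p$C * t,
         (p$T * p$A[2] - p$C * p$A[3]) / (p$T - p$C) +
           (p$A[3] - p$A[2]) / (p$T - p$C) * t)
}

#' The X* transform of a survival time
#'
#' The scalar transform whose expectation under the piecewise-exponential
#' survival model equals \eqn{M = \int_0^T S(t) U_0(t) dt}, the mean
#' utility-adjusted survival of the arm. Writing `X = min(xi, T) = X1 + X2`
#' with `X1 = min(X, C)` and `X2 = max(X - C, 0)`,
#' \deqn{X^* = A_1 X_1 + \frac{T A_2 - C A_3}{T - C} X_2
#'       + \frac{A_2 - A_1}{2C} X_1^2
#'       + \frac{A_3 - A_2}{2(T - C)} X_2^2
#'       + \frac{A_3 - A_2}{T - C} X_1 X_2.}
#'
#' @param xi survival time(s), `>= 0` (not truncated; truncation at `T` is
#'   internal).
#' @param params a [theory_params()] object.
#' @return `X*` evaluated at each `xi`.
#' @export
xstar_value <- function(xi, params) {
  p <- params
  stopifnot(all(xi >= 0))
  x <- pmin(xi, p$T)
  X1 <- pmin(x, p$C)
  X2 <- pmax(x - p$C, 0)
  A <- p$A; TC <- p$T - p$C
  A[1] * X1 + (p$T * A[2] - p$C * A[3]) / TC * X2 +
    (A[2] - A[1]) / (2 * p$C) * X1^2 +
    (A[3] - A[2]) / (2 * TC) * X2^2 +
    (A[3] - A[2]) / TC * X1 * X2
}

#' Moments of X* under the piecewise-exponential model
#'
#' `X*` is a deterministic transform of the scalar survival time, so its
#' mean and variance are one-dimensional integrals: adaptive quadrature of
#' `xstar_value(t)^k * f(t)` over `[0, C]` and `[C, T]` (the integrand has a
#' kink at `C`) plus the point mass `xstar_value(T)^k * S(T)` for survival
#' past the horizon.
#'
#' @param params a [theory_params()] object.
#' @param abs_tol absolute quadrature tolerance per piece.
#' @return An object of class `xstar_moments`: `M` (the mean, which equals
#'   `integral S(t) U0(t) dt`), `var_xstar`, `sd_xstar`.
#' @export
xstar_moments <- function(params, abs_tol = 1e-10) {
  p <- params
  mom <- function(k) {
    g <- function(t) xstar_value(t, p)^k * dens_theory(t, p)
    i1 <- integrate(g, 0, p$C, abs.tol = abs_tol, rel.tol = 1e-12,
                    subdivisions = 500L)
    i2 <- integrate(g, p$C, p$T, abs.tol = abs_tol, rel.tol = 1e-12,
                    subdivisions = 500L)
    if (i1$message != "OK" || i2$message != "OK")
      stop("quadrature failed: ", i1$message, " / ", i2$message)
    i1$value + i2$value + xstar_value(p$T, p)^k * surv_theory(p$T, p)
  }
  M <- mom(1)
  v <- mom(2) - M^2
  if (v < 0 && v > -1e-10) v <- 0
  structure(list(M = M, var_xstar = v, sd_xstar = sqrt(v)),
            class = "xstar_moments")
}

#' @export
print.xstar_moments <- function(x, ...) {
  cat(sprintf("X* moments: M = %.4f, var = %.4f, sd = %.4f\n",
              x$M, x$var_xstar, x$sd_xstar))
  invisible(x)
}

# map one arm of a simulation scenario onto theory_params (needs the 3-knot
# utility at times 0, C, T and a single exponential hazard per arm)
scenario_theory_params <- function(scenario, arm) {
  sc <- scenario
  if (is.null(sc$surgery_time))
    stop("scenario has no surgery time; analytic engine needs 3 knots at 0, C, T")
  kt <- sc$knot_times
  if (length(kt) != 3 || !isTRUE(all.equal(kt, c(0, sc$surgery_time, sc$horizon))))
    stop("analytic engine needs utility knots exactly at 0, C and T")
  theory_params(sc$surgery_time, sc$horizon, sc$hazard[arm],
                sc$utility_knots[[arm]])
}

#' Estimate variance balance factors and the true HUS difference
#'
#' The analytic standard error model is `SE(Q_g) = phi_g * SD(X*_g) / sqrt(n)`
#' where `phi_g >= 1` absorbs the extra variability that censoring, missing
#' utility scores, imputation and Kaplan-Meier estimation add on top of the
#' ideal `X*` sampling noise. `phi_g` and the true difference `T_true` are
#' estimated by simulating full trials under the scenario and computing the
#' per-arm Q statistics on each replicate.
#'
#' @param scenario a [hus_scenario()] (3 utility knots at 0, C, T; exponential
#'   survival per arm).
#' @param n_per_arm subjects per arm in the calibration trials (the factor is
#'   robust to this choice).
#' @param reps number of simulated trials; fewer than 100 triggers a warning.
#' @param seed optional integer seed.
#' @param imputation,add_noise utility imputation used when computing Q on the
#'   simulated trials (defaults match the package default pipeline).
#' @return An object of class `phi_estimate` with `phi1`, `phi2`, `T_true`,
#'   per-arm `var_xstar` and `M`, and the settings used.
#' @examples
#' \donttest{
#' ph <- estimate_phi(scenario_preset("scenario1"), n_per_arm = 200,
#'                    reps = 500, seed = 1)
#' ph
#' }
#' @export
estimate_phi <- function(scenario, n_per_arm = 200, reps = 4000, seed = NULL,
                         imputation = "group_mean_linear", add_noise = FALSE) {
  stopifnot(inherits(scenario, "hus_scenario"))
  if (reps < 100) warning("fewer than 100 replications: phi will be unstable")
  if (!is.null(seed)) set.seed(seed)
  tp <- lapply(1:2, scenario_theory_params, scenario = scenario)
  mom <- lapply(tp, xstar_moments)
  Q <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    trial <- generate_arm_matrices(scenario, n_per_arm, n_per_arm)
    for (g in 1:2) {
      a <- trial[[g]]
      Ui <- impute_matrix(a$U, a$time, a$visits, method = imputation,
                          add_noise = add_noise, warn = FALSE)
      Q[r, g] <- .hus_q_arm_cpp(a$time, a$event, Ui, a$visits,
                                scenario$horizon, 1, 1)
    }
  }
  phi <- vapply(1:2, function(g)
    sd(Q[, g]) * sqrt(n_per_arm) / mom[[g]]$sd_xstar, numeric(1))
  if (any(phi < 0.95))
    warning("estimated phi < 0.95; the SE model expects phi >= 1")
  structure(list(phi1 = phi[1], phi2 = phi[2],
                 T_true = mean(Q[, 1] - Q[, 2]),
                 var_xstar1 = mom[[1]]$var_xstar,
                 var_xstar2 = mom[[2]]$var_xstar,
                 M1 = mom[[1]]$M, M2 = mom[[2]]$M,
                 n_used = n_per_arm, reps = reps, seed = seed),
            class = "phi_estimate")
}

#' @export
print.phi_estimate <- function(x, ...) {
  cat(sprintf(
    "variance balance factors (n = %d per arm, %d replications):\n",
    x$n_used, x$reps))
  cat(sprintf("  phi1 = %.3f, phi2 = %.3f, T_true = %.3f\n",
              x$phi1, x$phi2, x$T_true))
  cat(sprintf("  var(X*): %.3f / %.3f;  M1 - M2 = %.3f\n",
              x$var_xstar1, x$var_xstar2, x$M1 - x$M2))
  invisible(x)
}

# phi-based var(T) at given arm sizes
var_T_at <- function(phi, n1, n2)
  phi$phi1^2 * phi$var_xstar1 / n1 + phi$phi2^2 * phi$var_xstar2 / n2

#' Analytic one-sided decision rule
#'
#' Rejects `H0: T <= 0` when `T - z_{1-alpha} * sqrt(var_T) > 0` (strict).
#'
#' @param t_obs observed HUS difference.
#' @param var_t variance of T, e.g. `phi1^2 var(X*1)/n1 + phi2^2 var(X*2)/n2`.
#' @param alpha one-sided level.
#' @return Logical: reject or not.
#' @export
analytic_decision <- function(t_obs, var_t, alpha = 0.05) {
  if (any(var_t <= 0)) stop("var_t must be positive")
  t_obs - qnorm(1 - alpha) * sqrt(var_t) > 0
}

#' Analytic power of the HUS test at given arm sizes
#'
#' \deqn{\omega = \Phi\!\left(\frac{T_{true}}{\sqrt{var(T)}} -
#'   z_{1-\alpha}\right)}, with
#' `var(T) = phi1^2 var(X*1)/n1 + phi2^2 var(X*2)/n2`.
#'
#' @param phi a [estimate_phi()] result.
#' @param n1,n2 subjects per arm (`n2` defaults to `n1`).
#' @param alpha one-sided level.
#' @return Object of class `hus_power`: `power`, `var_T`, `n1`, `n2`,
#'   `alpha`.
#' @export
hus_power <- function(phi, n1, n2 = n1, alpha = 0.05) {
  stopifnot(inherits(phi, "phi_estimate"), n1 >= 1, n2 >= 1,
            alpha > 0, alpha < 1)
  vT <- var_T_at(phi, n1, n2)
  if (phi$T_true <= 0)
    warning("T_true <= 0: one-sided power does not exceed alpha")
  w <- pnorm(phi$T_true / sqrt(vT) - qnorm(1 - alpha))
  structure(list(power = w, var_T = vT, n1 = n1, n2 = n2, alpha = alpha,
                 T_true = phi$T_true),
            class = "hus_power")
}

#' @export
print.hus_power <- function(x, ...) {
  cat(sprintf("analytic HUS power at n1 = %d, n2 = %d (alpha = %g): %.3f\n",
              x$n1, x$n2, x$alpha, x$power))
  invisible(x)
}

#' Per-arm sample size for a target power
#'
#' Inverts the analytic power formula under equal arm sizes:
#' \deqn{n = \frac{(\Phi^{-1}(\omega) + z_{1-\alpha})^2
#'   [\phi_1^2 var(X^*_1) + \phi_2^2 var(X^*_2)]}{T_{true}^2},}
#' rounded up to guarantee the target.
#'
#' @param phi a [estimate_phi()] result with `T_true > 0`.
#' @param power target power `omega` in (0, 1).
#' @param alpha one-sided level.
#' @return Object of class `hus_n`: `n` (per arm, ceiling), `n_exact`,
#'   `power`, `alpha`.
#' @export
hus_sample_size <- function(phi, power, alpha = 0.05) {
  stopifnot(inherits(phi, "phi_estimate"), power > 0, power < 1,
            alpha > 0, alpha < 1)
  if (phi$T_true <= 0)
    stop("T_true <= 0: cannot power a one-sided test in this direction")
  n <- (qnorm(power) + qnorm(1 - alpha))^2 *
    (phi$phi1^2 * phi$var_xstar1 + phi$phi2^2 * phi$var_xstar2) /
    phi$T_true^2
  structure(list(n = ceiling(n - 1e-9), n_exact = n, power = power,
                 alpha = alpha),
            class = "hus_n")
}

#' @export
print.hus_n <- function(x, ...) {
  cat(sprintf(
    "required sample size per arm for %g%% power (alpha = %g): %d (exact %.2f)\n",
    100 * x$power, x$alpha, x$n, x$n_exact))
  invisible(x)
}
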