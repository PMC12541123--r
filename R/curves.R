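#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function for one arm, via
#' [survival::survfit()]. Tied deaths are processed before tied censorings
#' (the standard convention).
#'
#' @param time observed follow-up times (months, `>= 0`).
#' @param event event indicators (1 = death, 0 = censored).
#' @return A `km_curve`: right-continuous step function with `S(0) = 1`,
#'   stored as `jump_times` (death times at which the curve drops) and
#'   `values` (the survival probability just after each drop).
#' @examples
#' fit_km(c(1, 2, 3), c(1, 0, 1))  # S = 2/3 on [1, 3), 0 after
#' @export
fit_km <- function(time, event) {
  if (length(time) == 0) stop("no subjects")
  if (any(time < 0)) stop("negative follow-up times")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  drop <- fit$n.event > 0
  km_curve(fit$time[drop], fit$surv[drop])
}

km_curve <- function(jump_times, values) {
  stopifnot(!is.unsorted(jump_times, strictly = TRUE),
            all(diff(c(1, values)) <= 1e-12), all(values >= -1e-12))
  structure(list(jump_times = as.numeric(jump_times),
                 values = pmax(as.numeric(values), 0)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#' @param curve a `km_curve` from [fit_km()].
#' @param t times at which to evaluate (right-continuous convention).
#' @return Survival probabilities `S(t)`.
#' @export
eval_km <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(t, curve$jump_times)
  c(1, curve$values)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d drops, S(last) = %.4f\n",
              length(x$jump_times),
              if (length(x$values)) tail(x$values, 1) else 1))
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = c(0, x$jump_times), value = c(1, x$values))
}

# ---- piecewise-linear utility curves ---------------------------------------

# A "pw_curve" is a sequence of closed segments [t0, t1] with linear values
# v0 -> v1; it may jump between segments (risk-set composition changes).
pw_curve <- function(t0, t1, v0, v1) {
  stopifnot(length(t0) == length(t1), all(t1 >= t0))
  structure(list(t0 = t0, t1 = t1, v0 = v0, v1 = v1), class = "pw_curve")
}

#' @export
as.data.frame.pw_curve <- function(x, ...) {
  data.frame(t0 = x$t0, t1 = x$t1, v0 = x$v0, v1 = x$v1)
}

#' @export
print.pw_curve <- function(x, ...) {
  cat(sprintf("piecewise-linear curve: %d segments on [%g, %g]\n",
              length(x$t0), min(x$t0), max(x$t1)))
  invisible(x)
}

# evaluate a pw_curve inside the segment containing midpoint m, at time t
pw_eval_segment <- function(curve, seg, t) {
  w <- curve$t1[seg] - curve$t0[seg]
  ifelse(w <= 0, curve$v0[seg],
         curve$v0[seg] +
           (curve$v1[seg] - curve$v0[seg]) * (t - curve$t0[seg]) / w)
}

#' Evaluate a piecewise-linear utility curve
#' @param curve a `pw_curve` (e.g. from [mean_utility_curve()]).
#' @param t evaluation times; at a jump between segments the left segment's
#'   value is returned (boundary-inclusive risk-set convention).
#' @return Curve values.
#' @export
eval_pw <- function(curve, t) {
  stopifnot(inherits(curve, "pw_curve"))
  seg <- findInterval(t, curve$t0, left.open = TRUE)
  seg[seg < 1] <- 1L
  seg <- pmin(seg, length(curve$t0))
  pw_eval_segment(curve, seg, pmin(pmax(t, curve$t0[seg]), curve$t1[seg]))
}

# convert a continuous knot curve (knots, values) to pw_curve segments
knots_to_pw <- function(knots, values, horizon) {
  stopifnot(length(knots) == length(values), !is.unsorted(knots))
  k <- c(if (knots[1] > 0) 0, knots,
         if (tail(knots, 1) < horizon) horizon)
  v <- c(if (knots[1] > 0) values[1], values,
         if (tail(knots, 1) < horizon) tail(values, 1))
  m <- length(k)
  pw_curve(k[-m], k[-1], v[-m], v[-1])
}

#' Mean-utility curve of the at-risk population
#'
#' Builds \eqn{\bar U_g(t)}, the average utility of subjects still at risk at
#' \eqn{t}, from complete per-subject utility trajectories (see
#' [impute_utilities()]). The risk set at \eqn{t} is `{i : time_i >= t}`
#' (boundary inclusive); each subject's trajectory is linearly interpolated
#' between its knots and constant outside them. Past the last departure the
#' last mean value is carried forward so the curve is defined on the whole
#' `[0, horizon]`.
#'
#' @param data a [hus_data()] object.
#' @param arm 1 or 2.
#' @param trajectories long data.frame `id, time, value` of imputed trajectory
#'   knots (each subject needs at least one knot at or before its follow-up
#'   time), as returned by [impute_utilities()].
#' @return A `pw_curve` of segments on which the mean is linear.
#' @export
mean_utility_curve <- function(data, arm, trajectories) {
  stopifnot(inherits(data, "hus_data"), arm %in% c(1, 2))
  s <- data$subjects[data$subjects$arm == arm, , drop = FALSE]
  if (nrow(s) == 0) stop("arm ", arm, " has no subjects")
  tr <- trajectories[trajectories$id %in% s$id, , drop = FALSE]
  if (!all(s$id %in% tr$id))
    stop("missing trajectories for some subjects in arm ", arm)
  horizon <- data$horizon
  bp <- sort(unique(c(0, s$time[s$time <= horizon],
                      tr$time[tr$time < horizon], horizon)))
  bp <- bp[bp >= 0]
  m <- length(bp)
  tr_by_id <- split(tr[c("time", "value")], tr$id)
  # subject trajectory values at all breakpoints (constant extrapolation)
  V <- vapply(as.character(s$id), function(id) {
    k <- tr_by_id[[id]]
    if (is.null(k) || nrow(k) == 0) stop("empty trajectory for id ", id)
    if (nrow(k) == 1) rep(k$value, m)
    else approx(k$time, k$value, xout = bp, rule = 2)$y
  }, numeric(m))
  t0 <- bp[-m]; t1 <- bp[-1]
  v0 <- v1 <- numeric(m - 1)
  last <- NA_real_
  for (j in seq_len(m - 1)) {
    risk <- s$time >= t1[j]
    if (!any(risk)) {
      v0[j] <- v1[j] <- last
    } else {
      v0[j] <- mean(V[j, risk])
      v1[j] <- mean(V[j + 1, risk])
    }
    last <- v1[j]
  }
  if (anyNA(c(v0, v1))) stop("risk set empty before any mean was available")
  pw_curve(t0, t1, v0, v1)
}

#' Weighted HUS Q-statistic for one arm
#'
#' Computes \eqn{Q = \int_0^T S(t)^{\lambda_1} \bar U(t)^{\lambda_2} dt}
#' exactly, segment by segment over the union of the survival curve's jump
#' times and the utility curve's breakpoints: on each segment \eqn{S} is
#' constant and \eqn{\bar U} linear, so the integral has a closed form.
#' Wherever \eqn{S(t) = 0} the integrand is defined as 0.
#'
#' @param surv a `km_curve` from [fit_km()].
#' @param util a `pw_curve` (risk-set mean utility, [mean_utility_curve()]),
#'   or a two-column data.frame / list with `time` (or `knots`) and `value`
#'   giving a continuous piecewise-linear curve.
#' @param lambda1 weight (exponent) on survival, `>= 0`; default 1.
#' @param lambda2 weight (exponent) on utility, `>= 0`; default 1. With
#'   `lambda2 = 0` the statistic reduces to the restricted mean survival time.
#'   A non-integer `lambda2` requires a non-negative utility curve.
#' @param horizon upper limit of integration `T` (months).
#' @return The Q value (months, utility-weighted).
#' @examples
#' km <- fit_km(rep(36, 4), rep(0, 4))
#' u <- data.frame(time = c(0, 36), value = c(0.5, 0.5))
#' q_statistic(km, u, horizon = 36)  # 18
#' @export
q_statistic <- function(surv, util, lambda1 = 1, lambda2 = 1, horizon) {
  stopifnot(inherits(surv, "km_curve"), lambda1 >= 0, lambda2 >= 0,
            horizon > 0)
  if (!inherits(util, "pw_curve")) {
    kt <- if (!is.null(util$time)) util$time else util$knots
    util <- knots_to_pw(kt, util$value, horizon)
  }
  bp <- sort(unique(c(0, horizon,
                      surv$jump_times[surv$jump_times < horizon],
                      util$t0[util$t0 > 0 & util$t0 < horizon],
                      util$t1[util$t1 > 0 & util$t1 < horizon])))
  t0 <- bp[-length(bp)]; t1 <- bp[-1]
  mid <- (t0 + t1) / 2
  S <- eval_km(surv, mid)
  seg <- pmin(pmax(findInterval(mid, util$t0), 1L), length(util$t0))
  va <- pw_eval_segment(util, seg, t0)
  vb <- pw_eval_segment(util, seg, t1)
  if (lambda2 != lambda2 %/% 1 && any(pmin(va, vb)[S > 0] < 0)) {
    bad <- which(S > 0 & pmin(va, vb) < 0)[1]
    stop(sprintf(
      "negative utility on segment [%g, %g] with fractional lambda2",
      t0[bad], t1[bad]))
  }
  dt <- t1 - t0
  flat <- abs(vb - va) < 1e-12
  seg_int <- if (lambda2 == 0) dt else
    ifelse(flat, va^lambda2 * dt,
           (vb^(lambda2 + 1) - va^(lambda2 + 1)) /
             ((vb - va) / dt * (lambda2 + 1)))
  sum(ifelse(S > 0, S^lambda1 * seg_int, 0))
}

#' Two-sample HUS test statistic T = Q1 - Q2
#'
#' Estimates the per-arm HUS values and their difference from a two-arm trial
#' dataset: per-arm Kaplan-Meier curves, utility imputation, risk-set mean
#' utility curves, and exact integration of the weighted product.
#'
#' @param data a [hus_data()] object with both arms non-empty.
#' @param lambda1,lambda2 survival / utility weights (see [q_statistic()]).
#' @param imputation imputation method for missing utility visits; one of
#'   `"group_mean_linear"` (default), `"subject_linear"`,
#'   `"trajectory_mean"`. See [impute_utilities()].
#' @param add_noise add normal noise to group-mean imputed values (only for
#'   `"group_mean_linear"`); requires the RNG state to be managed by the
#'   caller for reproducibility.
#' @return A list with components `Q1`, `Q2`, `T`.
#' @examples
#' subj <- data.frame(id = 1:4, arm = c(1, 1, 2, 2),
#'                    time = 10, event = 0)
#' util <- data.frame(id = 1:4, time = 0,
#'                    score = c(0.8, 0.8, 0.4, 0.4))
#' t_statistic(hus_data(subj, util, horizon = 10))  # T = 8 - 4 = 4
#' @export
t_statistic <- function(data, lambda1 = 1, lambda2 = 1,
                        imputation = c("group_mean_linear", "subject_linear",
                                       "trajectory_mean"),
                        add_noise = FALSE) {
  stopifnot(inherits(data, "hus_data"))
  imputation <- match.arg(imputation)
  arms <- arm_split(data)
  if (length(arms[[1]]$id) == 0 || length(arms[[2]]$id) == 0)
    stop("both arms must be non-empty")
  q <- vapply(arms, function(a) {
    am <- arm_matrix(a)
    Ui <- impute_matrix(am$U, am$time, am$visits, method = imputation,
                        add_noise = add_noise, warn = FALSE)
    .hus_q_arm_cpp(am$time, am$event, Ui, am$visits, data$horizon,
                   lambda1, lambda2)
  }, numeric(1))
  list(Q1 = q[1], Q2 = q[2], T = q[1] - q[2])
}
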