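#' One-sided log-rank superiority test on overall survival
#'
#' Standard two-sample log-rank statistic, signed so that positive values
#' mean fewer deaths than expected in arm 1 (arm 1 superior); rejects when
#' the signed statistic exceeds `z_{1-alpha}`.
#'
#' @param data a [hus_data()] object.
#' @param alpha one-sided level.
#' @return Object of class `os_test` with `statistic` (signed z), `p`
#'   (one-sided), `reject`.
#' @export
logrank_superiority <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "hus_data"), alpha > 0, alpha < 1)
  s <- data$subjects
  if (length(unique(s$arm)) < 2) stop("both arms required")
  if (sum(s$event) == 0) {
    warning("no events in either arm; not rejecting")
    return(structure(list(test = "logrank_superiority", statistic = 0,
                          p = 1, reject = FALSE, alpha = alpha),
                     class = "os_test"))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ arm, data = s)
  v <- if (is.matrix(sd_$var)) sd_$var[1, 1] else sd_$var[1]
  z <- (sd_$exp[1] - sd_$obs[1]) / sqrt(v)
  structure(list(test = "logrank_superiority", statistic = unname(z),
                 p = unname(1 - pnorm(z)), reject = unname(z > qnorm(1 - alpha)),
                 alpha = alpha),
            class = "os_test")
}

#' Hazard-ratio non-inferiority test on overall survival
#'
#' Fits a two-group proportional-hazards model (partial likelihood, Breslow
#' ties) for the hazard ratio of arm 1 vs arm 2 and declares non-inferiority
#' when the upper bound of the Wald confidence interval is below
#' `1 + margin` (e.g. a 5\% margin requires the 95\% CI upper bound to be
#' below 1.05).
#'
#' @param data a [hus_data()] object.
#' @param margin allowed excess hazard, `> 0` (0.05 and 0.10 are common).
#' @param level confidence level of the interval (default 0.95).
#' @return Object of class `os_test` with `hr`, `ci` (length 2), `margin`,
#'   `reject` (non-inferiority declared).
#' @export
hr_noninferiority <- function(data, margin, level = 0.95) {
  stopifnot(inherits(data, "hus_data"), level > 0, level < 1)
  if (!is.numeric(margin) || length(margin) != 1 || margin <= 0)
    stop("margin must be a single positive number")
  s <- data$subjects
  res <- tryCatch({
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ I(arm == 1),
                      data = s, ties = "breslow"))
    est <- unname(fit$coefficients[1])
    se <- sqrt(unname(fit$var[1, 1]))
    if (!is.finite(est) || !is.finite(se)) stop("non-finite HR estimate")
    z <- qnorm(1 - (1 - level) / 2)
    list(hr = exp(est), ci = exp(est + c(-1, 1) * z * se))
  }, error = function(e) e)
  if (inherits(res, "condition")) {
    return(structure(list(test = "hr_noninferiority", hr = NA_real_,
                          ci = c(NA_real_, NA_real_), margin = margin,
                          level = level, reject = FALSE,
                          note = conditionMessage(res)),
                     class = "os_test"))
  }
  structure(list(test = "hr_noninferiority", hr = res$hr, ci = res$ci,
                 margin = margin, level = level,
                 reject = res$ci[2] < 1 + margin),
            class = "os_test")
}

#' @export
print.os_test <- function(x, ...) {
  if (x$test == "logrank_superiority") {
    cat(sprintf(
      "one-sided log-rank (arm 1 superior): z = %.3f, p = %.4f, reject: %s\n",
      x$statistic, x$p, x$reject))
  } else {
    cat(sprintf(
      "HR non-inferiority (margin %g%%): HR = %.3f, %g%% CI [%.3f, %.3f], declared: %s\n",
      100 * x$margin, x$hr, 100 * x$level, x$ci[1], x$ci[2], x$reject))
    if (!is.null(x$note)) cat("  note:", x$note, "\n")
  }
  invisible(x)
}
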