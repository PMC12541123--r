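#' Resampling tests for the HUS difference T = Q1 - Q2
#'
#' One-sided decision procedures for the null hypothesis that arm 1's health
#' utility adjusted survival does not exceed arm 2's (`H0: T <= 0`):
#'
#' \describe{
#'   \item{bootstrap (default)}{`B` stratified resamples (subjects drawn with
#'     replacement within each arm, carrying their utility records); utility
#'     imputation is re-run inside every resample so its uncertainty
#'     propagates. Reject when the one-sided percentile interval
#'     `[q_alpha(T(b)), Inf)` excludes 0, i.e. when the empirical
#'     `alpha`-quantile of the resampled statistics is positive.}
#'   \item{permutation}{arm labels are reassigned at random `B` times,
#'     producing the null distribution of T; reject when the observed T
#'     exceeds the `(1 - alpha)`-quantile of the permuted statistics.}
#'   \item{jackknife}{delete-one replicates pooled over both arms give a
#'     grouped jackknife standard error; reject when
#'     `T - z_{1-alpha} * SE > 0`.}
#' }
#'
#' Empirical quantiles use type-7 interpolation throughout. With
#' `two_sided = TRUE` the bootstrap uses the equal-tailed `(1 - alpha)`
#' interval, the permutation test compares `|T|` to the `(1 - alpha)`-quantile
#' of `|T(b)|`, and the jackknife uses `z_{1-alpha/2}`.
#'
#' @param data a [hus_data()] object with both arms non-empty.
#' @param method `"bootstrap"`, `"permutation"` or `"jackknife"`.
#' @param lambda1,lambda2 survival / utility weights (see [q_statistic()]).
#' @param B number of resamples (ignored by the jackknife); 500 is usually
#'   sufficient to control the type-I error.
#' @param alpha one-sided significance level in (0, 1).
#' @param imputation,add_noise utility imputation settings, see
#'   [impute_utilities()].
#' @param seed optional integer seed; fixing it makes draws and decision
#'   reproducible.
#' @param two_sided use the two-sided variant of the decision rule.
#' @return An object of class `hus_test` with elements `Q1`, `Q2`,
#'   `T_observed`, `method`, `B`, `alpha`, `bound` (the decision quantile, or
#'   the lower confidence bound for the jackknife), `reject`, `draws`, `se`
#'   (jackknife only) and the call settings.
#' @examples
#' sc <- scenario_preset("scenario1")
#' d <- generate_trial(sc, n1 = 40, n2 = 40, seed = 1)
#' hus_test(d, B = 100, seed = 2)
#' @export
hus_test <- function(data,
                     method = c("bootstrap", "permutation", "jackknife"),
                     lambda1 = 1, lambda2 = 1, B = 500, alpha = 0.05,
                     imputation = "group_mean_linear", add_noise = FALSE,
                     seed = NULL, two_sided = FALSE) {
  stopifnot(inherits(data, "hus_data"))
  method <- match.arg(method)
  if (!is.numeric(B) || B < 1) stop("B must be >= 1")
  B <- as.integer(B)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)

  arms <- arm_split(data)
  n1 <- length(arms[[1]]$id); n2 <- length(arms[[2]]$id)
  if (n1 == 0 || n2 == 0) stop("both arms must be non-empty")
  am <- lapply(arms, arm_matrix)
  H <- data$horizon

  q_arm <- function(a, idx = NULL) {
    tm <- a$time; ev <- a$event; U <- a$U
    if (!is.null(idx)) { tm <- tm[idx]; ev <- ev[idx]; U <- U[idx, , drop = FALSE] }
    Ui <- impute_matrix(U, tm, a$visits, method = imputation,
                        add_noise = add_noise, warn = FALSE)
    .hus_q_arm_cpp(tm, ev, Ui, a$visits, H, lambda1, lambda2)
  }
  Q1 <- q_arm(am[[1]]); Q2 <- q_arm(am[[2]])
  T_obs <- Q1 - Q2

  se <- NULL
  if (method == "bootstrap") {
    draws <- vapply(seq_len(B), function(b) {
      q_arm(am[[1]], sample.int(n1, n1, replace = TRUE)) -
        q_arm(am[[2]], sample.int(n2, n2, replace = TRUE))
    }, numeric(1))
    if (two_sided) {
      lo <- quantile(draws, alpha / 2, names = FALSE)
      hi <- quantile(draws, 1 - alpha / 2, names = FALSE)
      bound <- lo
      reject <- lo > 0 || hi < 0
    } else {
      bound <- quantile(draws, alpha, names = FALSE)
      reject <- bound > 0
    }
  } else if (method == "permutation") {
    # pool the two arms on a common visit grid
    visits <- sort(unique(c(am[[1]]$visits, am[[2]]$visits)))
    pm <- lapply(arms, arm_matrix, visits = visits)
    tm <- c(pm[[1]]$time, pm[[2]]$time)
    ev <- c(pm[[1]]$event, pm[[2]]$event)
    U <- rbind(pm[[1]]$U, pm[[2]]$U)
    pooled <- list(time = tm, event = ev, U = U, visits = visits)
    draws <- vapply(seq_len(B), function(b) {
      p <- sample.int(n1 + n2)
      q_arm(pooled, p[seq_len(n1)]) - q_arm(pooled, p[n1 + seq_len(n2)])
    }, numeric(1))
    if (two_sided) {
      bound <- quantile(abs(draws), 1 - alpha, names = FALSE)
      reject <- abs(T_obs) > bound
    } else {
      bound <- quantile(draws, 1 - alpha, names = FALSE)
      reject <- T_obs > bound
    }
  } else { # jackknife
    if (n1 < 2 || n2 < 2) stop("jackknife needs at least 2 subjects per arm")
    loo1 <- vapply(seq_len(n1), function(i)
      q_arm(am[[1]], -i) - Q2, numeric(1))
    loo2 <- vapply(seq_len(n2), function(i)
      Q1 - q_arm(am[[2]], -i), numeric(1))
    v <- (n1 - 1) / n1 * sum((loo1 - mean(loo1))^2) +
         (n2 - 1) / n2 * sum((loo2 - mean(loo2))^2)
    se <- sqrt(v)
    z <- qnorm(1 - if (two_sided) alpha / 2 else alpha)
    bound <- T_obs - z * se
    reject <- if (two_sided) abs(T_obs) > z * se else bound > 0
    draws <- c(loo1, loo2)
    B <- length(draws)
  }

  structure(list(Q1 = Q1, Q2 = Q2, T_observed = T_obs, method = method,
                 B = B, alpha = alpha, bound = bound,
                 reject = as.logical(reject), draws = draws, se = se,
                 lambda1 = lambda1, lambda2 = lambda2,
                 imputation = imputation, two_sided = two_sided,
                 seed = seed),
            class = "hus_test")
}

#' @export
print.hus_test <- function(x, ...) {
  cat(sprintf("HUS %s test (lambda1 = %g, lambda2 = %g, %s alpha = %g)\n",
              x$method, x$lambda1, x$lambda2,
              if (x$two_sided) "two-sided" else "one-sided", x$alpha))
  cat(sprintf("  Q1 = %.4f, Q2 = %.4f, T = %.4f\n", x$Q1, x$Q2, x$T_observed))
  if (x$method == "jackknife")
    cat(sprintf("  jackknife SE = %.4f, lower bound = %.4f\n", x$se, x$bound))
  else
    cat(sprintf("  B = %d, decision quantile = %.4f\n", x$B, x$bound))
  cat(sprintf("  reject H0 (T <= 0): %s\n", x$reject))
  invisible(x)
}

#' Serialize a HUS test result to JSON
#' @param x a `hus_test` object.
#' @param path optional file to write to.
#' @param draws include the resampled statistics.
#' @return The JSON string, invisibly if written to `path`.
#' @export
hus_test_json <- function(x, path = NULL, draws = FALSE) {
  stopifnot(inherits(x, "hus_test"))
  rec <- x[c("Q1", "Q2", "T_observed", "method", "B", "alpha", "bound",
             "reject", "lambda1", "lambda2", "imputation", "two_sided")]
  rec$seed <- if (is.null(x$seed)) NA else x$seed
  if (draws) rec$draws <- x$draws
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
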