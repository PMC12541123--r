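#' Impute complete utility trajectories from sparse visit scores
#'
#' HUS needs a complete utility trajectory on `[0, time_i]` for every subject,
#' while in practice scores are collected at a few scheduled visits and some
#' are missing. Three single-imputation methods are provided, all followed by
#' linear interpolation between knots and constant extrapolation before the
#' first / after the last knot:
#'
#' \describe{
#'   \item{`subject_linear`}{use only the subject's own recorded scores; a
#'     subject observed at a single time point gets a constant trajectory.}
#'   \item{`group_mean_linear` (default)}{at each key time point (a time at
#'     which at least one subject in the arm has a recorded score), replace a
#'     subject's missing value by the arm mean of the recorded scores at that
#'     time, optionally plus normal noise with the standard deviation of the
#'     recorded scores at that time (`add_noise = TRUE`).}
#'   \item{`trajectory_mean`}{replace missing key-time values by the mean of
#'     the subject's own recorded scores. (The source this method follows
#'     defines it only loosely; the subject-own-mean reading used here is an
#'     interpretation.)}
#' }
#'
#' Subjects with no recorded score at all receive the arm-mean curve (the
#' `group_mean_linear` backbone) under every method; their ids are returned in
#' the `"fallback_ids"` attribute. A key time with no recorded score in the
#' arm (possible inside bootstrap resamples) borrows the nearest key time's
#' arm mean, with a warning.
#'
#' @param data a [hus_data()] object.
#' @param method imputation method, see above.
#' @param add_noise logical; add `N(0, sd_t)` noise to group-mean imputed
#'   values (`group_mean_linear` only). Noise makes results depend on the RNG
#'   state; pass `seed` for reproducibility.
#' @param seed optional integer seed used for the noise draws.
#' @param noise_range optional length-2 numeric; if given, noisy imputed
#'   values are clamped into this range (default: no clamping).
#' @return A long data.frame `id, time, value` of trajectory knots with
#'   attribute `"fallback_ids"`. Under the group-mean and trajectory-mean
#'   methods every subject has a knot at every key time — knots after a
#'   subject's departure act as interpolation scaffolding so the trajectory
#'   keeps the arm's utility trend up to the departure; the risk-set mean
#'   curve only ever evaluates a trajectory on `[0, time_i]`.
#' @examples
#' subj <- data.frame(id = 1:2, arm = 1, time = 36, event = 0)
#' util <- data.frame(id = c(1, 1, 2), time = c(1, 3, 1),
#'                    score = c(0.8, 0.6, 0.4))
#' d <- hus_data(subj, util, horizon = 36)
#' impute_utilities(d)  # subject 2 gets the arm mean 0.6 at t = 3
#' @export
impute_utilities <- function(data,
                             method = c("group_mean_linear", "subject_linear",
                                        "trajectory_mean"),
                             add_noise = FALSE, seed = NULL,
                             noise_range = NULL) {
  stopifnot(inherits(data, "hus_data"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  arms <- arm_split(data)
  out <- lapply(arms, function(a) {
    if (length(a$id) == 0) return(NULL)
    am <- arm_matrix(a)
    Ui <- impute_matrix(am$U, am$time, am$visits, method = method,
                        add_noise = add_noise, noise_range = noise_range,
                        warn = TRUE)
    idx <- which(!is.na(Ui), arr.ind = TRUE)
    o <- order(idx[, 1], idx[, 2])
    df <- data.frame(id = a$id[idx[o, 1]],
                     time = am$visits[idx[o, 2]],
                     value = Ui[idx[o, , drop = FALSE]])
    attr(df, "fallback_ids") <- a$id[attr(Ui, "fallback_rows")]
    df
  })
  res <- rbind(out[[1]], out[[2]])
  fb <- c(attr(out[[1]], "fallback_ids"), attr(out[[2]], "fallback_ids"))
  attr(res, "fallback_ids") <- fb
  rownames(res) <- NULL
  res
}

# Matrix-form single imputation on a visit grid.
#
# U: n x K matrix of recorded scores (NA = missing, whether skipped at a
# followed visit or never collected because follow-up had ended), X:
# follow-up times (used only for validation), visits: the K key times.
#
# The group-mean and trajectory-mean methods fill every missing key-time
# value, including visits after a subject's departure: those knots only
# serve as interpolation scaffolding — the risk-set mean never evaluates a
# trajectory past its subject's follow-up time — but they let a trajectory
# keep the arm's utility trend between its last recorded visit and its
# departure instead of freezing at the last observation. The subject-linear
# method by design uses only the subject's own recorded scores (and
# therefore flattens after the last one).
impute_matrix <- function(U, X, visits,
                          method = c("group_mean_linear", "subject_linear",
                                     "trajectory_mean"),
                          add_noise = FALSE, noise_range = NULL,
                          warn = TRUE) {
  method <- match.arg(method)
  obs <- !is.na(U)
  out <- U
  cm <- colMeans(U, na.rm = TRUE)
  if (anyNA(cm) || any(is.nan(cm))) {
    have <- which(!is.nan(cm) & !is.na(cm))
    if (length(have) == 0) stop("arm has no recorded utility scores at all")
    if (warn) warning("key time(s) with no recorded score in the arm; ",
                      "using the nearest key time's arm mean")
    for (k in which(is.nan(cm) | is.na(cm)))
      cm[k] <- cm[have[which.min(abs(visits[have] - visits[k]))]]
  }
  no_obs <- rowSums(obs) == 0
  miss <- !obs
  if (method == "group_mean_linear") {
    out[miss] <- cm[col(out)[miss]]
    if (add_noise) {
      csd <- apply(U, 2, function(z) stats::sd(z, na.rm = TRUE))
      csd[is.na(csd)] <- 0
      noisy <- out[miss] + rnorm(sum(miss), 0, csd[col(out)[miss]])
      if (!is.null(noise_range))
        noisy <- pmin(pmax(noisy, noise_range[1]), noise_range[2])
      out[miss] <- noisy
    }
  } else if (method == "trajectory_mean") {
    rm_ <- rowMeans(U, na.rm = TRUE)
    fill <- miss & !no_obs
    out[fill] <- rm_[row(out)[fill]]
    fb <- miss & no_obs
    out[fb] <- cm[col(out)[fb]]
  } else { # subject_linear: keep observed knots only, arm-mean fallback
    fb <- miss & no_obs
    out[fb] <- cm[col(out)[fb]]
  }
  attr(out, "fallback_rows") <- which(no_obs)
  out
}

#' Linear interpolation of one subject's utility scores
#'
#' Evaluates the subject-level linear imputation at requested key times:
#' linear interpolation between recorded scores, constant extrapolation
#' outside, and a constant trajectory when only one score is available.
#'
#' @param times,scores the subject's recorded visit times and scores.
#' @param key_times times at which the trajectory is needed.
#' @return data.frame `time, value` of trajectory knots at `key_times`.
#' @examples
#' impute_subject_linear(c(0, 3), c(0.8, 0.4), c(0, 3, 36))  # 0.4 at t = 36
#' @export
impute_subject_linear <- function(times, scores, key_times) {
  stopifnot(length(times) == length(scores), length(times) >= 1)
  v <- if (length(times) == 1) rep(scores, length(key_times))
       else approx(times, scores, xout = key_times, rule = 2)$y
  data.frame(time = key_times, value = v)
}

#' Group-mean imputation of an arm's utility scores
#'
#' Fills each subject's missing scores at the arm's key time points with the
#' arm mean of the recorded scores there (optionally plus normal noise with
#' the recorded scores' standard deviation), then interpolates linearly.
#' Stand-alone variant of the default method used by [impute_utilities()].
#'
#' @param observations data.frame `id, time, score` for one arm; missing
#'   visits are simply absent rows.
#' @param key_times the key time points of the arm (default: all recorded
#'   times).
#' @param add_noise,seed,noise_range see [impute_utilities()].
#' @return Long data.frame `id, time, value` with a knot for every subject at
#'   every key time.
#' @export
impute_group_mean_linear <- function(observations, key_times = NULL,
                                     add_noise = FALSE, seed = NULL,
                                     noise_range = NULL) {
  stopifnot(all(c("id", "time", "score") %in% names(observations)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(key_times)) key_times <- sort(unique(observations$time))
  ids <- unique(observations$id)
  U <- matrix(NA_real_, length(ids), length(key_times))
  i <- match(observations$id, ids)
  j <- match(observations$time, key_times)
  ok <- !is.na(j)
  U[cbind(i[ok], j[ok])] <- observations$score[ok]
  Ui <- impute_matrix(U, X = rep(Inf, length(ids)), visits = key_times,
                      method = "group_mean_linear", add_noise = add_noise,
                      noise_range = noise_range)
  data.frame(id = rep(ids, each = length(key_times)),
             time = rep(key_times, length(ids)),
             value = as.vector(t(Ui)))
}

#' Trajectory-mean imputation of one subject's utility scores
#'
#' Missing key-time values are replaced by the mean of the subject's own
#' recorded scores; recorded values are kept.
#'
#' @inheritParams impute_subject_linear
#' @return data.frame `time, value` with a knot at every key time.
#' @export
impute_trajectory_mean <- function(times, scores, key_times) {
  stopifnot(length(times) == length(scores), length(times) >= 1)
  v <- rep(mean(scores), length(key_times))
  hit <- match(round(key_times, 9), round(times, 9))
  v[!is.na(hit)] <- scores[hit[!is.na(hit)]]
  data.frame(time = key_times, value = v)
}
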