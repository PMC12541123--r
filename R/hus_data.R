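#' Assemble a two-arm trial dataset for HUS analysis
#'
#' Bundles a subject-level survival table and a long-format longitudinal
#' utility table into a validated `hus_data` object, the input to
#' [t_statistic()], [hus_test()] and the comparator tests.
#'
#' @param subjects data.frame with columns `id` (unique subject identifier),
#'   `arm` (1 or 2), `time` (observed follow-up in months, already truncated
#'   at the study horizon) and `event` (1 = death, 0 = censored).
#' @param utilities data.frame with columns `id`, `time` (visit time in
#'   months) and `score` (health utility, typically in `[0, 1]`). Every `id`
#'   must appear in `subjects`, and no score may be recorded after the
#'   subject's observed follow-up time.
#' @param horizon study follow-up length `T` in months.
#' @param surgery_time optional landmark time `C` in months (metadata).
#'
#' @return An object of class `hus_data`: a list with elements `subjects`,
#'   `utilities`, `horizon`, `surgery_time`.
#' @examples
#' subj <- data.frame(id = 1:4, arm = c(1, 1, 2, 2),
#'                    time = c(36, 20, 36, 36), event = c(0, 1, 0, 0))
#' util <- data.frame(id = rep(1:4, each = 2),
#'                    time = rep(c(1, 3), 4),
#'                    score = c(0.8, 0.7, 0.6, 0.5, 0.8, 0.6, 0.7, 0.6))
#' d <- hus_data(subj, util, horizon = 36, surgery_time = 3)
#' d
#' @export
hus_data <- function(subjects, utilities, horizon, surgery_time = NULL) {
  stopifnot(is.data.frame(subjects), is.data.frame(utilities))
  need_s <- c("id", "arm", "time", "event")
  need_u <- c("id", "time", "score")
  if (!all(need_s %in% names(subjects)))
    stop("`subjects` needs columns: ", paste(need_s, collapse = ", "))
  if (!all(need_u %in% names(utilities)))
    stop("`utilities` needs columns: ", paste(need_u, collapse = ", "))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("`horizon` must be a single positive number")
  if (anyDuplicated(subjects$id))
    stop("duplicate subject ids")
  if (!all(subjects$arm %in% c(1, 2)))
    stop("`arm` must be 1 or 2")
  if (any(subjects$time < 0))
    stop("negative follow-up times")
  if (any(subjects$time > horizon + 1e-8))
    stop("follow-up times exceed the study horizon; truncate at `horizon`")
  if (!all(subjects$event %in% c(0, 1)))
    stop("`event` must be 0 or 1")
  if (!all(utilities$id %in% subjects$id))
    stop("utility records for unknown subject ids")
  if (any(!is.finite(utilities$score)))
    stop("non-finite utility scores")
  if (any(utilities$time < 0))
    stop("negative utility visit times")
  fu <- subjects$time[match(utilities$id, subjects$id)]
  late <- utilities$time > fu + 1e-8
  if (any(late))
    stop("utility scores recorded after follow-up ended for id(s): ",
         paste(unique(utilities$id[late]), collapse = ", "))
  structure(
    list(subjects = subjects[need_s], utilities = utilities[need_u],
         horizon = horizon, surgery_time = surgery_time),
    class = "hus_data")
}

#' Read a HUS trial dataset from CSV files
#'
#' @param subjects_csv path to a CSV with columns `id, arm, time, event`.
#' @param utilities_csv path to a CSV with columns `id, time, score`.
#' @inheritParams hus_data
#' @return A [hus_data()] object.
#' @export
read_hus_data <- function(subjects_csv, utilities_csv, horizon,
                          surgery_time = NULL) {
  subj <- utils::read.csv(subjects_csv)
  util <- utils::read.csv(utilities_csv)
  hus_data(subj, util, horizon, surgery_time)
}

#' Write a HUS trial dataset to CSV files
#'
#' @param data a [hus_data()] object.
#' @param prefix path prefix; writes `<prefix>_subjects.csv` and
#'   `<prefix>_utilities.csv`.
#' @return Invisibly, the two file paths.
#' @export
write_hus_data <- function(data, prefix) {
  stopifnot(inherits(data, "hus_data"))
  fs <- paste0(prefix, "_subjects.csv")
  fu <- paste0(prefix, "_utilities.csv")
  write.csv(data$subjects, fs, row.names = FALSE)
  write.csv(data$utilities, fu, row.names = FALSE)
  invisible(c(fs, fu))
}

#' @export
print.hus_data <- function(x, ...) {
  n <- table(factor(x$subjects$arm, levels = c(1, 2)))
  cat("HUS trial dataset\n")
  cat(sprintf("  subjects: %d (arm 1: %d, arm 2: %d), events: %d\n",
              nrow(x$subjects), n[[1]], n[[2]], sum(x$subjects$event)))
  cat(sprintf("  utility records: %d at %d distinct visit times\n",
              nrow(x$utilities), length(unique(x$utilities$time))))
  cat(sprintf("  horizon: %g months", x$horizon))
  if (!is.null(x$surgery_time))
    cat(sprintf(", surgery time: %g months", x$surgery_time))
  cat("\n")
  invisible(x)
}

# split a hus_data object by arm; returns list of lists with survival vectors
# and the utility sub-table
arm_split <- function(data) {
  lapply(c(1, 2), function(g) {
    s <- data$subjects[data$subjects$arm == g, , drop = FALSE]
    u <- data$utilities[data$utilities$id %in% s$id, , drop = FALSE]
    list(id = s$id, time = s$time, event = s$event, util = u)
  })
}

# matrix ("engine") form of one arm: visit grid + n x K score matrix with NA
# for missing / post-departure visits. Visit grid defaults to the times at
# which at least one subject in the arm has a recorded score.
arm_matrix <- function(arm, visits = NULL) {
  if (is.null(visits)) visits <- sort(unique(arm$util$time))
  n <- length(arm$id)
  U <- matrix(NA_real_, n, length(visits))
  if (nrow(arm$util)) {
    i <- match(arm$util$id, arm$id)
    j <- match(arm$util$time, visits)
    ok <- !is.na(j)
    U[cbind(i[ok], j[ok])] <- arm$util$score[ok]
  }
  list(time = arm$time, event = as.integer(arm$event), U = U, visits = visits)
}
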