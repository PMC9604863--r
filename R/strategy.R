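# Strategy labelling of testing trials, the four-way participant
# classification, success-onset bins and compelled-task scoring.

#' Label one testing trial as AS / ES / none
#'
#' In the interposed testing trials the participant starts from alley 4
#' with both alley 1 and alley 3 rewarded. Reaching alley 3 requires
#' recognising the environmental landmarks (allocentric strategy, label
#' `"AS"`); replaying the trained route lands in alley 1 (egocentric
#' strategy, `"ES"`); an unsuccessful trial is labelled `"none"`.
#'
#' @param metrics One-row data frame from [score_trial()].
#' @param spec The matching schedule row; must be a `free_testing` trial.
#' @return `"AS"`, `"ES"` or `"none"`.
#' @export
label_testing_trial <- function(metrics, spec) {
  if (is.data.frame(spec)) spec <- trial_spec(spec)
  if (!identical(spec$task, "free_testing"))
    stop("strategy labels are defined only for free_testing trials",
         call. = FALSE)
  if (!isTRUE(metrics$success)) return("none")
  term <- metrics$terminal_alley
  if (identical(term, 3L)) "AS" else if (identical(term, 1L)) "ES" else "none"
}

#' Classify a participant from the five testing-trial labels
#'
#' Rules, applied in precedence order over the 5 labels:
#' \enumerate{
#'   \item `no_strategy` if more than two trials are failures (`"none"`);
#'   \item `allocentric` if `"AS"` occurs in more than three consecutive
#'     trials (a run of at least 4);
#'   \item `egocentric` likewise for `"ES"`;
#'   \item `shifter` otherwise (the participant mixes strategies across
#'     the testing trials).
#' }
#' The precedence makes the classification total: every one of the
#' 3^5 = 243 possible label sequences receives exactly one category.
#'
#' @param labels Character vector of exactly 5 labels in trial order,
#'   each `"AS"`, `"ES"` or `"none"`.
#' @return A list with `category` (one of `allocentric`, `egocentric`,
#'   `shifter`, `no_strategy`), `max_run` (longest same-strategy run) and
#'   `failures` (number of `"none"` labels).
#' @export
classify_participant <- function(labels) {
  if (length(labels) != 5L)
    stop("exactly 5 testing-trial labels are required", call. = FALSE)
  if (!all(labels %in% c("AS", "ES", "none")))
    stop("labels must be 'AS', 'ES' or 'none'", call. = FALSE)
  failures <- sum(labels == "none")
  runs <- rle(labels)
  run_of <- function(lab) {
    w <- runs$lengths[runs$values == lab]
    if (length(w)) max(w) else 0L
  }
  max_run <- max(run_of("AS"), run_of("ES"))
  category <- if (failures > 2L) "no_strategy"
  else if (run_of("AS") >= 4L) "allocentric"
  else if (run_of("ES") >= 4L) "egocentric"
  else "shifter"
  list(category = category, max_run = max_run, failures = failures)
}

#' Success onset over the 16 training trials
#'
#' The onset is the earliest training trial from which the participant
#' succeeded in every remaining trial ("stably found the treasure").
#' Onsets are binned as in the learning analysis: success from the first
#' trial, from the second or third, from the fourth or later, or never.
#'
#' @param successes Logical vector of exactly 16 per-trial success flags
#'   in trial order.
#' @return A list with `onset` (integer trial index or `NA` if never) and
#'   `bin` (`"first"`, `"second_third"`, `"fourth_plus"`, `"never"`).
#' @export
success_onset <- function(successes) {
  if (length(successes) != 16L || !is.logical(successes))
    stop("exactly 16 logical success flags are required", call. = FALSE)
  fails <- which(!successes)
  onset <- if (length(fails) == 0L) 1L
           else if (max(fails) == 16L) NA_integer_
           else max(fails) + 1L
  bin <- if (is.na(onset)) "never"
         else if (onset == 1L) "first"
         else if (onset <= 3L) "second_third"
         else "fourth_plus"
  list(onset = onset, bin = bin)
}

#' Success of one compelled-strategy trial
#'
#' A compelled trial counts as successful only when the treasure is found
#' along a direct route from the start alley to the reward alley, i.e.
#' exactly 2 visited alleys (start and reward) with no detour.
#'
#' @param metrics One-row data frame from [score_trial()].
#' @param spec The matching schedule row; must be `compelled_AS` or
#'   `compelled_ES`.
#' @return Logical.
#' @export
compelled_trial_success <- function(metrics, spec) {
  if (is.data.frame(spec)) spec <- trial_spec(spec)
  if (!spec$task %in% c("compelled_AS", "compelled_ES"))
    stop("compelled scoring applies only to compelled trials", call. = FALSE)
  isTRUE(metrics$success) && identical(as.integer(metrics$n_alleys), 2L)
}

#' Percentage of successful trials
#'
#' @param flags Non-empty logical vector of per-trial success flags.
#' @return Percentage in \[0, 100\].
#' @export
compelled_percent <- function(flags) {
  if (!length(flags)) stop("no trials to score", call. = FALSE)
  100 * sum(flags) / length(flags)
}

#' Strategy and compelled-task summary per participant and session
#'
#' Derives, from a scored metrics table, the per-participant strategy
#' classification (from the five testing trials), the success-onset bin
#' (from the 16 training trials) and the compelled-task success
#' percentages (imposed allocentric over 4 trials, imposed egocentric
#' over 3).
#'
#' @param metrics Data frame from [score_cohort()].
#' @return A data frame with one row per participant x session: `pid`,
#'   `group`, `session`, `category`, `onset`, `onset_bin`,
#'   `pct_compelled_AS`, `pct_compelled_ES`.
#' @export
classify_cohort <- function(metrics) {
  key <- interaction(metrics$pid, metrics$session, drop = TRUE)
  out <- lapply(split(metrics, key), function(m) {
    test <- m[m$task == "free_testing", ]
    test <- test[order(test$trial_index), ]
    labels <- vapply(seq_len(nrow(test)), function(i)
      label_testing_trial(test[i, ], list(task = "free_testing")), "")
    train <- m[m$task == "free_training", ]
    train <- train[order(train$trial_index), ]
    on <- success_onset(as.logical(train$success))
    comp_pct <- function(task) {
      cm <- m[m$task == task, ]
      if (!nrow(cm)) return(NA_real_)
      flags <- vapply(seq_len(nrow(cm)), function(i)
        compelled_trial_success(cm[i, ], list(task = task)), NA)
      compelled_percent(flags)
    }
    data.frame(pid = m$pid[1], group = m$group[1], session = m$session[1],
               category = classify_participant(labels)$category,
               onset = on$onset, onset_bin = on$bin,
               pct_compelled_AS = comp_pct("compelled_AS"),
               pct_compelled_ES = comp_pct("compelled_ES"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$pid, res$session), ]
}
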