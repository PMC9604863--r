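# Trial schedules for the free and compelled navigation tasks.

#' Build the trial schedule for one assessment session
#'
#' The free-navigation block holds 21 trials: 16 training trials (start
#' alley 1, reward alley 3) with 5 testing trials interposed after
#' training trials 4, 7, 10, 13 and 16. Testing trials start from alley 4
#' with both alley 1 and alley 3 rewarded; which one the participant
#' reaches reveals the spontaneous strategy (alley 3: allocentric, alley
#' 1: egocentric route replay). The compelled block holds 4 compelled-
#' allocentric trials (starts alternating 2, 5, 2, 5; landmarks visible)
#' and 3 compelled-egocentric trials (start 1, landmarks removed); the
#' order of the two compelled sub-blocks is counterbalanced by participant
#' parity. Every trial has a 120 s time limit.
#'
#' @param session `"T0"` or `"T1"`.
#' @param participant_parity `"even"` or `"odd"`; even participants run
#'   the compelled-allocentric sub-block first.
#' @param testing_after Training-trial indices after which the five
#'   testing trials are interposed.
#' @param time_limit Per-trial time limit in seconds.
#' @return A data frame with one row per trial: `session`, `block`
#'   (`"free"`/`"compelled"`), `block_order` (position within the whole
#'   session), `task` (`free_training`, `free_testing`, `compelled_AS`,
#'   `compelled_ES`), `trial_index` (ordinal within its task),
#'   `start_alley`, `reward_alleys` (list column), `landmarks_visible`,
#'   `time_limit`.
#' @examples
#' sch <- build_schedule("T0", "even")
#' table(sch$task)
#' @export
build_schedule <- function(session = c("T0", "T1"),
                           participant_parity = c("even", "odd"),
                           testing_after = c(4, 7, 10, 13, 16),
                           time_limit = 120) {
  session <- match.arg(session)
  participant_parity <- match.arg(participant_parity)
  stopifnot(length(testing_after) == 5L, all(testing_after %in% 1:16),
            !is.unsorted(testing_after, strictly = TRUE))

  free_tasks <- character(0)
  for (t in 1:16) {
    free_tasks <- c(free_tasks, "free_training")
    if (t %in% testing_after) free_tasks <- c(free_tasks, "free_testing")
  }
  free <- data.frame(task = free_tasks, stringsAsFactors = FALSE)
  free$trial_index <- stats::ave(seq_along(free$task), free$task, FUN = seq_along)
  free$start_alley <- ifelse(free$task == "free_training", 1L, 4L)
  free$reward_alleys <- lapply(free$task, function(tk)
    if (tk == "free_training") 3L else c(1L, 3L))
  free$landmarks_visible <- TRUE
  free$block <- "free"

  as_block <- data.frame(task = "compelled_AS", trial_index = 1:4,
                         start_alley = c(2L, 5L, 2L, 5L),
                         stringsAsFactors = FALSE)
  es_block <- data.frame(task = "compelled_ES", trial_index = 1:3,
                         start_alley = 1L, stringsAsFactors = FALSE)
  comp <- if (participant_parity == "even") rbind(as_block, es_block)
          else rbind(es_block, as_block)
  comp$reward_alleys <- list(3L)
  comp$landmarks_visible <- comp$task == "compelled_AS"
  comp$block <- "compelled"

  sch <- rbind(free[, names(comp)], comp)
  sch$session <- session
  sch$block_order <- seq_len(nrow(sch))
  sch$time_limit <- time_limit
  sch[, c("session", "block", "block_order", "task", "trial_index",
          "start_alley", "reward_alleys", "landmarks_visible", "time_limit")]
}

# One-row trial specification as a plain list (used by the simulator and
# per-trial scorers).
trial_spec <- function(row) {
  spec <- as.list(row[1, setdiff(names(row), "reward_alleys")])
  spec$reward_alleys <- row$reward_alleys[[1]]
  spec
}
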