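# Per-trial trajectory scoring: success, visited alleys, total path
# length, distance error and rotation angle.

#' Construct / validate a trajectory
#'
#' A trajectory is the timestamped 2-D position record of one trial:
#' a data frame with columns `t_s` (seconds, strictly increasing), `x_m`
#' and `y_m` (meters).
#'
#' @param t_s,x_m,y_m Numeric vectors of equal length (>= 2).
#' @return A data frame of class `sm_trajectory`.
#' @export
trajectory <- function(t_s, x_m, y_m) {
  n <- length(t_s)
  if (n < 2L || length(x_m) != n || length(y_m) != n)
    stop("degenerate trajectory: need >= 2 equal-length samples", call. = FALSE)
  if (any(diff(t_s) <= 0))
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  structure(data.frame(t_s = as.numeric(t_s), x_m = as.numeric(x_m),
                       y_m = as.numeric(y_m)),
            class = c("sm_trajectory", "data.frame"))
}

as_trajectory <- function(df) {
  stopifnot(all(c("t_s", "x_m", "y_m") %in% names(df)))
  trajectory(df$t_s, df$x_m, df$y_m)
}

traj_xy <- function(traj) cbind(traj$x_m, traj$y_m)

#' Total path length of a trajectory
#'
#' Sum of Euclidean distances between consecutive position samples, in
#' meters ("TPL").
#'
#' @param traj A [trajectory()].
#' @return Path length in meters.
#' @export
path_length <- function(traj) {
  traj <- as_trajectory(traj)
  sum(sqrt(rowSums(diff(traj_xy(traj))^2)))
}

#' Alley-entry events along a trajectory
#'
#' Detects every transition into an alley region: a sample enters alley k
#' when its corridor depth strictly exceeds `entry_depth`, and the agent
#' is considered inside that alley until depth drops below
#' `entry_depth - exit_hysteresis` (hysteresis suppresses boundary
#' chatter). The start alley counts as visited because the trajectory
#' begins inside it; re-entries emit new events, so the event count is
#' the "number of visited alleys" (theoretical value 2 for a direct
#' route).
#'
#' @param traj A [trajectory()].
#' @param geom A [star_maze()] geometry.
#' @return A list with `sequence` (integer vector of entered alleys in
#'   order) and `count` (number of entry events).
#' @export
visited_alleys <- function(traj, geom) {
  traj <- as_trajectory(traj)
  stopifnot(inherits(geom, "maze_geometry"))
  xy <- traj_xy(traj)
  rmax <- geom$pentagon_circumradius + geom$alley_length
  oob <- which(sqrt(rowSums(xy^2)) > rmax + 1e-9)
  if (length(oob))
    stop("trajectory sample out of maze bounds at index ", oob[1], call. = FALSE)
  depth <- alley_depths(xy, geom)
  enter <- depth > geom$entry_depth + 1e-9
  release <- depth < geom$entry_depth - geom$exit_hysteresis
  rs <- rowSums(enter)
  cand <- integer(nrow(enter))
  if (any(rs > 0))
    cand[rs > 0] <- max.col(enter[rs > 0, , drop = FALSE], ties.method = "first")
  seq_out <- integer(0)
  cur <- 0L
  for (i in seq_along(cand)) {
    if (cur != 0L && release[i, cur]) cur <- 0L
    if (cur == 0L && cand[i] != 0L) {
      cur <- cand[i]
      seq_out <- c(seq_out, cur)
    }
  }
  list(sequence = seq_out, count = length(seq_out))
}

#' Distance error (percent excess over the ideal path)
#'
#' `DE = 100 * (total - ideal) / ideal`: the percentage by which the
#' travelled distance exceeds the ideal (direct-route) distance. 0 for a
#' perfectly direct trial; negative values cannot occur for a successful
#' trial scored against the true ideal but are returned as computed.
#'
#' @param total_distance Distance travelled (m), >= 0.
#' @param ideal_distance Ideal direct-route distance (m), > 0.
#' @return Distance error in percent.
#' @examples
#' distance_error(246.76, 246)  # 0.309 % (the TD baseline median)
#' @export
distance_error <- function(total_distance, ideal_distance) {
  if (any(ideal_distance <= 0))
    stop("ideal_distance must be positive", call. = FALSE)
  if (any(total_distance < 0))
    stop("total_distance must be non-negative", call. = FALSE)
  100 * (total_distance - ideal_distance) / ideal_distance
}

#' Cumulative rotation of a trajectory
#'
#' Headings are computed from consecutive displacement vectors longer
#' than `min_displacement` (jitter below the threshold is discarded); the
#' cumulative rotation is the sum of absolute signed heading changes in
#' degrees ("participant's rotations").
#'
#' @param traj A [trajectory()].
#' @param min_displacement Minimum displacement (m) for a step to
#'   contribute a heading.
#' @return Cumulative rotation in degrees.
#' @export
cumulative_rotation <- function(traj, min_displacement = 0.05) {
  traj <- as_trajectory(traj)
  d <- diff(traj_xy(traj))
  len <- sqrt(rowSums(d^2))
  d <- d[len > min_displacement, , drop = FALSE]
  if (nrow(d) < 2L)
    stop("degenerate trajectory: fewer than 2 displacements above the ",
         "minimum-displacement threshold", call. = FALSE)
  head_deg <- atan2(d[, 2], d[, 1]) * 180 / pi
  sum(abs(wrap_angle(diff(head_deg))))
}

#' Rotation angle (excess rotation over the ideal route)
#'
#' `RA = participant's rotations - minimum rotations`, in degrees. Noise
#' in the heading estimate can push the measured rotations below the
#' ideal minimum; negative values are clamped to 0 and flagged.
#'
#' @param participant_rotations Measured cumulative rotation (degrees, >= 0).
#' @param min_rotation Minimum rotation of the ideal route (degrees, >= 0).
#' @return Rotation angle in degrees (>= 0) with attribute `clamped`
#'   (`TRUE` when the raw difference was negative).
#' @export
rotation_angle <- function(participant_rotations, min_rotation) {
  if (any(participant_rotations < 0) || any(min_rotation < 0))
    stop("rotations must be non-negative", call. = FALSE)
  raw <- participant_rotations - min_rotation
  clamped <- raw < 0
  if (any(clamped))
    warning("rotation angle below the ideal minimum; clamped to 0",
            call. = FALSE)
  structure(pmax(raw, 0), clamped = clamped)
}

#' Score one trial
#'
#' Computes the full per-trial metric set from a trajectory and its trial
#' specification: success (the trajectory comes within the treasure
#' capture radius in a reward alley within the time limit), the visited-
#' alley sequence and count, total path length (TPL), distance error (DE,
#' percent) and rotation angle (RA, degrees). DE and RA are computed
#' against the ideal route from the start alley to the reward alley
#' actually reached (for unsuccessful trials, the reward alley closest to
#' the start on the pentagon).
#'
#' @param traj A [trajectory()].
#' @param spec One schedule row (see [build_schedule()]) or an equivalent
#'   list with `task`, `start_alley`, `reward_alleys`, `time_limit`.
#' @param geom A [star_maze()] geometry.
#' @return A one-row data frame: `success`, `n_alleys`, `alley_seq`
#'   (string, e.g. `"1>5>3"`), `terminal_alley`, `tpl_m`, `de_pct`,
#'   `rot_deg`, `ra_deg`, `duration_s`.
#' @export
score_trial <- function(traj, spec, geom) {
  traj <- as_trajectory(traj)
  if (is.data.frame(spec)) spec <- trial_spec(spec)
  stopifnot(inherits(geom, "maze_geometry"))
  dur <- traj$t_s[nrow(traj)] - traj$t_s[1]
  if (dur > spec$time_limit + 1)
    stop("trajectory exceeds the trial time limit by more than 1 s",
         call. = FALSE)

  xy <- traj_xy(traj)
  rewards <- spec$reward_alleys
  reached <- NA_integer_
  t_hit <- Inf
  for (k in rewards) {
    p <- alley_position(k, geom)
    hit <- which(sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2) <=
                   geom$capture_radius)
    if (length(hit) && traj$t_s[hit[1]] < t_hit) {
      t_hit <- traj$t_s[hit[1]]
      reached <- k
    }
  }
  success <- is.finite(t_hit) && (t_hit - traj$t_s[1]) <= spec$time_limit

  va <- visited_alleys(traj, geom)
  target <- if (success) reached else {
    d <- alley_circular_distance(spec$start_alley, rewards)
    rewards[order(d, rewards)][1]
  }
  ir <- ideal_route(spec$start_alley, target, geom)
  tpl <- path_length(traj)
  # an idle participant produces no displacements above the jitter
  # threshold: their measured rotation is zero, not an error
  rot <- tryCatch(cumulative_rotation(traj), error = function(e) 0)
  ra <- suppressWarnings(rotation_angle(rot, ir$min_rotation))
  data.frame(success = success,
             n_alleys = va$count,
             alley_seq = paste(va$sequence, collapse = ">"),
             terminal_alley = if (length(va$sequence))
               va$sequence[length(va$sequence)] else NA_integer_,
             tpl_m = tpl,
             de_pct = distance_error(tpl, ir$ideal_distance),
             rot_deg = rot,
             ra_deg = as.numeric(ra),
             duration_s = dur,
             stringsAsFactors = FALSE)
}

#' Score every trial of a cohort
#'
#' Applies [score_trial()] to each trajectory of a simulated or loaded
#' cohort and binds the per-trial metrics to the schedule rows.
#'
#' @param cohort A cohort as returned by [simulate_cohort()] or
#'   [read_cohort()].
#' @param geom A [star_maze()] geometry (defaults to the cohort's).
#' @return A data frame with one row per trial: participant and trial
#'   identifiers, group, task fields and all [score_trial()] metrics.
#' @export
score_cohort <- function(cohort, geom = cohort$geometry) {
  stopifnot(!is.null(cohort$trials), !is.null(cohort$trajectories))
  trials <- cohort$trials
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- cohort$trajectories[[trials$traj_id[i]]]
    m <- score_trial(tr, trials[i, ], geom)
    out[[i]] <- cbind(trials[i, c("pid", "group", "session", "block",
                                  "block_order", "task", "trial_index",
                                  "start_alley", "traj_id")],
                      m, row.names = NULL)
  }
  do.call(rbind, out)
}
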