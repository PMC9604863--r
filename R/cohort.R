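# Cohort-level simulation: study arms, strategy mixtures, demographics,
# visuospatial Z-scores, ground-truth labels, and dataset I/O.

#' Configuration of a synthetic cohort
#'
#' Describes the simulated study: arm sizes (by default the 14 typically
#' developing, 11 CP-Regular and 16 CP-Navigation participants of the
#' study design this pipeline targets), the per-arm strategy mixture,
#' per-arm and per-session learning onsets (baseline: training-trial 5
#' for TD, 7 for the CP arms; follow-up: 2 for everyone, the maze having
#' been learnt), and ranges for the per-agent nuisance parameters.
#'
#' @param arms Named integer vector of arm sizes; all >= 1.
#' @param sessions Character vector of assessment sessions to simulate
#'   (subset of `c("T0", "T1")`).
#' @param mixtures Named list (one per arm) of strategy mixtures: numeric
#'   vectors over `allocentric`, `egocentric`, `shifter`, `no_strategy`
#'   summing to 1.
#' @param learning_onset Named list (one per session) of named numeric
#'   vectors (one per arm): the training trial from which simulated
#'   performance is asymptotic.
#' @param noise_range,speed_range,excess_range Ranges (min, max) from
#'   which each agent's heading-noise SD (degrees), speed (m/s) and
#'   pre-learning path-excess factor are drawn uniformly.
#' @param switch_probability,fail_probability Passed to
#'   [agent_profile()].
#' @param seed Integer master seed; required and recorded in the
#'   manifest.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(arms = c("TD" = 14L, "CP-Regular" = 11L,
                                   "CP-Navigation" = 16L),
                          sessions = c("T0", "T1"),
                          mixtures = NULL,
                          learning_onset = NULL,
                          noise_range = c(2, 5),
                          speed_range = c(3.5, 4.5),
                          excess_range = c(1.4, 1.8),
                          switch_probability = 0.5,
                          fail_probability = 0.85,
                          seed) {
  if (missing(seed)) stop("cohort_config requires a seed", call. = FALSE)
  if (is.null(names(arms)) || any(!nzchar(names(arms))))
    stop("arms must be a named vector", call. = FALSE)
  if (any(arms < 1))
    stop("every arm must have at least 1 participant", call. = FALSE)
  stopifnot(all(sessions %in% c("T0", "T1")))
  strategies <- c("allocentric", "egocentric", "shifter", "no_strategy")
  if (is.null(mixtures)) {
    mixtures <- list(
      "TD" = c(0.50, 0.36, 0.14, 0.00),
      "CP-Regular" = c(0.27, 0.37, 0.18, 0.18),
      "CP-Navigation" = c(0.25, 0.37, 0.19, 0.19))
    mixtures <- lapply(mixtures, stats::setNames, strategies)
    mixtures <- mixtures[intersect(names(mixtures), names(arms))]
    for (a in setdiff(names(arms), names(mixtures)))
      mixtures[[a]] <- stats::setNames(c(0.5, 0.36, 0.14, 0), strategies)
  }
  for (a in names(arms)) {
    mx <- mixtures[[a]]
    if (is.null(mx) || length(mx) != 4L || abs(sum(mx) - 1) > 1e-8 ||
        any(mx < 0))
      stop("strategy mixture for arm '", a,
           "' must be 4 non-negative weights summing to 1", call. = FALSE)
    if (is.null(names(mx))) names(mixtures[[a]]) <- strategies
  }
  if (is.null(learning_onset)) {
    base <- stats::setNames(ifelse(grepl("^TD", names(arms)), 5, 7),
                            names(arms))
    learning_onset <- list(T0 = base,
                           T1 = stats::setNames(rep(2, length(arms)),
                                                names(arms)))
  }
  structure(list(arms = arms, sessions = sessions, mixtures = mixtures,
                 learning_onset = learning_onset,
                 noise_range = noise_range, speed_range = speed_range,
                 excess_range = excess_range,
                 switch_probability = switch_probability,
                 fail_probability = fail_probability,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Small stable FNV-1a hash of a serialized configuration (hex string);
# recorded in the manifest so reruns can be checked for config identity.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

# Demographic marginals used for the simulated metadata (per arm:
# male proportion, age mean/sd, GMFCS and MACS level weights).
arm_demographics <- function(arm) {
  if (grepl("^TD", arm))
    list(p_male = 6 / 14, age = c(10.7, 2.6), gmfcs = NULL, macs = NULL)
  else if (grepl("Regular", arm))
    list(p_male = 8 / 11, age = c(9.6, 1.7),
         gmfcs = c(4, 4, 3) / 11, macs = c(7, 3, 1) / 11)
  else
    list(p_male = 13 / 16, age = c(11.5, 2.2),
         gmfcs = c(9, 0, 7) / 16, macs = c(9, 5, 2) / 16)
}

# Z-score generating parameters per arm: mean/sd at T0 and the T0->T1
# mean shift, per test.
arm_zscores <- function(arm) {
  if (grepl("^TD", arm))
    list(raven = c(1.6, 0.9), corsi = c(0.6, 0.8), labyrinth = c(0.8, 0.8),
         d_corsi = 0.05, d_lab = 0.05)
  else if (grepl("Regular", arm))
    list(raven = c(0.0, 1.0), corsi = c(-0.2, 1.0), labyrinth = c(-0.6, 1.0),
         d_corsi = 0.1, d_lab = 0.4)
  else
    list(raven = c(0.0, 1.3), corsi = c(-0.5, 1.0), labyrinth = c(-0.7, 1.0),
         d_corsi = 0.3, d_lab = 0.5)
}

#' Simulate a full synthetic cohort
#'
#' Draws participants for every arm (strategy from the arm's mixture,
#' nuisance parameters from the configured ranges, demographics and
#' visuospatial Z-scores from arm-level distributions), builds each
#' session's trial schedule, and simulates every trial's trajectory with
#' [simulate_trial()]. All randomness derives from the master seed, so a
#' rerun with the same configuration is reproducible sample-for-sample.
#'
#' @param config A [cohort_config()].
#' @param geom A [star_maze()] geometry.
#' @return A list of class `sm_cohort` with elements `trials` (one row
#'   per scheduled trial, with `traj_id`), `trajectories` (named list of
#'   trajectory data frames), `metadata`, `zscores`, `truth`
#'   (per-participant-session strategy and learning labels), `geometry`
#'   and `manifest`.
#' @export
simulate_cohort <- function(config, geom = star_maze()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(geom, "maze_geometry"))
  set.seed(config$seed)
  strategies <- c("allocentric", "egocentric", "shifter", "no_strategy")

  prefixes <- toupper(substr(gsub("[^A-Za-z]", "", names(config$arms)), 1, 3))
  if (anyDuplicated(prefixes))
    prefixes <- paste0(prefixes, seq_along(prefixes))
  names(prefixes) <- names(config$arms)

  participants <- list()
  idx <- 0L
  for (a in names(config$arms)) {
    prefix <- prefixes[[a]]
    demo <- arm_demographics(a)
    zs <- arm_zscores(a)
    for (i in seq_len(config$arms[[a]])) {
      idx <- idx + 1L
      gmfcs <- if (is.null(demo$gmfcs)) NA_character_ else
        sample(c("I", "II", "III"), 1L, prob = demo$gmfcs)
      macs <- if (is.null(demo$macs)) NA_character_ else
        sample(c("I", "II", "III"), 1L, prob = demo$macs)
      corsi0 <- stats::rnorm(1, zs$corsi[1], zs$corsi[2])
      lab0 <- stats::rnorm(1, zs$labyrinth[1], zs$labyrinth[2])
      participants[[idx]] <- data.frame(
        pid = sprintf("%s%02d", prefix, i), group = a,
        parity = if (idx %% 2L == 0L) "even" else "odd",
        gender = sample(c("M", "F"), 1L,
                        prob = c(demo$p_male, 1 - demo$p_male)),
        age = round(min(max(stats::rnorm(1, demo$age[1], demo$age[2]), 5),
                        18), 1),
        gmfcs = gmfcs, macs = macs,
        raven_T0 = round(stats::rnorm(1, zs$raven[1], zs$raven[2]), 2),
        corsi_T0 = round(corsi0, 2),
        corsi_T1 = round(corsi0 + stats::rnorm(1, zs$d_corsi, 0.4), 2),
        labyrinth_T0 = round(lab0, 2),
        labyrinth_T1 = round(lab0 + stats::rnorm(1, zs$d_lab, 0.4), 2),
        stringsAsFactors = FALSE)
    }
  }
  participants <- do.call(rbind, participants)

  trials_out <- list()
  trajectories <- list()
  truth <- list()
  for (p in seq_len(nrow(participants))) {
    row <- participants[p, ]
    for (ses in config$sessions) {
      strategy <- sample(strategies, 1L, prob = config$mixtures[[row$group]])
      profile <- agent_profile(
        strategy = strategy,
        heading_noise_sd = stats::runif(1, config$noise_range[1],
                                        config$noise_range[2]),
        speed = stats::runif(1, config$speed_range[1],
                             config$speed_range[2]),
        learning_onset = config$learning_onset[[ses]][[row$group]],
        pre_learning_excess = stats::runif(1, config$excess_range[1],
                                           config$excess_range[2]),
        switch_probability = config$switch_probability,
        fail_probability = config$fail_probability)
      truth[[length(truth) + 1L]] <- data.frame(
        pid = row$pid, group = row$group, session = ses,
        strategy = strategy, learning_onset = profile$learning_onset,
        heading_noise_sd = profile$heading_noise_sd,
        speed = profile$speed,
        pre_learning_excess = profile$pre_learning_excess,
        stringsAsFactors = FALSE)
      sch <- build_schedule(ses, row$parity)
      seeds <- sample.int(.Machine$integer.max, nrow(sch))
      for (j in seq_len(nrow(sch))) {
        traj <- simulate_trial(profile, sch[j, ], geom, seed = seeds[j])
        tid <- sprintf("%s_%s_%s_%02d", row$pid, ses, sch$task[j],
                       sch$trial_index[j])
        if (!is.null(trajectories[[tid]]))
          stop("trajectory id collision: ", tid, call. = FALSE)
        trajectories[[tid]] <- traj
        tr <- sch[j, ]
        tr$pid <- row$pid; tr$group <- row$group; tr$traj_id <- tid
        trials_out[[length(trials_out) + 1L]] <- tr
      }
    }
  }
  trials <- do.call(rbind, trials_out)
  rownames(trials) <- NULL
  truth <- do.call(rbind, truth)

  manifest <- list(seed = config$seed,
                   config_hash = config_hash(unclass(config)),
                   n_participants = nrow(participants),
                   n_trials = nrow(trials),
                   sessions = config$sessions,
                   arms = as.list(config$arms))
  structure(list(trials = trials, trajectories = trajectories,
                 metadata = participants[, c("pid", "group", "parity",
                                             "gender", "age", "gmfcs",
                                             "macs")],
                 zscores = participants[, c("pid", "group", "raven_T0",
                                            "corsi_T0", "corsi_T1",
                                            "labyrinth_T0",
                                            "labyrinth_T1")],
                 truth = truth, geometry = geom, manifest = manifest),
            class = "sm_cohort")
}

#' Write a cohort to disk as plain-text files
#'
#' Lays the dataset out as one trajectory CSV per trial
#' (`trajectories/{pid}_{session}_{task}_{index}.csv` with columns
#' `t_s, x_m, y_m`), plus `trials.csv`, `metadata.csv`, `zscores.csv`,
#' `truth.csv` and `manifest.json`.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param dir Output directory (created if needed; must not already
#'   contain a `trajectories/` directory).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sm_cohort"))
  tdir <- file.path(dir, "trajectories")
  if (dir.exists(tdir))
    stop("output collision: ", tdir, " already exists", call. = FALSE)
  dir.create(tdir, recursive = TRUE)
  trials <- cohort$trials
  trials$reward_alleys <- vapply(trials$reward_alleys, paste,
                                 "", collapse = ";")
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$zscores, file.path(dir, "zscores.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  for (tid in names(cohort$trajectories))
    utils::write.csv(cohort$trajectories[[tid]],
                     file.path(tdir, paste0(tid, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort dataset from disk
#'
#' Counterpart of [write_cohort()]. Trajectory files referenced by
#' `trials.csv` but absent from `trajectories/` are collected and
#' reported in a single error.
#'
#' @param dir Dataset directory.
#' @param geom A [star_maze()] geometry to attach.
#' @return An `sm_cohort` list (see [simulate_cohort()]); `truth` is
#'   `NULL` when no `truth.csv` is present.
#' @export
read_cohort <- function(dir, geom = star_maze()) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  trials$reward_alleys <- lapply(strsplit(as.character(trials$reward_alleys),
                                          ";"), as.integer)
  tdir <- file.path(dir, "trajectories")
  missing_files <- trials$traj_id[!file.exists(
    file.path(tdir, paste0(trials$traj_id, ".csv")))]
  if (length(missing_files))
    stop("missing trajectory file(s): ",
         paste(utils::head(missing_files, 5), collapse = ", "),
         if (length(missing_files) > 5) " ...", call. = FALSE)
  trajectories <- lapply(stats::setNames(trials$traj_id, trials$traj_id),
                         function(tid)
                           as_trajectory(utils::read.csv(
                             file.path(tdir, paste0(tid, ".csv")))))
  truth_path <- file.path(dir, "truth.csv")
  manifest_path <- file.path(dir, "manifest.json")
  structure(list(
    trials = trials, trajectories = trajectories,
    metadata = utils::read.csv(file.path(dir, "metadata.csv"),
                               stringsAsFactors = FALSE),
    zscores = utils::read.csv(file.path(dir, "zscores.csv"),
                              stringsAsFactors = FALSE),
    truth = if (file.exists(truth_path))
      utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL,
    geometry = geom,
    manifest = if (file.exists(manifest_path))
      jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL),
    class = "sm_cohort")
}
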