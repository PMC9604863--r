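# Goal-directed agent simulator: synthetic participants, trajectories
# and ground-truth labels with the statistical structure the analysis
# assumes (strategy profiles, learning, heading noise).

#' Agent behavioural profile
#'
#' Parameters of one simulated participant-session. The agent walks at
#' constant `speed` in 0.1 s steps, each step's heading pointing at the
#' current waypoint plus a Gaussian perturbation of `heading_noise_sd`
#' degrees. Strategy governs the target alley in testing and compelled
#' trials; learning governs how inflated the path is in early training
#' trials.
#'
#' @param strategy `"allocentric"`, `"egocentric"`, `"shifter"` or
#'   `"no_strategy"`.
#' @param heading_noise_sd Per-step heading noise SD (degrees), >= 0.
#' @param speed Walking speed (m/s), > 0.
#' @param learning_onset Training trial (1..16) from which the path is
#'   asymptotically efficient.
#' @param pre_learning_excess Multiplicative path-length factor at
#'   training trial 1 (>= 1); the excess decays linearly to 1 at
#'   `learning_onset`.
#' @param switch_probability Probability that a shifter uses the
#'   allocentric strategy in a given testing trial.
#' @param fail_probability Probability that a no-strategy agent times out
#'   in a testing or compelled trial.
#' @return A list of class `agent_profile`.
#' @export
agent_profile <- function(strategy = c("allocentric", "egocentric",
                                       "shifter", "no_strategy"),
                          heading_noise_sd = 3,
                          speed = 4,
                          learning_onset = 5,
                          pre_learning_excess = 1.6,
                          switch_probability = 0.5,
                          fail_probability = 0.85) {
  strategy <- match.arg(strategy)
  stopifnot(heading_noise_sd >= 0, speed > 0,
            learning_onset >= 1, learning_onset <= 16,
            pre_learning_excess >= 1,
            switch_probability >= 0, switch_probability <= 1,
            fail_probability >= 0, fail_probability <= 1)
  structure(list(strategy = strategy, heading_noise_sd = heading_noise_sd,
                 speed = speed, learning_onset = learning_onset,
                 pre_learning_excess = pre_learning_excess,
                 switch_probability = switch_probability,
                 fail_probability = fail_probability),
            class = "agent_profile")
}

# Alley reached by replaying the trained turn sequence (start 1 ->
# reward 3, i.e. two alleys counterclockwise) from an arbitrary start.
ego_replay_alley <- function(start) ((start - 1L + 2L) %% 5L) + 1L

# Steer along waypoints at constant speed with per-step heading noise.
# Returns the sampled trajectory, truncated at capture of the final
# waypoint or at the time limit. `wander = TRUE` keeps appending random
# in-maze waypoints instead of terminating (timeout behaviour).
steer_path <- function(start_pos, waypoints, speed, noise_sd_deg, geom,
                       time_limit = 120, dt = 0.1, wander = FALSE) {
  max_steps <- ceiling(time_limit / dt)
  noise <- stats::rnorm(max_steps, 0, noise_sd_deg) * pi / 180
  xs <- numeric(max_steps + 1); ys <- numeric(max_steps + 1)
  pos <- start_pos
  xs[1] <- pos[1]; ys[1] <- pos[2]
  wpi <- 1L
  nwp <- nrow(waypoints)
  reach_tol <- 2
  final_tol <- 0.8 * geom$capture_radius
  n_rec <- 1L
  for (s in seq_len(max_steps)) {
    repeat {
      if (wpi > nwp) break
      tol <- if (wpi == nwp && !wander) final_tol else reach_tol
      if (sqrt(sum((pos - waypoints[wpi, ])^2)) >= tol) break
      wpi <- wpi + 1L
    }
    if (wpi > nwp) {
      if (!wander) break
      waypoints <- rbind(waypoints, wander_waypoint(geom))
      nwp <- nrow(waypoints)
    }
    dir <- waypoints[wpi, ] - pos
    h <- atan2(dir[2], dir[1]) + noise[s]
    pos <- pos + speed * dt * c(cos(h), sin(h))
    n_rec <- s + 1L
    xs[n_rec] <- pos[1]; ys[n_rec] <- pos[2]
  }
  trajectory(t_s = dt * (seq_len(n_rec) - 1L),
             x_m = xs[seq_len(n_rec)], y_m = ys[seq_len(n_rec)])
}

# Random exploration waypoint: somewhere in the hub or shallow in an
# alley, never near a reward position.
wander_waypoint <- function(geom) {
  k <- sample.int(5L, 1L)
  r <- stats::runif(1, 5, geom$pentagon_circumradius + 35)
  r * alley_units(geom)[k, ]
}

#' Simulate one trial of one agent
#'
#' Produces a goal-directed trajectory consistent with the agent's
#' strategy and the trial task:
#' \itemize{
#'   \item training trials: start alley -> hub -> reward alley, with a
#'     detour (via the hub into a non-target alley and back) whose length
#'     realises the profile's pre-learning path excess before
#'     `learning_onset`;
#'   \item free testing trials: allocentric agents steer to alley 3 by
#'     landmark use; egocentric agents replay the trained turns (from
#'     start 4 they terminate in alley 1); shifters draw between the two;
#'     no-strategy agents mostly time out wandering;
#'   \item compelled allocentric: egocentric agents first replay their
#'     trained route into the wrong alley, then search on to the reward
#'     (an indirect, hence unsuccessful-by-rule, trial);
#'   \item compelled egocentric (landmarks removed): every strategic
#'     agent replays the trained route; allocentric agents do so with
#'     3-fold elevated heading noise, having lost their landmarks.
#' }
#'
#' @param profile An [agent_profile()].
#' @param spec One schedule row (see [build_schedule()]).
#' @param geom A [star_maze()] geometry.
#' @param seed Integer seed; required (every trajectory must be
#'   reproducible).
#' @param dt Sampling interval in seconds (10 Hz by default).
#' @return A [trajectory()].
#' @export
simulate_trial <- function(profile, spec, geom, seed, dt = 0.1) {
  stopifnot(inherits(profile, "agent_profile"),
            inherits(geom, "maze_geometry"))
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("simulate_trial requires an explicit integer seed ",
         "(reproducibility contract)", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.data.frame(spec)) spec <- trial_spec(spec)

  start <- spec$start_alley
  rewards <- spec$reward_alleys
  start_pos <- alley_position(start, geom)
  noise <- profile$heading_noise_sd
  wander <- FALSE
  center <- rbind(geom$center)

  route_to <- function(target, via = NULL)
    rbind(center, via, alley_position(target, geom))

  waypoints <- switch(spec$task,
    free_training = {
      target <- rewards[1]
      f <- 1
      t_tr <- spec$trial_index
      o <- profile$learning_onset
      if (t_tr < o)
        f <- 1 + (profile$pre_learning_excess - 1) * (o - t_tr) / max(1, o - 1)
      if (profile$strategy == "no_strategy") noise <- 2 * noise
      ir <- ideal_route(start, target, geom)
      extra <- (f - 1) * ir$ideal_distance
      if (extra > 6) {
        w <- sample(setdiff(1:5, c(start, target)), 1L)
        r <- min(extra / 2,
                 geom$pentagon_circumradius + geom$alley_length - 10)
        via <- rbind(r * alley_units(geom)[w, ], center)
        route_to(target, via)
      } else route_to(target)
    },
    free_testing = {
      strat <- profile$strategy
      if (strat == "shifter")
        strat <- if (stats::runif(1) < profile$switch_probability)
          "allocentric" else "egocentric"
      if (strat == "no_strategy") {
        if (stats::runif(1) < profile$fail_probability) {
          wander <- TRUE
          center
        } else route_to(sample(rewards, 1L))
      } else if (strat == "allocentric") {
        route_to(if (3L %in% rewards) 3L else rewards[1])
      } else {
        route_to(ego_replay_alley(start))
      }
    },
    compelled_AS = {
      target <- rewards[1]
      switch(profile$strategy,
        egocentric = {
          # replay the trained turns into the wrong alley, search part of
          # it, then fall back on the landmarks that are still visible
          wrong <- ego_replay_alley(start)
          via <- rbind(alley_position(wrong, geom, depth = 60), center)
          route_to(target, via)
        },
        no_strategy = {
          if (stats::runif(1) < profile$fail_probability) {
            wander <- TRUE
            center
          } else {
            w <- sample(setdiff(1:5, c(start, target)), 1L)
            via <- rbind(alley_position(w, geom, depth = 60), center)
            route_to(target, via)
          }
        },
        route_to(target))
    },
    compelled_ES = {
      target <- ego_replay_alley(start)  # trained turns; equals the reward
      if (profile$strategy == "allocentric") noise <- 3 * noise
      if (profile$strategy == "no_strategy") {
        if (stats::runif(1) < profile$fail_probability) {
          wander <- TRUE
          center
        } else route_to(target)
      } else route_to(target)
    },
    stop("unknown task: ", spec$task, call. = FALSE))

  steer_path(start_pos, waypoints, profile$speed, noise, geom,
             time_limit = spec$time_limit, dt = dt, wander = wander)
}
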