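test_that("path length sums Euclidean steps", {
  # 3-4-5 right triangle: two legs walked, 3 + 4
  expect_equal(path_length(trajectory(0:2, c(0, 3, 3), c(0, 0, 4))), 7)
  # closing the hypotenuse adds 5
  expect_equal(path_length(trajectory(0:3, c(0, 3, 3, 0), c(0, 0, 4, 0))), 12)
  expect_equal(path_length(trajectory(0:3, rep(1, 4), rep(2, 4))), 0)
  line <- trajectory(0:10, 0:10, rep(0, 11))  # 1 m/s for 10 s
  expect_equal(path_length(line), 10)
  expect_error(trajectory(0, 1, 1), "degenerate")
  expect_error(trajectory(c(0, 0), c(0, 1), c(0, 1)), "strictly increasing")
})

test_that("path length is invariant to resampling a piecewise-linear path", {
  geom <- sm_geom()
  poly <- ideal_route(2, 5, geom)$polyline
  a <- path_length(polyline_trajectory(poly, speed = 4, dt = 0.1))
  b <- path_length(polyline_trajectory(poly, speed = 2, dt = 0.05))
  expect_equal(a, b, tolerance = 1e-9)
  expect_equal(a, 246, tolerance = 1e-9)
})

test_that("distance error implements the percent-excess formula", {
  expect_equal(distance_error(246, 246), 0)
  expect_equal(round(distance_error(246.76, 246), 2), 0.31)
  expect_equal(round(distance_error(252.86, 246), 2), 2.79)
  expect_error(distance_error(100, 0), "positive")
  expect_error(distance_error(-1, 246), "non-negative")
  # strictly increasing in the travelled distance, so medians commute
  tpl <- c(250, 260, 270, 300)
  expect_equal(distance_error(median(tpl), 246),
               median(distance_error(tpl, 246)))
})

test_that("cumulative rotation sums absolute heading changes", {
  line <- trajectory(0:10, 0:10, rep(0, 11))
  expect_equal(cumulative_rotation(line), 0)
  turn <- polyline_trajectory(rbind(c(0, 0), c(5, 0), c(5, 5)), speed = 1)
  expect_equal(cumulative_rotation(turn), 90)
  square <- polyline_trajectory(rbind(c(0, 0), c(4, 0), c(4, 4),
                                      c(0, 4), c(0, 0)), speed = 1)
  expect_equal(cumulative_rotation(square), 270)  # 3 interior turns
  jitter <- trajectory(0:5, c(0, 0.01, 0, 0.01, 0, 0.01), rep(0, 6))
  expect_error(cumulative_rotation(jitter), "degenerate")
})

test_that("rotation angle subtracts the ideal minimum and clamps at zero", {
  expect_equal(as.numeric(rotation_angle(70, 70)), 0)
  expect_equal(as.numeric(rotation_angle(100, 70)), 30)
  expect_warning(ra <- rotation_angle(60, 70), "clamped")
  expect_equal(as.numeric(ra), 0)
  expect_true(attr(ra, "clamped"))
  expect_error(rotation_angle(-1, 0), "non-negative")
})

test_that("visited alleys counts entry events with hysteresis", {
  geom <- sm_geom()
  direct <- ideal_trajectory(1, 3)
  va <- visited_alleys(direct, geom)
  expect_equal(va$sequence, c(1L, 3L))
  expect_equal(va$count, 2L)

  # never leaves the start alley
  stay <- polyline_trajectory(rbind(alley_position(1, geom, depth = 5),
                                    alley_position(1, geom, depth = 20)),
                              speed = 1)
  expect_equal(visited_alleys(stay, geom)$count, 1L)

  # tour through all five alleys, hub crossings in between
  pts <- list(alley_position(1, geom, depth = 5))
  for (k in 2:5) {
    pts <- c(pts, list(c(0, 0)), list(alley_position(k, geom, depth = 5)))
  }
  tour <- polyline_trajectory(do.call(rbind, pts), speed = 4)
  expect_equal(visited_alleys(tour, geom)$sequence, 1:5)

  # dip within the hysteresis band is not an exit; a deeper dip is
  ax <- function(d) alley_position(1, geom, depth = d)
  wobble <- polyline_trajectory(rbind(ax(5), ax(0.8), ax(5), ax(0.3), ax(5)),
                                speed = 0.5, dt = 0.1)
  expect_equal(visited_alleys(wobble, geom)$sequence, c(1L, 1L))

  far <- trajectory(0:1, c(0, 0), c(0, 400))
  expect_error(visited_alleys(far, geom), "out of maze bounds")
})

test_that("score_trial composes the metrics and applies the success rule", {
  geom <- sm_geom()
  sch <- build_schedule("T0", "even")
  spec_tr <- sch[sch$task == "free_training" & sch$trial_index == 1, ]
  m <- score_trial(ideal_trajectory(1, 3), spec_tr, geom)
  expect_true(m$success)
  expect_equal(m$n_alleys, 2L)
  expect_equal(m$de_pct, 0, tolerance = 1e-9)
  expect_equal(m$ra_deg, 0, tolerance = 1e-9)
  expect_equal(m$tpl_m, 246, tolerance = 1e-9)

  # idling out the clock in the start alley
  p <- alley_position(1, geom)
  idle <- trajectory(seq(0, 120, by = 1), p[1] + rep(c(0, 0.005), 61)[1:121],
                     rep(p[2], 121))
  mi <- score_trial(idle, spec_tr, geom)
  expect_false(mi$success)
  expect_equal(mi$n_alleys, 1L)

  # overlong recordings are rejected
  late <- trajectory(seq(0, 125, by = 1), seq(0, 12.5, by = 0.1)[1:126],
                     rep(0, 126))
  expect_error(score_trial(late, spec_tr, geom), "time limit")
})

test_that("successful trials end their alley sequence in a reward alley", {
  met <- sm_small_metrics()
  ok <- met[met$success, ]
  cohort <- sm_small_cohort()
  for (i in seq_len(nrow(ok))) {
    rw <- cohort$trials$reward_alleys[
      cohort$trials$traj_id == ok$traj_id[i]][[1]]
    expect_true(ok$terminal_alley[i] %in% rw)
  }
})
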