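test_that("agent profiles validate their parameters", {
  expect_error(agent_profile(heading_noise_sd = -1))
  expect_error(agent_profile(speed = 0))
  expect_error(agent_profile(learning_onset = 17))
  expect_error(agent_profile(pre_learning_excess = 0.5))
  expect_error(agent_profile("telepathic"))
})

test_that("noise-free agents reveal their strategy in testing trials", {
  geom <- sm_geom()
  sch <- build_schedule("T0", "even")
  spec <- sch[sch$task == "free_testing" & sch$trial_index == 1, ]
  terminal <- function(strategy) {
    prof <- agent_profile(strategy, heading_noise_sd = 0)
    tr <- simulate_trial(prof, spec, geom, seed = 5)
    locate(as.numeric(tr[nrow(tr), c("x_m", "y_m")]), geom)
  }
  expect_identical(terminal("egocentric"), "alley 1")   # start 4 replay
  expect_identical(terminal("allocentric"), "alley 3")  # landmark use
})

test_that("simulation is deterministic under a fixed seed and needs one", {
  geom <- sm_geom()
  sch <- build_schedule("T0", "even")
  spec <- sch[sch$task == "free_training" & sch$trial_index == 2, ]
  prof <- agent_profile("allocentric", heading_noise_sd = 4)
  a <- simulate_trial(prof, spec, geom, seed = 123)
  b <- simulate_trial(prof, spec, geom, seed = 123)
  expect_identical(a, b)
  c <- simulate_trial(prof, spec, geom, seed = 124)
  expect_false(identical(a, c))
  expect_error(simulate_trial(prof, spec, geom), "seed")
})

test_that("trajectories start in the start alley and respect the limit", {
  cohort <- sm_small_cohort()
  trials <- cohort$trials
  geom <- cohort$geometry
  idx <- sample(seq_len(nrow(trials)), 40)
  for (i in idx) {
    tr <- cohort$trajectories[[trials$traj_id[i]]]
    expect_lte(max(tr$t_s), trials$time_limit[i])
    expect_identical(locate(as.numeric(tr[1, c("x_m", "y_m")]), geom),
                     paste("alley", trials$start_alley[i]))
  }
})

test_that("cohort simulation produces the configured arm sizes", {
  # default arms mirror the study: 14 + 11 + 16 = 41 participants
  cfg <- cohort_config(seed = 1)
  expect_equal(sum(cfg$arms), 41L)
  cohort <- sm_small_cohort()
  expect_equal(nrow(cohort$metadata), 9L)
  expect_equal(sort(unique(cohort$metadata$group)),
               c("CP-Navigation", "CP-Regular", "TD"))
  # 21 free + 7 compelled trials per participant per session
  expect_equal(nrow(cohort$trials), 9L * 2L * 28L)
  expect_equal(nrow(cohort$truth), 9L * 2L)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(arms = c(TD = 0), seed = 1), "at least 1")
  expect_error(cohort_config(seed = 1, mixtures = list(
    "TD" = c(0.5, 0.5, 0.5, 0), "CP-Regular" = c(1, 0, 0, 0),
    "CP-Navigation" = c(1, 0, 0, 0))), "summing to 1")
  expect_error(cohort_config(arms = c(5, 5), seed = 1), "named")
  expect_error(cohort_config(), "seed")
})

test_that("an all-allocentric low-noise cohort is recovered downstream", {
  geom <- sm_geom()
  sch <- build_schedule("T0", "even")
  tests <- sch[sch$task == "free_testing", ]
  set.seed(1)
  seeds <- sample.int(1e6, 20 * 5)
  recovered <- vapply(1:20, function(a) {
    prof <- agent_profile("allocentric",
                          heading_noise_sd = runif(1, 1, 3))
    labels <- vapply(1:5, function(j) {
      tr <- simulate_trial(prof, tests[j, ], geom,
                           seed = seeds[(a - 1) * 5 + j])
      label_testing_trial(score_trial(tr, tests[j, ], geom),
                          tests[j, ])
    }, "")
    classify_participant(labels)$category
  }, "")
  expect_gte(mean(recovered == "allocentric"), 0.9)
})

test_that("cohort datasets round-trip through disk", {
  cohort <- sm_small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_error(write_cohort(cohort, dir), "collision")
  back <- read_cohort(dir, geom = cohort$geometry)
  expect_equal(back$metadata, cohort$metadata)
  expect_equal(back$truth, cohort$truth)
  tid <- cohort$trials$traj_id[10]
  expect_equal(back$trajectories[[tid]]$x_m,
               cohort$trajectories[[tid]]$x_m, tolerance = 1e-9)
  m1 <- score_cohort(cohort)
  m2 <- score_cohort(back)
  expect_equal(m2$tpl_m, m1$tpl_m, tolerance = 1e-6)
  expect_equal(m2$success, m1$success)

  # a missing trajectory file is reported by id
  file.remove(file.path(dir, "trajectories", paste0(tid, ".csv")))
  expect_error(read_cohort(dir), tid, fixed = TRUE)
})
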