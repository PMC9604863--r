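test_that("testing-trial labels follow the terminal-alley rule", {
  spec <- list(task = "free_testing")
  expect_identical(label_testing_trial(
    data.frame(success = TRUE, terminal_alley = 3L), spec), "AS")
  expect_identical(label_testing_trial(
    data.frame(success = TRUE, terminal_alley = 1L), spec), "ES")
  expect_identical(label_testing_trial(
    data.frame(success = FALSE, terminal_alley = NA_integer_), spec), "none")
  expect_error(label_testing_trial(
    data.frame(success = TRUE, terminal_alley = 3L),
    list(task = "free_training")), "free_testing")
})

test_that("participant classification matches its stated examples", {
  expect_identical(classify_participant(rep("AS", 5))$category, "allocentric")
  expect_identical(classify_participant(rep("ES", 5))$category, "egocentric")
  expect_identical(
    classify_participant(c("none", "none", "none", "AS", "ES"))$category,
    "no_strategy")
  expect_identical(
    classify_participant(c("AS", "ES", "AS", "ES", "AS"))$category,
    "shifter")
  # a run of 4 suffices ("more than three consecutive")
  expect_identical(
    classify_participant(c("AS", "AS", "AS", "AS", "ES"))$category,
    "allocentric")
  # a single-strategy record broken below a run of 4 falls to shifter
  expect_identical(
    classify_participant(c("AS", "AS", "AS", "none", "AS"))$category,
    "shifter")
  expect_error(classify_participant(rep("AS", 4)), "5")
  expect_error(classify_participant(c(rep("AS", 4), "XX")), "labels")
})

test_that("classification is total and matches the brute-force oracle", {
  seqs <- all_label_sequences()
  cats <- character(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    got <- classify_participant(seqs[i, ])$category
    expect_identical(got, oracle_classify(seqs[i, ]))
    cats[i] <- got
  }
  expect_setequal(unique(cats),
                  c("allocentric", "egocentric", "shifter", "no_strategy"))
})

test_that("success onset bins the stable-success trial", {
  expect_equal(success_onset(rep(TRUE, 16)),
               list(onset = 1L, bin = "first"))
  expect_equal(success_onset(c(FALSE, rep(TRUE, 15))),
               list(onset = 2L, bin = "second_third"))
  expect_equal(success_onset(c(rep(FALSE, 3), rep(TRUE, 13))),
               list(onset = 4L, bin = "fourth_plus"))
  expect_equal(success_onset(rep(FALSE, 16)),
               list(onset = NA_integer_, bin = "never"))
  # a late isolated failure pushes the onset past it
  flags <- rep(TRUE, 16); flags[10] <- FALSE
  expect_equal(success_onset(flags)$onset, 11L)
  expect_error(success_onset(rep(TRUE, 15)), "16")
})

test_that("compelled trials succeed only on a direct route", {
  spec <- list(task = "compelled_AS")
  expect_true(compelled_trial_success(
    data.frame(success = TRUE, n_alleys = 2L), spec))
  expect_false(compelled_trial_success(
    data.frame(success = TRUE, n_alleys = 3L), spec))
  expect_false(compelled_trial_success(
    data.frame(success = FALSE, n_alleys = 2L), spec))
  expect_error(compelled_trial_success(
    data.frame(success = TRUE, n_alleys = 2L),
    list(task = "free_training")), "compelled")
})

test_that("compelled percentage is the success share", {
  expect_equal(compelled_percent(c(TRUE, TRUE, TRUE, FALSE)), 75)
  expect_equal(compelled_percent(rep(TRUE, 4)), 100)
  expect_equal(compelled_percent(rep(FALSE, 3)), 0)
  expect_equal(compelled_percent(c(TRUE, FALSE, TRUE)),
               compelled_percent(c(FALSE, TRUE, TRUE)))
  expect_error(compelled_percent(logical(0)), "no trials")
})

test_that("classify_cohort recovers simulated strategies end to end", {
  met <- sm_small_metrics()
  strat <- classify_cohort(met)
  truth <- sm_small_cohort()$truth
  cmp <- merge(strat, truth[, c("pid", "session", "strategy")],
               by = c("pid", "session"))
  non_shifter <- cmp[cmp$strategy != "shifter", ]
  expect_gte(mean(non_shifter$category == non_shifter$strategy), 0.8)
  # shifters may legitimately resolve to one of their two strategies
  sh <- cmp[cmp$strategy == "shifter", ]
  expect_true(all(sh$category %in% c("shifter", "allocentric",
                                     "egocentric", "no_strategy")))
})
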