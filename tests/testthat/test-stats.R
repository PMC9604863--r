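test_that("chi-square uniformity reproduces hand-computed statistics", {
  r <- chisq_gof_uniform(c(10, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # (21-13.5)^2/13.5 * 2 = 8.333...
  r <- chisq_gof_uniform(c(21, 6))
  expect_equal(r$statistic, 2 * 7.5^2 / 13.5, tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_error(chisq_gof_uniform(c(5)), ">= 2")
})

test_that("contingency chi-square uses no continuity correction", {
  tab <- rbind(c(4, 4, 3), c(9, 0, 7))
  r <- chisq_contingency(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - exp_tab)^2 / exp_tab),
               tolerance = 1e-10)
  expect_equal(r$df, 2)
  # independence: proportional rows give statistic 0
  prop <- rbind(c(10, 20), c(5, 10))
  expect_equal(chisq_contingency(prop)$statistic, 0)
  expect_equal(chisq_contingency(prop)$p, 1)
  expect_error(chisq_contingency(rbind(c(1, 0), c(2, 0))), "margin")
  expect_error(chisq_contingency(matrix(1:3, 1)), "2 x 2")
})

test_that("contingency statistic is invariant to row/column permutation", {
  set.seed(5)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 8) + 1, 2, 3)
    a <- chisq_contingency(tab)$statistic
    b <- chisq_contingency(tab[2:1, c(2, 3, 1)])$statistic
    expect_equal(a, b)
  }
})

test_that("Kruskal-Wallis matches the closed-form rank statistic", {
  r <- kruskal_groups(c(1, 2, 3, 4), rep(c("a", "b"), each = 2))
  expect_equal(r$statistic, 2.4, tolerance = 1e-10)  # rank sums 3 and 7
  expect_equal(r$df, 1)
  same <- kruskal_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(kruskal_groups(1:4, rep("a", 4)), ">= 2 groups")
})

test_that("Mann-Whitney post hocs: exact enumeration and Bonferroni", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  ph <- mannwhitney_bonferroni(vals, grp)
  expect_equal(nrow(ph), 3L)
  p12 <- ph$p_raw[ph$group1 == "g1" & ph$group2 == "g2"]
  # enumeration oracle: all choose(6,3) assignments of {1..6} ranks
  combs <- combn(6, 3)
  w_obs <- sum(rank(vals[1:6])[1:3]) - 3 * 4 / 2
  w_all <- apply(combs, 2, function(ix) sum(seq_len(6)[ix]) - 6)
  p_or <- mean(abs(w_all - 4.5) >= abs(w_obs - 4.5))
  expect_equal(p12, p_or, tolerance = 1e-10)
  expect_equal(p12, 0.1, tolerance = 1e-10)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))
  expect_true(all(ph$p_adj >= ph$p_raw))

  same <- mannwhitney_bonferroni(rep(1:4, 2), rep(c("a", "b"), each = 4))
  expect_equal(same$p_adj, 1)
})

test_that("paired Wilcoxon: exact tied-case enumeration and invariances", {
  r <- wilcoxon_paired(rep(1, 5), rep(0, 5))
  expect_equal(r$statistic, 0)
  # oracle: 2^5 equally likely sign assignments, W+ = 0 only once
  signs <- expand.grid(rep(list(c(-1, 1)), 5))
  w <- apply(signs, 1, function(s) sum(rank(rep(1, 5))[s > 0]))
  expect_equal(r$p, 2 * mean(w <= 0))
  expect_equal(r$p, 0.0625)

  expect_warning(d <- wilcoxon_paired(1:4, 1:4), "zero")
  expect_equal(d$p, 1)

  set.seed(9)
  x <- rnorm(10); y <- rnorm(10)
  a <- wilcoxon_paired(x, y)
  b <- wilcoxon_paired(x + 5, y + 5)  # shift both members of every pair
  expect_equal(a$p, b$p)
  expect_equal(a$statistic, b$statistic)
})

test_that("exact signed-rank p agrees with the reference implementation", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_paired(x, y)
    ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("delta scores are elementwise T1 - T0", {
  expect_equal(delta_scores(c(0, 1), c(1, 3)), c(1, 2))
  expect_equal(delta_scores(1:3, 1:3), rep(0, 3))
  expect_equal(delta_scores(c(0, 1), c(1, 3)),
               -delta_scores(c(1, 3), c(0, 1)))
  expect_error(delta_scores(1:3, 1:2), "equal length")
})

test_that("the full statistical battery runs on a simulated cohort", {
  cohort <- sm_small_cohort()
  met <- sm_small_metrics()
  strat <- classify_cohort(met)
  demo <- demographic_statistics(cohort$metadata, cohort$zscores)
  expect_true(is.numeric(demo$cp_uniformity$gender$p))
  expect_true(all(vapply(demo$zscores, function(z)
    z$kruskal_wallis$p >= 0 && z$kruskal_wallis$p <= 1, TRUE)))
  nav <- suppressWarnings(
    navigation_statistics(met, strat, stable_trials = c(T0 = 7, T1 = 2)))
  expect_equal(nav$at_stable_trial$T0$stable_trial, 7)
  for (p in c("n_alleys", "tpl_m", "de_pct", "ra_deg")) {
    pv <- nav$at_stable_trial$T0[[p]]$kruskal_wallis$p
    expect_true(pv >= 0 && pv <= 1)
  }
  expect_true(all(vapply(nav$compelled$T0, function(x)
    x$kruskal_wallis$p >= 0, TRUE)))
})
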