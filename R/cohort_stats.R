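# The full group-comparison battery applied to a scored cohort:
# demographics, visuospatial Z-scores, navigation metrics at the
# stabilization trial, success rates and compelled-task scores.

unwrap_test <- function(x) if (inherits(x, "sm_test")) unclass(x) else x

kw_with_posthoc <- function(values, groups) {
  kw <- kruskal_groups(values, groups)
  list(kruskal_wallis = unwrap_test(kw),
       post_hoc = mannwhitney_bonferroni(values, groups))
}

#' Demographic and visuospatial statistics of a cohort
#'
#' Runs the demographic battery: chi-square uniformity of gender and
#' MACS within the pooled CP participants; chi-square contingency of
#' gender (all groups) and GMFCS/MACS (CP arms); Kruskal-Wallis on age
#' and on the Raven, Corsi and Labyrinth Z-scores with
#' Bonferroni-corrected Mann-Whitney post hocs; paired Wilcoxon on the
#' Corsi and Labyrinth Z-scores between sessions per group; and
#' Kruskal-Wallis on the T1 - T0 delta Z-scores across groups.
#'
#' @param metadata Participant table (`pid`, `group`, `gender`, `age`,
#'   `gmfcs`, `macs`).
#' @param zscores Z-score table (`pid`, `group`, `raven_T0`, `corsi_T0`,
#'   `corsi_T1`, `labyrinth_T0`, `labyrinth_T1`). Deltas are always
#'   recomputed here, never read from input.
#' @return Nested list of test results (JSON-serializable).
#' @export
demographic_statistics <- function(metadata, zscores) {
  cp <- metadata[grepl("^CP", metadata$group), ]
  out <- list()
  out$cp_uniformity <- list(
    gender = unwrap_test(chisq_gof_uniform(
      as.vector(table(factor(cp$gender, c("M", "F")))))),
    macs = if (any(!is.na(cp$macs))) unwrap_test(chisq_gof_uniform(
      as.vector(table(factor(cp$macs, c("I", "II", "III")))))) else NULL,
    gmfcs = if (any(!is.na(cp$gmfcs))) unwrap_test(chisq_gof_uniform(
      as.vector(table(factor(cp$gmfcs, c("I", "II", "III")))))) else NULL)
  gender_tab <- table(metadata$group, metadata$gender)
  out$group_contingency <- list(
    gender = unwrap_test(chisq_contingency(gender_tab)))
  if (any(!is.na(cp$gmfcs)) && length(unique(cp$group)) >= 2) {
    gm <- table(cp$group, factor(cp$gmfcs, c("I", "II", "III")))
    gm <- gm[, colSums(gm) > 0, drop = FALSE]
    out$group_contingency$gmfcs <-
      tryCatch(unwrap_test(chisq_contingency(gm)), error = function(e) NULL)
    mc <- table(cp$group, factor(cp$macs, c("I", "II", "III")))
    mc <- mc[, colSums(mc) > 0, drop = FALSE]
    out$group_contingency$macs <-
      tryCatch(unwrap_test(chisq_contingency(mc)), error = function(e) NULL)
  }
  out$age <- kw_with_posthoc(metadata$age, metadata$group)

  z <- merge(zscores, metadata[, c("pid", "group")], by = "pid")
  z$group <- z$group.x
  for (v in c("raven_T0", "corsi_T0", "corsi_T1", "labyrinth_T0",
              "labyrinth_T1"))
    out$zscores[[v]] <- kw_with_posthoc(z[[v]], z$group)
  out$t0_vs_t1 <- lapply(split(z, z$group), function(g)
    list(corsi = unwrap_test(wilcoxon_paired(g$corsi_T0, g$corsi_T1)),
         labyrinth = unwrap_test(wilcoxon_paired(g$labyrinth_T0,
                                                 g$labyrinth_T1))))
  out$delta <- list(
    corsi = kw_with_posthoc(delta_scores(z$corsi_T0, z$corsi_T1), z$group),
    labyrinth = kw_with_posthoc(delta_scores(z$labyrinth_T0,
                                             z$labyrinth_T1), z$group))
  out
}

#' Navigation statistics of a scored cohort
#'
#' For each session: Kruskal-Wallis across groups of each learning
#' parameter (visited alleys, TPL, DE, RA) at that session's
#' stabilization trial; per-group paired Wilcoxon of the training
#' success rate between sessions; Kruskal-Wallis of the T1 - T0 deltas
#' of the learning parameters (evaluated at each session's own
#' stabilization trial); and the compelled-task battery (Kruskal-Wallis
#' across groups, Wilcoxon between sessions, delta Kruskal-Wallis).
#'
#' @param metrics Scored metrics table ([score_cohort()]).
#' @param strategies Per-participant summary ([classify_cohort()]).
#' @param stable_trials Named numeric vector: stabilization trial per
#'   session (e.g. `c(T0 = 7, T1 = 2)`).
#' @return Nested list of test results (JSON-serializable).
#' @export
navigation_statistics <- function(metrics, strategies,
                                  stable_trials = c(T0 = 7, T1 = 2)) {
  params <- c("n_alleys", "tpl_m", "de_pct", "ra_deg")
  sessions <- intersect(names(stable_trials), unique(metrics$session))
  out <- list()
  at_stable <- list()
  for (ses in sessions) {
    k <- stable_trials[[ses]]
    sl <- metrics[metrics$task == "free_training" &
                    metrics$session == ses & metrics$trial_index == k, ]
    at_stable[[ses]] <- sl
    out$at_stable_trial[[ses]] <- c(
      list(stable_trial = k),
      lapply(stats::setNames(params, params), function(p)
        kw_with_posthoc(sl[[p]], sl$group)))
  }
  if (length(sessions) == 2L) {
    tr <- metrics[metrics$task == "free_training", ]
    rate <- stats::aggregate(success ~ pid + group + session, tr, mean)
    wide <- merge(rate[rate$session == sessions[1], ],
                  rate[rate$session == sessions[2], ],
                  by = c("pid", "group"), suffixes = c("_a", "_b"))
    out$success_rate_t0_vs_t1 <- lapply(split(wide, wide$group), function(g)
      unwrap_test(wilcoxon_paired(g$success_a, g$success_b)))
    both <- merge(at_stable[[sessions[1]]], at_stable[[sessions[2]]],
                  by = c("pid", "group"), suffixes = c("_a", "_b"))
    out$delta_at_stable <- lapply(stats::setNames(params, params),
      function(p) kw_with_posthoc(
        delta_scores(both[[paste0(p, "_a")]], both[[paste0(p, "_b")]]),
        both$group))
  }
  for (ses in unique(strategies$session)) {
    st <- strategies[strategies$session == ses, ]
    out$compelled[[ses]] <- list(
      imposed_AS = kw_with_posthoc(st$pct_compelled_AS, st$group),
      imposed_ES = kw_with_posthoc(st$pct_compelled_ES, st$group))
  }
  if (length(sessions) == 2L) {
    sw <- merge(strategies[strategies$session == sessions[1], ],
                strategies[strategies$session == sessions[2], ],
                by = c("pid", "group"), suffixes = c("_a", "_b"))
    out$compelled_t0_vs_t1 <- lapply(split(sw, sw$group), function(g)
      list(imposed_AS = unwrap_test(
             wilcoxon_paired(g$pct_compelled_AS_a, g$pct_compelled_AS_b)),
           imposed_ES = unwrap_test(
             wilcoxon_paired(g$pct_compelled_ES_a, g$pct_compelled_ES_b))))
    out$compelled_delta <- list(
      imposed_AS = kw_with_posthoc(
        delta_scores(sw$pct_compelled_AS_a, sw$pct_compelled_AS_b),
        sw$group),
      imposed_ES = kw_with_posthoc(
        delta_scores(sw$pct_compelled_ES_a, sw$pct_compelled_ES_b),
        sw$group))
  }
  out
}
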