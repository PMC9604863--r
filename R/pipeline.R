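# End-to-end orchestration: simulate or ingest a dataset, score every
# trial, classify strategies, run the learning and cohort statistics,
# and emit a structured report bundle.

#' Run the full analysis pipeline
#'
#' Either simulates a cohort from `config` or loads one from `data_dir`
#' ([read_cohort()] layout), then scores all trials, classifies
#' strategies, builds learning curves, detects stabilization trials per
#' group and session, and runs the statistical battery. All stage
#' outputs are written to `out_dir` as plain-text files:
#' `metrics.csv`, `strategies.csv`, `compelled.csv`,
#' `learning_curves.csv`, `stabilization.json`, `stats_report.json` and
#' `manifest.json`.
#'
#' The pipeline is a pure function of (dataset, configuration, seed):
#' rerunning with identical inputs reproduces the metric tables
#' byte-for-byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()]; required when simulating.
#' @param data_dir Dataset directory; when given, the cohort is loaded
#'   instead of simulated.
#' @param geom A [star_maze()] geometry.
#' @param alpha Significance level for stabilization detection.
#' @return Invisibly, a list with `cohort`, `metrics`, `strategies`,
#'   `curves`, `stabilization`, `stats`, `manifest`.
#' @export
run_pipeline <- function(out_dir, config = NULL, data_dir = NULL,
                         geom = star_maze(), alpha = 0.05) {
  if (is.null(data_dir) && is.null(config))
    stop("provide either a cohort_config (simulate) or a data_dir (ingest)",
         call. = FALSE)
  cohort <- if (!is.null(data_dir)) read_cohort(data_dir, geom)
            else simulate_cohort(config, geom)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  metrics <- score_cohort(cohort)
  strategies <- classify_cohort(merge_group(metrics, cohort$metadata))
  curves <- group_curves(metrics)

  stab <- list()
  for (ses in unique(metrics$session)) {
    for (g in unique(metrics$group)) {
      series <- training_series(metrics, group = g, session = ses)
      if (nrow(series[[1]]) < 2L) next
      st <- stabilization_trial(series, alpha = alpha)
      stab[[ses]][[g]] <- list(stable_trial = st$stable_trial,
                               alpha = alpha,
                               min_p_at_stable = if (!is.na(st$stable_trial))
                                 min(st$p_trace$p[st$p_trace$k ==
                                                    st$stable_trial])
                                 else NA)
    }
  }
  stable_by_session <- vapply(stab, function(s) {
    ks <- vapply(s, function(g) as.numeric(g$stable_trial), 0)
    if (all(is.na(ks))) NA_real_ else max(ks, na.rm = TRUE)
  }, 0)

  stats_report <- list(
    demographics = demographic_statistics(cohort$metadata, cohort$zscores),
    navigation = navigation_statistics(
      metrics, strategies,
      stable_trials = stable_by_session[!is.na(stable_by_session)]))

  manifest <- list(
    package_version = as.character(utils::packageVersion("starmaze")),
    source = if (!is.null(data_dir)) data_dir else "simulated",
    seed = cohort$manifest$seed,
    config_hash = cohort$manifest$config_hash,
    n_participants = length(unique(metrics$pid)),
    n_trials_scored = nrow(metrics),
    outputs = c("metrics.csv", "strategies.csv", "compelled.csv",
                "learning_curves.csv", "stabilization.json",
                "stats_report.json", "manifest.json"))

  write_num_csv(metrics, file.path(out_dir, "metrics.csv"))
  write_num_csv(strategies[, c("pid", "group", "session", "category",
                               "onset", "onset_bin")],
                file.path(out_dir, "strategies.csv"))
  write_num_csv(strategies[, c("pid", "group", "session",
                               "pct_compelled_AS", "pct_compelled_ES")],
                file.path(out_dir, "compelled.csv"))
  write_num_csv(curves, file.path(out_dir, "learning_curves.csv"))
  jsonlite::write_json(stab, file.path(out_dir, "stabilization.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(stats_report,
                       file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, metrics = metrics,
                 strategies = strategies, curves = curves,
                 stabilization = stab, stats = stats_report,
                 manifest = manifest))
}

# Attach the group column when a metrics table lacks it.
merge_group <- function(metrics, metadata) {
  if ("group" %in% names(metrics)) return(metrics)
  merge(metrics, metadata[, c("pid", "group")], by = "pid")
}

# Deterministic CSV writer: fixed significant digits so byte-identity
# across runs is well-defined.
write_num_csv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 10,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render report tables from a pipeline bundle
#'
#' Produces the human-readable summary tables of a run: demographics per
#' group, Z-score medians (IQR) per group and session, the learning
#' parameters at the stabilization trial with their theoretical best
#' values (2 visited alleys, 246 m TPL, 0 % DE, 0 deg RA), the strategy
#' cross-tab (counts and percentages per group and session), and the
#' compelled-task success medians.
#'
#' @param bundle The list returned by [run_pipeline()].
#' @return A named list of data frames: `demographics`, `zscores`,
#'   `stable_metrics`, `strategy_crosstab`, `compelled`.
#' @export
render_tables <- function(bundle) {
  for (need in c("cohort", "metrics", "strategies", "stabilization"))
    if (is.null(bundle[[need]]))
      stop("incomplete bundle: missing stage '", need, "'", call. = FALSE)
  md <- bundle$cohort$metadata
  zs <- bundle$cohort$zscores
  metrics <- bundle$metrics
  strategies <- bundle$strategies

  groups <- sort(unique(md$group))
  demo <- do.call(rbind, lapply(groups, function(g) {
    m <- md[md$group == g, ]
    data.frame(group = g, n = nrow(m),
               males = sum(m$gender == "M"), females = sum(m$gender == "F"),
               age_mean = round(mean(m$age), 1),
               age_sd = round(stats::sd(m$age), 1),
               gmfcs_I_II_III = paste(table(factor(m$gmfcs,
                                                   c("I", "II", "III"))),
                                      collapse = "/"),
               macs_I_II_III = paste(table(factor(m$macs,
                                                  c("I", "II", "III"))),
                                     collapse = "/"),
               stringsAsFactors = FALSE)
  }))

  med_iqr <- function(v) sprintf("%.2f (%.2f)", stats::median(v),
                                 stats::IQR(v))
  ztab <- do.call(rbind, lapply(groups, function(g) {
    z <- zs[zs$group == g, ]
    data.frame(group = g,
               raven_T0 = med_iqr(z$raven_T0),
               corsi_T0 = med_iqr(z$corsi_T0), corsi_T1 = med_iqr(z$corsi_T1),
               labyrinth_T0 = med_iqr(z$labyrinth_T0),
               labyrinth_T1 = med_iqr(z$labyrinth_T1),
               stringsAsFactors = FALSE)
  }))

  th <- c(n_alleys = 2, tpl_m = 246, de_pct = 0, ra_deg = 0)
  stable_rows <- list()
  for (ses in names(bundle$stabilization)) {
    ks <- vapply(bundle$stabilization[[ses]],
                 function(g) as.numeric(g$stable_trial), 0)
    k <- if (all(is.na(ks))) NA else max(ks, na.rm = TRUE)
    if (is.na(k)) next
    sl <- metrics[metrics$task == "free_training" &
                    metrics$session == ses & metrics$trial_index == k, ]
    for (p in names(th)) {
      row <- data.frame(parameter = p, session = ses, stable_trial = k,
                        th_value = th[[p]], stringsAsFactors = FALSE)
      for (g in groups)
        row[[g]] <- if (sum(sl$group == g))
          med_iqr(sl[[p]][sl$group == g]) else "n=0"
      stable_rows[[paste(ses, p)]] <- row
    }
  }
  stable_metrics <- do.call(rbind, stable_rows)
  if (!is.null(stable_metrics)) rownames(stable_metrics) <- NULL

  cats <- c("allocentric", "egocentric", "shifter", "no_strategy")
  cross <- do.call(rbind, lapply(split(strategies,
                                       list(strategies$group,
                                            strategies$session),
                                       drop = TRUE), function(s) {
    counts <- table(factor(s$category, cats))
    data.frame(group = s$group[1], session = s$session[1],
               n = nrow(s), category = cats,
               count = as.vector(counts),
               percent = round_half_up(100 * as.vector(counts) /
                                         max(1, nrow(s))),
               stringsAsFactors = FALSE)
  }))
  rownames(cross) <- NULL

  compelled <- do.call(rbind, lapply(split(strategies,
                                           list(strategies$group,
                                                strategies$session),
                                           drop = TRUE), function(s) {
    data.frame(group = s$group[1], session = s$session[1], n = nrow(s),
               pct_AS = med_iqr(s$pct_compelled_AS),
               pct_ES = med_iqr(s$pct_compelled_ES),
               stringsAsFactors = FALSE)
  }))
  rownames(compelled) <- NULL

  list(demographics = demo, zscores = ztab, stable_metrics = stable_metrics,
       strategy_crosstab = cross, compelled = compelled)
}

#' Plot group learning curves
#'
#' Median and interquartile ribbon of each learning parameter over the
#' 16 training trials, per group, faceted by parameter and session.
#' Requires ggplot2.
#'
#' @param curves Tidy curve table from [group_curves()].
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = trial, y = median,
                               colour = group, fill = group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = median - iqr / 2,
                                      ymax = median + iqr / 2),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(parameter ~ session, scales = "free_y") +
    ggplot2::labs(x = "training trial", y = "median (IQR ribbon)")
}
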