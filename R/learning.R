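# Learning curves over the 16 training trials and Friedman-based
# stabilization detection.

#' Friedman test on a participants-by-trials matrix
#'
#' Repeated-measures rank test for one learning parameter: rows are
#' participants, columns are trials. Ranks are computed within each
#' participant with average ranks for ties; the chi-square approximation
#' with k - 1 degrees of freedom is used (no tie correction, matching the
#' classical statistic). A Monte-Carlo permutation p-value (permuting
#' trial order within participants) is available for small samples where
#' the chi-square approximation is doubtful.
#'
#' @param mat Numeric matrix, participants x trials; >= 2 rows and >= 2
#'   columns, no missing cells.
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param nperm Number of permutations for `method = "permutation"`.
#' @return A list with `statistic`, `df`, `p`, `method`.
#' @export
friedman_rank_test <- function(mat, method = c("chisq", "permutation"),
                               nperm = 2000) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L || nrow(mat) < 2L)
    stop("Friedman test needs >= 2 participants and >= 2 repeated trials",
         call. = FALSE)
  if (anyNA(mat))
    stop("Friedman test requires complete cases (listwise-delete upstream)",
         call. = FALSE)
  ft <- stats::friedman.test(mat)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {
    # every participant fully tied across trials: no evidence of change
    stat <- 0
    p <- 1
  }
  out <- list(statistic = stat, df = unname(ft$parameter),
              p = p, method = "chisq")
  if (method == "permutation") {
    stat_of <- function(m) {
      s <- unname(stats::friedman.test(m)$statistic)
      if (is.nan(s)) 0 else s
    }
    obs <- out$statistic
    perm <- replicate(nperm, {
      pm <- t(apply(mat, 1L, sample))
      stat_of(pm)
    })
    out$p <- (1 + sum(perm >= obs - 1e-12)) / (nperm + 1)
    out$method <- "permutation"
  }
  out
}

#' Detect the stabilization trial of the learning curves
#'
#' Performance is "stable from trial k" when the Friedman test over
#' trials k..16 is non-significant simultaneously for all supplied
#' learning parameters (visited alleys, TPL, DE, RA). The stabilization
#' trial is the smallest such k. The search stops at k = 13 so that at
#' least 4 repeated trials always enter each test.
#'
#' @param series Named list of numeric matrices (one per learning
#'   parameter), each participants x 16 training trials.
#' @param alpha Significance level (default 0.05).
#' @param k_max Largest window start searched.
#' @return A list with `stable_trial` (integer, or `NA` when the curves
#'   never stabilize), `alpha`, and `p_trace` (data frame of per-window,
#'   per-parameter Friedman p-values, including the minimum across
#'   parameters).
#' @export
stabilization_trial <- function(series, alpha = 0.05, k_max = 13L) {
  stopifnot(is.list(series), length(series) >= 1L)
  lapply(series, function(m)
    if (ncol(as.matrix(m)) != 16L)
      stop("each learning-parameter matrix must have 16 trial columns",
           call. = FALSE))
  trace <- list()
  stable <- NA_integer_
  for (k in seq_len(k_max)) {
    ps <- vapply(series, function(m)
      friedman_rank_test(as.matrix(m)[, k:16, drop = FALSE])$p, 0)
    trace[[k]] <- data.frame(k = k, parameter = names(ps), p = unname(ps),
                             stringsAsFactors = FALSE)
    if (all(ps > alpha)) {
      stable <- k
      break
    }
  }
  list(stable_trial = stable, alpha = alpha,
       p_trace = do.call(rbind, trace))
}

#' Verify stability from a fixed trial onward
#'
#' Companion to [stabilization_trial()]: rather than searching for the
#' smallest stable window, tests whether performance is already stable
#' from a given trial (for instance the previously published 5th and 7th
#' stabilization trials), reporting the minimum Friedman p-value across
#' parameters.
#'
#' @inheritParams stabilization_trial
#' @param k First trial of the tested window.
#' @return A list with `k`, `p_values` (named per parameter), `min_p` and
#'   `stable` (logical, all p > alpha).
#' @export
verify_stability <- function(series, k, alpha = 0.05) {
  ps <- vapply(series, function(m)
    friedman_rank_test(as.matrix(m)[, k:16, drop = FALSE])$p, 0)
  list(k = k, p_values = ps, min_p = min(ps), stable = all(ps > alpha))
}

#' Per-group learning curves (median and IQR per trial)
#'
#' @param metrics Scored metrics table ([score_cohort()]); only
#'   `free_training` rows are used.
#' @param parameters Metric columns to summarize.
#' @return Tidy data frame: `group`, `session`, `parameter`, `trial`,
#'   `median`, `iqr`, `n`.
#' @export
group_curves <- function(metrics,
                         parameters = c("n_alleys", "tpl_m", "de_pct",
                                        "ra_deg")) {
  tr <- metrics[metrics$task == "free_training", ]
  miss <- stats::aggregate(trial_index ~ pid + session, tr,
                           FUN = length)
  bad <- miss[miss$trial_index < 16L, ]
  if (nrow(bad)) {
    warning("excluding participants with missing training trials: ",
            paste(unique(bad$pid), collapse = ", "), call. = FALSE)
    drop <- paste(tr$pid, tr$session) %in% paste(bad$pid, bad$session)
    tr <- tr[!drop, ]
  }
  out <- list()
  for (p in parameters) {
    agg <- stats::aggregate(tr[[p]],
                            by = list(group = tr$group, session = tr$session,
                                      trial = tr$trial_index),
                            FUN = function(v)
                              c(median = stats::median(v),
                                iqr = stats::IQR(v), n = length(v)))
    out[[p]] <- data.frame(group = agg$group, session = agg$session,
                           parameter = p, trial = agg$trial,
                           median = agg$x[, "median"], iqr = agg$x[, "iqr"],
                           n = agg$x[, "n"], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group, res$session, res$parameter, res$trial), ]
}

# participants x 16 matrices of the four learning parameters for one
# group/session slice of a metrics table.
training_series <- function(metrics, group = NULL, session = NULL,
                            parameters = c("n_alleys", "tpl_m", "de_pct",
                                           "ra_deg")) {
  tr <- metrics[metrics$task == "free_training", ]
  if (!is.null(group)) tr <- tr[tr$group %in% group, ]
  if (!is.null(session)) tr <- tr[tr$session == session, ]
  pids <- unique(tr$pid)
  lapply(stats::setNames(parameters, parameters), function(p) {
    m <- vapply(pids, function(id) {
      rows <- tr[tr$pid == id, ]
      rows[[p]][order(rows$trial_index)]
    }, numeric(16))
    t(m)
  })
}
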