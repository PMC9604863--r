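# Nonparametric group-comparison battery: chi-square uniformity and
# contingency tests, Kruskal-Wallis with Bonferroni-corrected
# Mann-Whitney post hocs, paired Wilcoxon, delta scores.

sm_test <- function(test, statistic, df = NA_real_, p, ...) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), ...),
            class = "sm_test")
}

#' @export
print.sm_test <- function(x, ...) {
  cat(x$test, ": statistic = ", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Chi-square goodness-of-fit test against a uniform distribution
#'
#' Pearson chi-square of observed category counts against equal expected
#' counts (df = k - 1); used to check the uniformity of demographic
#' distributions (e.g. gender, MACS levels) within a cohort.
#'
#' @param counts Non-negative integer vector of category counts (>= 2
#'   categories, positive total).
#' @return An `sm_test` with `statistic`, `df`, `p`, `counts`.
#' @examples
#' chisq_gof_uniform(c(21, 6))$p   # 0.004: gender split of the CP cohort
#' @export
chisq_gof_uniform <- function(counts) {
  if (length(counts) < 2L || sum(counts) <= 0)
    stop("need >= 2 categories with a positive total", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts))
  sm_test("chi-square uniformity", ct$statistic, ct$parameter, ct$p.value,
          counts = counts)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Expected counts are the usual row x column products over the total;
#' df = (r - 1)(c - 1); no continuity correction (the correction is not
#' applied in the reference analyses this battery mirrors).
#'
#' @param tab Matrix of non-negative counts, at least 2 x 2, with no zero
#'   row or column margin.
#' @return An `sm_test` with `statistic`, `df`, `p`, `expected`.
#' @export
chisq_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row/column margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  sm_test("chi-square contingency", ct$statistic, ct$parameter, ct$p.value,
          expected = ct$expected)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction, p-value from the
#' chi-square approximation with k - 1 df; reports per-group medians and
#' IQRs alongside.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (>= 2 non-empty groups).
#' @return An `sm_test` with `statistic`, `df`, `p`, `medians`, `iqrs`,
#'   `n`.
#' @export
kruskal_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (any(tabulate(groups) == 0L)) stop("empty group", call. = FALSE)
  kt <- stats::kruskal.test(values, groups)
  if (is.nan(kt$statistic)) {
    # all observations identical: no evidence of a group difference
    kt$statistic <- 0
    kt$p.value <- 1
  }
  sm_test("Kruskal-Wallis", kt$statistic, kt$parameter, kt$p.value,
          medians = tapply(values, groups, stats::median),
          iqrs = tapply(values, groups, stats::IQR),
          n = as.vector(table(groups)))
}

#' Bonferroni-corrected Mann-Whitney pairwise post hocs
#'
#' All k(k-1)/2 two-sided Mann-Whitney (Wilcoxon rank-sum) tests between
#' groups; exact p-values when both groups have n <= 20 and the data are
#' tie-free, otherwise the normal approximation with tie correction.
#' Adjusted p = min(1, raw p x number of comparisons performed).
#'
#' @inheritParams kruskal_groups
#' @return Data frame with one row per pair: `group1`, `group2`, `U`
#'   (rank-sum W statistic), `p_raw`, `p_adj`, `exact`.
#' @export
mannwhitney_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    x <- values[groups == pairs[1, j]]
    y <- values[groups == pairs[2, j]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    use_exact <- length(x) <= 20 && length(y) <= 20 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                              correct = !use_exact))
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               U = unname(wt$statistic), p_raw = wt$p.value,
               p_adj = min(1, wt$p.value * m), exact = use_exact,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Exact null distribution of the positive signed-rank sum W+ conditional
# on the observed |difference| ranks (average ranks for ties): the
# generating polynomial prod_i (1 + x^(2 r_i)) / 2^n over doubled ranks,
# so tied half-ranks stay integral.
signed_rank_null <- function(ranks2) {
  probs <- 1
  offset <- 0L  # probs[i+1] = P(2 W+ = i)
  for (r in ranks2) {
    n_old <- length(probs)
    new <- numeric(n_old + r)
    new[seq_len(n_old)] <- probs / 2
    new[r + seq_len(n_old)] <- new[r + seq_len(n_old)] + probs / 2
    probs <- new
  }
  probs
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired measurements (e.g. a Z-score at
#' T0 vs T1). Zero differences are dropped (and counted); ties among the
#' absolute differences receive average ranks. For n <= 25 non-zero
#' pairs the p-value is exact, computed from the full sign-flip null
#' distribution conditional on the observed ranks; larger samples use
#' the normal approximation with tie correction and continuity
#' correction. When every difference is zero the result is the
#' degenerate p = 1 with a warning.
#'
#' @param t0,t1 Paired numeric vectors of equal length.
#' @return An `sm_test` with `statistic` (W+, the positive rank sum),
#'   `p`, `n_used`, `n_zero`, `exact`.
#' @export
wilcoxon_paired <- function(t0, t1) {
  if (length(t0) != length(t1))
    stop("paired samples must have equal length", call. = FALSE)
  keep <- !(is.na(t0) | is.na(t1))
  d <- t1[keep] - t0[keep]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; degenerate p = 1",
            call. = FALSE)
    return(sm_test("Wilcoxon signed-rank", NA_real_, p = 1,
                   n_used = 0L, n_zero = n_zero, exact = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= 25L) {
    null <- signed_rank_null(round(2 * r))
    w2 <- round(2 * w_pos)
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  sm_test("Wilcoxon signed-rank", w_pos, p = p, n_used = n,
          n_zero = n_zero, exact = exact)
}

#' Paired delta scores (T1 - T0)
#'
#' @param t0,t1 Paired numeric vectors of equal length.
#' @return Elementwise `t1 - t0`.
#' @export
delta_scores <- function(t0, t1) {
  if (length(t0) != length(t1))
    stop("paired samples must have equal length", call. = FALSE)
  t1 - t0
}
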