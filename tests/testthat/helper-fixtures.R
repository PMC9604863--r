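# Shared fixtures and independent oracles for the test suite.

sm_geom <- function() star_maze()

# Constant-speed samples along a polyline (piecewise-linear path):
# builds trajectory fixtures whose true length and turns are known.
polyline_trajectory <- function(points, speed = 4, dt = 0.1) {
  pts <- as.matrix(points)
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  seg <- seg[keep, , drop = FALSE]
  len <- len[keep]
  pts <- pts[c(TRUE, keep), , drop = FALSE]
  cum <- c(0, cumsum(len))
  total <- sum(len)
  s <- sort(unique(c(seq(0, total, by = speed * dt), cum, total)))
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(len))
  f <- (s - cum[i]) / len[i]
  xy <- pts[i, , drop = FALSE] + seg[i, , drop = FALSE] * f
  trajectory(t_s = s / speed, x_m = xy[, 1], y_m = xy[, 2])
}

# Trajectory along the ideal route start -> reward.
ideal_trajectory <- function(start, reward, geom = sm_geom(), speed = 4) {
  polyline_trajectory(ideal_route(start, reward, geom)$polyline,
                      speed = speed)
}

# Independent brute-force strategy classifier: evaluates the written
# rules by explicit window scans, without run-length encoding.
oracle_classify <- function(labels) {
  if (sum(labels == "none") > 2) return("no_strategy")
  has_run <- function(lab) {
    for (start in 1:2)
      for (width in 4:5)
        if (start + width - 1 <= 5 &&
            all(labels[start:(start + width - 1)] == lab))
          return(TRUE)
    FALSE
  }
  if (has_run("AS")) return("allocentric")
  if (has_run("ES")) return("egocentric")
  "shifter"
}

# All 3^5 label sequences, one per row.
all_label_sequences <- function() {
  as.matrix(expand.grid(rep(list(c("AS", "ES", "none")), 5),
                        stringsAsFactors = FALSE))
}

# A small simulated cohort shared across tests (cached per session).
sm_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(arms = c("TD" = 3, "CP-Regular" = 3,
                                    "CP-Navigation" = 3), seed = 42)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

sm_small_metrics <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- score_cohort(sm_small_cohort())
    cache
  }
})
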