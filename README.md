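# starmaze

Analysis pipeline for immersive virtual-reality **star-maze** navigation
experiments — a task used to probe spatial-navigation strategy in
children, including clinical cohorts with cerebral palsy (CP). Five
alleys radiate from a regular pentagon; across 16 training trials
(start alley 1, reward alley 3) participants learn the route, and 5
interposed testing trials (start alley 4, alleys 1 and 3 both rewarded)
reveal whether they re-orient by environmental landmarks (**allocentric
strategy**, ending in alley 3) or replay the trained motor sequence
(**egocentric strategy**, ending in alley 1). A compelled block (4
imposed-allocentric + 3 imposed-egocentric trials) tests each strategy
in isolation.

The package is for researchers who record per-trial 2-D position
traces from such tasks and need the complete, reproducible scoring and
statistics chain:

* **Trajectory metrics** per trial: success, visited-alley sequence and
  count (entry events with hysteresis), total path length
  (TPL, m), distance error, and rotation angle:

  `DE (%) = 100 · (total distance − ideal distance) / ideal distance`

  `RA (°) = participant's rotations − minimum rotations`

  computed against the ideal hub route (246 m, one 36° turn, 2 alleys).
* **Strategy classification** of each participant from the five
  testing-trial labels: *allocentric* / *egocentric* (a run of more than
  three consecutive same-strategy trials), *no-strategy* (more than two
  failures), *shifter* (otherwise) — a total rule verified against
  brute-force enumeration of all 243 label sequences.
* **Learning analysis**: per-group median/IQR curves over the 16
  training trials and Friedman-based stabilization detection (the
  smallest trial k such that trials k..16 show no systematic change in
  any of the four learning parameters).
* **Nonparametric group battery**: chi-square (uniformity and
  contingency, no continuity correction), Kruskal–Wallis with
  Bonferroni-corrected Mann–Whitney post hocs, exact paired Wilcoxon
  (tie-aware sign-flip null), delta scores.
* **Synthetic cohorts**: a goal-directed agent simulator with
  configurable strategy mixtures, heading noise and learning onsets,
  emitting trajectories plus ground-truth labels — so the whole
  pipeline is testable without access to recorded participant data.

## Worked example

```r
library(starmaze)

geom <- star_maze()
geom
#> Star maze: 5 alleys, pentagon circumradius 23 m,
#>   alley length 110 m, width 14 m, reward at 100 m past the hub
#>   (direct route between reward positions: 246 m)

ir <- ideal_route(1, 3, geom)
round(distance_error(246.76, ir$ideal_distance), 2)  # DE of a 246.76 m trial
#> 0.31

cfg <- cohort_config(arms = c("TD" = 4, "CP-Regular" = 4,
                              "CP-Navigation" = 4), seed = 2024)
bundle <- run_pipeline("demo_out", config = cfg)
tb <- render_tables(bundle)
tb$stable_metrics[tb$stable_metrics$session == "T0", ]
#>  parameter session stable_trial th_value    CP-Navigation        CP-Regular               TD
#>   n_alleys      T0            7        2      2.00 (0.00)       2.00 (0.00)      2.00 (0.00)
#>      tpl_m      T0            7      246    246.00 (0.50)     245.47 (0.66)    245.52 (0.07)
#>     de_pct      T0            7        0     -0.00 (0.20)      -0.22 (0.27)     -0.19 (0.03)
#>     ra_deg      T0            7        0 3494.84 (808.17) 2322.23 (1034.39) 2471.30 (488.85)
```

The table reports each learning parameter at the detected baseline
stabilization trial (here the 7th), as median (IQR) per group, next to
its theoretical best value (2 visited alleys, 246 m, 0 % DE, 0° RA):
once stable, every simulated group navigates essentially ideal routes
(the slightly negative DE reflects trials ending at the 1 m treasure
capture radius; the large RA is accumulated simulator heading noise —
see the vignette). Stabilization at baseline is detected per group from
the Friedman search, e.g. trial 5 for TD and trial 7 for CP-Regular in
this run, matching each group's configured learning onset; strategy
recovery against the simulator's ground truth is tabulated in
`bundle$strategies` vs `bundle$cohort$truth`.

`run_pipeline()` writes the full report bundle (`metrics.csv`,
`strategies.csv`, `compelled.csv`, `learning_curves.csv`,
`stabilization.json`, `stats_report.json`, `manifest.json`) and is a
pure function of (configuration, seed): reruns are byte-identical.

## Vignette

`vignettes/star-maze-navigation.Rmd` documents the measurement model,
the classification and stabilization rules, every tunable parameter
with its default and rationale, what the synthetic cohort does and does
not emulate, and known limitations.
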