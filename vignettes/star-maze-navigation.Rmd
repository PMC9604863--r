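---
title: "Scoring star-maze navigation: metrics, strategy classification and learning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring star-maze navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmaze)
```

## The task and its measurement model

The star maze is an immersive-VR spatial-navigation task used with
children, including clinical cohorts with cerebral palsy: five alleys
radiate from the angles of a regular pentagon, distal landmarks surround
the scene, and a treasure hides at a fixed depth inside one alley. A
session comprises a *free navigation* block of 21 trials — 16 training
trials (start alley 1, reward alley 3) with 5 testing trials interposed
after training trials 4, 7, 10, 13 and 16 — and a *compelled* block of 4
imposed-allocentric trials (new start alleys 2/5, landmarks on) and 3
imposed-egocentric trials (start 1, landmarks removed), the two
sub-blocks counterbalanced across participants. Every trial allows 120 s.

The testing trials are the diagnostic core. They start from alley 4 with
both alley 1 and alley 3 rewarded: a navigator who re-orients by the
landmarks (allocentric strategy, AS) enters alley 3, while one who
replays the trained motor sequence (egocentric strategy, ES) lands in
alley 1. The package operationalizes "entered alley k" as a corridor
point strictly deeper than `entry_depth` (1 m) past the pentagon
boundary, with a 0.5 m exit hysteresis so boundary jitter cannot
manufacture entry events; a point exactly at the threshold counts as the
hub (entry must strictly exceed the threshold).

## Per-trial metrics

For each trial the scorer computes:

* **success** — the position record comes within the 1 m capture radius
  of a reward position within 120 s;
* **visited alleys** — entry events per the hysteresis rule; the direct
  route has the theoretical value 2 (start alley + reward alley);
* **TPL** — total path length, the sum of Euclidean inter-sample
  distances (m);
* **DE** — distance error, `100 * (TPL - ideal) / ideal` (%), where the
  ideal distance is the direct route through the hub;
* **RA** — rotation angle, the cumulative absolute heading change minus
  the ideal route's single turn (degrees), clamped at 0 with a flag when
  measurement noise pushes it negative.

Headings are estimated from consecutive displacement vectors longer than
0.05 m; how rotation is extracted from raw positions is not part of the
task definition, and the displacement filter is our choice for
suppressing stationary jitter. The maze dimensions are likewise not
fixed by the task: the package's default geometry (pentagon circumradius
23 m, reward depth 100 m past the boundary) is calibrated so the direct
route between reward positions measures exactly 246 m, the reference
value against which DE is expressed; all calibration constants travel
inside the `maze_geometry` object. Because every ideal route runs
through the hub at the same depth, all start/reward pairs share that
246 m ideal length, and routes two alleys apart have a minimal turn of
36° (adjacent: 108°).

## Strategy classification

Each testing trial is labelled AS (success ending in alley 3), ES
(success ending in alley 1) or none (no success). A participant's
five-label record is classified with these rules, in precedence order:

1. **no-strategy** — more than two failed testing trials;
2. **allocentric** — AS in more than three *consecutive* trials (a run
   of at least 4);
3. **egocentric** — the same for ES;
4. **shifter** — everything else.

The precedence makes the rule total over all 3^5 = 243 sequences; the
test suite checks it against an independently written brute-force
evaluator on every sequence. Sequences dominated by one strategy but
with the run broken below 4 fall to shifter — the conservative reading
that keeps the four categories exhaustive and mutually exclusive.

In the compelled block a trial counts as successful only when the
treasure is found by a *direct* route, which we quantify as exactly 2
visited alleys; per-participant success percentages are computed
separately for the imposed-AS (4 trials) and imposed-ES (3 trials)
conditions.

## Learning curves and stabilization

The 16 training trials trace a learning curve in four parameters
(visited alleys, TPL, DE, RA), summarized per group as per-trial medians
and IQRs. Stability is assessed with the Friedman test on the
within-participant trial series: performance is *stable from trial k*
when the test over trials k..16 is non-significant (alpha 0.05)
simultaneously for all four parameters. `stabilization_trial()` searches
the smallest such k (capped at 13 so at least four repeated trials enter
every test); `verify_stability()` additionally reports the fixed-window
check at a prespecified trial, since published analyses of this task
verified stability at the 5th (typically developing children) and 7th
(children with cerebral palsy) trials at baseline and the 2nd trial at
follow-up.

Ties receive average ranks. We use the standard tie-corrected Friedman
chi-square (as in `stats::friedman.test`); a fully tied matrix — which
flat post-learning curves genuinely produce — makes that correction
0/0, and we define the result as statistic 0, p 1 (no evidence of
change). A Monte-Carlo permutation p-value (shuffling trial order within
participants) is available where the chi-square approximation is
doubtful; full enumeration is infeasible at 16 trials.

## The group-comparison battery

Demographics and visuospatial Z-scores (Raven, Corsi, Labyrinth;
consumed already age-normalized) are compared with the nonparametric
battery standard for small clinical cohorts: Pearson chi-square without
continuity correction (uniformity within the pooled clinical group;
independence across the three arms), Kruskal-Wallis with tie correction
across arms, Bonferroni-corrected two-sided Mann-Whitney post hocs
(exact when both groups have n ≤ 20 and no ties; the multiplier is the
number of pairwise comparisons actually performed), paired Wilcoxon
signed-rank between assessments, and Kruskal-Wallis on recomputed
T1 − T0 deltas. The continuity-correction choice matters: with these
group sizes the uncorrected chi-square is what reproduces the reference
p-values (0.004 for a 21/6 gender split, 0.008 for pooled MACS 16/8/3,
0.033 and 0.074 for the GMFCS and gender contingency tables).

The paired Wilcoxon is implemented in the package rather than delegated,
because the exact two-sided p-value under ties requires the sign-flip
null distribution conditional on the observed average ranks; we build it
by convolution over doubled ranks for n ≤ 25 (normal approximation with
tie and continuity correction beyond), drop zero differences with a
count, and define the all-zero case as p 1 with a warning. On tie-free
data it agrees with `wilcox.test(..., exact = TRUE)` to full precision.

## The synthetic cohort

Because the recorded study data cannot ship with the package, a
goal-directed agent simulator generates cohorts with the statistical
structure the analysis assumes, plus ground-truth labels for validation:

* **kinematics** — 10 Hz sampling; constant speed drawn from
  U(3.5, 4.5) m/s per agent (the ideal route then takes ≈ 55–70 s,
  leaving room for detours within the 120 s limit); per-step heading =
  direction to the current waypoint + Gaussian noise, SD drawn from
  U(2, 5)°;
* **strategy** — allocentric agents steer to the landmark-defined alley;
  egocentric agents replay the trained turn sequence relative to their
  start (from alley 4 they land in alley 1); shifters draw between the
  two per testing trial (p = 0.5); no-strategy agents time out wandering
  with probability 0.85 per probe trial;
* **learning** — before a configured onset trial, training paths are
  inflated by a multiplicative excess (U(1.4, 1.8) at trial 1, decaying
  linearly to 1 at onset) realized as a hub-detour into a non-target
  alley, so visited alleys, TPL, DE and RA all decline and then plateau;
  default onsets are 5 (TD) and 7 (CP arms) at baseline and 2 at
  follow-up, mirroring the published stabilization pattern;
* **cohort structure** — default arm sizes 14/11/16 (TD, CP-Regular,
  CP-Navigation); strategy mixtures TD 50/36/14/0% and CP arms ≈
  25/37/19/19%; demographics and Z-scores drawn from arm-level
  distributions shaped like the reference cohort's marginals (these
  exist to exercise the statistical battery, not to claim clinical
  realism).

Every trajectory derives from an explicit seed; the whole cohort derives
from one master seed, making pipeline runs byte-reproducible.

What the simulator does *not* emulate: biomechanics and gait, wall
collisions, momentum (heading noise is white, so simulated cumulative
rotation is far larger than a human's smooth heading record — harmless
for the rank-based analyses, but absolute RA values should not be read
as human-like), fatigue, or any treatment effect beyond the configured
onset/mixture shifts. Passing parameter-recovery tests therefore shows
the *pipeline* recovers what the generator encodes, not that the
generator reproduces the deposited study data; published group-level
tables that depend on the real cohort are deliberately not reproduced.

Two numerical consequences worth knowing: simulated trials end at the
1 m capture radius, so a near-ideal trial's TPL sits ~1.5 m below the
246 m ideal and its DE is slightly *negative* (≈ −0.3%); and simulated
TPL is quantized by the fixed step length, so post-learning TPL is
nearly constant within agents — both are properties of the generator,
not of the scoring.

## Problem sizes and defaults used in validation

The test suite validates on small cohorts (3 participants per arm for
end-to-end checks; 10 for onset recovery; 40 agents for strategy
recovery at heading noise ≤ 5°, of whom ≥ 90% of non-shifters must be
recovered), with stabilization-detection accuracy of ±1 trial around
the configured onset, and calibrates the rank tests' type-I error
(1000 null replicates, nominal 0.05, accepted within [0.03, 0.07]).
These sizes are the package's chosen validation conditions; larger
cohorts only sharpen the same checks.

## Known limitations

* Strategy inference uses terminal-alley logic only; trajectory shape,
  gaze or landmark fixation are out of scope.
* The stabilization search inherits Friedman-test power: with very few
  participants a true pre-onset trend can be missed and stabilization
  reported early (the ±1-trial recovery holds from ~10 participants in
  our validation conditions).
* DE is reported in percent throughout; reference tables sometimes
  label DE in meters while defining it as a percentage — the percentage
  definition is implemented.
* Z-score norming of the cognitive tests is upstream of this package;
  tables arrive already normalized.
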