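---
title: "Quantifying goal-directed movement during tadpole transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying goal-directed movement during tadpole transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frogtraj)
```

## The analysis problem

Male poison frogs of territorial, tadpole-transporting species shuttle their
larvae from terrestrial clutches to small, scattered water bodies and then
return home. A telemetry study of this behaviour yields, per individual, a
sparse track of timestamped planar fixes (one every 30–60 min during the
07:00–19:00 activity window, across several days with night gaps), a table
of candidate deposition pools whose availability can be manipulated
experimentally, and a capture history from which a home-territory centre can
be derived. The scientific questions — how directed is the movement towards
pools and back home, does carrying tadpoles change speed, does pool
availability change precision — all reduce to a small set of reusable
operations which this package implements end to end:

1. **Phase segmentation.** A track is split into the tadpole-transport
   phase (TT), from the first fix to the fix at the *last* deposition
   event, and the homing phase (HT), from that fix until the frog is back
   in its territory. The splitting fix belongs to both phases so that
   distances and durations partition exactly.
2. **Accounting.** Path length (sum of fix-to-fix segments), active
   duration (elapsed time minus 12 h per night spanned), mean and per-step
   speed (m/h), and a straight-line interpolation of the unobserved section
   from the territory centre to the first encounter — a minimum-distance
   estimate, since a chord can never exceed any realised path.
3. **Precision metrics.** Straightness coefficient (SC), mean absolute
   angular deviation between each step and the bearing to the current goal,
   and mean perpendicular deviation from the straight path, with Rayleigh
   tests of directionality.
4. **Pool visits.** Radius-based visit detection, deposition inference from
   drops in the carried-tadpole count, visits-per-transport summaries and a
   post-deposition exploration flag.
5. **Model comparison.** Gamma/beta/gaussian mixed models with a
   per-individual random intercept, compared by small-sample corrected AICc
   (full vs null, all-subset selection, Akaike weights, model averaging).
6. **A synthetic study generator** that reproduces the field design, so
   every stage can be validated against known ground truth without any
   field data.

## Segmentation and accounting choices

Several operational details are not fixed by the field protocol and were
decided once, as follows.

* **"Returned home"** is the first fix within `r_home` of the territory
  centre. The default of 7 m is the radius of a circle with the average
  defended territory area of roughly 151 m²; it is configurable.
* **Territory centre** is the unweighted centroid of the capture points at
  which the male showed territorial behaviour (calling, courtship,
  aggression); non-territorial captures are ignored.
* **Night exclusion** subtracts the full 12 h night for every calendar
  night a track spans. Fixes logged outside the daylight window (clock
  drift) are clamped to the nearest window edge with a warning rather than
  rejected, because the protocol precludes genuine night fixes.
* **Timestamps carry no timezone**; arithmetic is in local clock time,
  matching how field data are recorded. Coordinates must be projected
  planar metres; the reader refuses values that look like raw
  longitude/latitude and asks the user to project first.
* **Visits** are maximal runs of fixes within `r_visit` of a pool centre,
  nearest pool winning. The field definition of a visit is observational
  ("the frog entered the pool"), so the radius is a proxy and should be a
  small multiple of the fix measurement noise; the pipeline default is
  2.5 m (five times the nominal 0.5 m tracking noise) against a 20 m pool
  spacing. A visit interrupted by a single out-of-radius fix spanning less
  than 30 min is merged (tracking noise).
* **Depositions** are inferred only where the carried-tadpole count is
  known on both sides of a visit and strictly drops, and only at available
  pools; unknown counts leave the flag unknown rather than guessed. A count
  increase is a validation error.

## The precision statistics

For a trajectory with fixes $p_1,\dots,p_n$ and ordered goal waypoints
$w_1,\dots,w_m$ (TT: the first fix, then each visited deposition site in
visit order; HT: the last deposition site, then the territory centre):

* **Straightness coefficient.**
  $SC = \sum_j \lVert w_{j+1}-w_j \rVert \,/\, \sum_i \lVert p_{i+1}-p_i \rVert$,
  1 for a perfectly straight path. With noisy fixes — or an HT cut at the
  returned-home fix short of the centre — the ideal-waypoint chord can
  exceed the realised path and push this ratio above 1. The package
  therefore anchors the chord vertices to the realised track by default
  (first and last fix, plus the fix nearest each intermediate goal): every
  vertex then lies on the path in temporal order, which confines SC to
  $(0,1]$ by the triangle inequality. `anchor = "waypoints"` restores the
  textbook chord, which also supplies the straight-line distance columns of
  the summary tables.
* **Angular deviation.** For each non-final fix, the absolute circular
  difference between the bearing to the current goal and the bearing of the
  realised step, wrapped to $[0°,180°]$. During a multi-pool transport a
  fix's goal is the next deposition site subsequently reached
  (chronological attribution). Zero-length steps are skipped, as is a fix
  coinciding with its goal (ideal direction undefined; a warning is
  emitted).
* **Perpendicular deviation.** Distance from each fix to the infinite line
  through its current chord segment (matching "deviation from the straight
  path"); distance to the clamped segment is available as an option.
* **Rayleigh test.** $\bar R$ is the mean resultant length of the angle
  set, $Z = n\bar R^2$, and the p-value uses the standard series
  approximation clamped to $[0,1]$. Trajectories with three or fewer
  locations are excluded from all directionality analysis. The pipeline
  pools *goal-relative* deviation angles across the trajectories of a phase
  (each trajectory's ideal direction mapped to 0°), since pooling raw
  compass bearings would conflate goal direction with precision; the raw
  operation is exposed for any angle set.

Mean angular and perpendicular deviations are reported per trajectory and
averaged per phase (per-trajectory means, then the grand mean); pooling all
steps instead is possible from the per-fix values returned in the
`"values"` attribute.

## Mixed models and information-theoretic comparison

Average speed per phase is strictly positive and right-skewed, so the
speed-versus-tadpole-presence contrast uses a gamma mixed model with a log
link and a per-frog random intercept. The log link is the package default
for gamma responses; a logit link for a gamma response is nonstandard
(undefined for means above 1 on the response scale) and is refused with a
warning that falls back to log. SC is bounded by 1 and can attain it, so
beta-family responses are squeezed off the boundary with
$y' = (y(n-1)+0.5)/n$ before fitting — on interior data of reasonable size
this changes estimates by well under $10^{-3}$, and it is the only
boundary handling applied.

Model comparison follows the information-theoretic workflow:
$AICc = -2\log L + 2k + 2k(k+1)/(n-k-1)$; a full model is supported over
its null only when $\Delta AICc > 2$; all-subset selection ranks every
subset of candidate terms, keeps those within 2 units of the best, and
model-averages coefficients with Akaike weights renormalised within that
subset (full average, absent terms contributing zero; the conditional
average is also reported). Fixed-effect optimisation starts from the
null-model estimate with slopes at zero, which makes refits deterministic.
A truly constant response makes the gamma/beta likelihood unbounded in the
dispersion; `fit_mixed_model()` then returns the analytic limit (mean equal
to the constant), flagged non-converged with undefined AICc so it can never
win a model comparison.

Power note: with two phase means of 10.16 and 7.22 m/h, gamma shape 5 and
16 frogs × 2 observations, the log-ratio standard error is ≈ 0.16 while the
$\Delta AICc > 2$ rule demands roughly $|z| > 2.15$ — so the rule supports
the full model in only about half of such replicates even though the effect
is real and the estimated ratio itself is recovered essentially unbiased.
The rule is deliberately conservative; the package reports the measured
support rates rather than hiding them.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions; `simulate_study()` draws a
landscape, tracks and captures from named RNG sub-streams of one master
seed (bit-identical reruns; adding new draws never perturbs existing
streams).

* **Landscape.** Thirteen artificial pools in a cross at 20 m spacing, with
  every second pool along each transect removed (the centre and the four
  mid-arm pools), leaving 8 available. Territory centres are uniform in a
  10–60 m annulus around the array, kept 5 m clear of pools. Coordinates
  carry a UTM-like offset so the generated CSVs are valid projected input.
* **Movement.** A two-state (move/pause) walk at one-minute resolution;
  move-state headings are von Mises around the bearing to the current goal
  and step lengths capped exponential, multiplied by 1.41 while tadpoles
  are carried. Defaults (`kappa = 1`, mean step 0.35 m/min, move fraction
  1/3) were chosen once so that the *fix-scale* precision statistics land
  where field tracks of this system do: transport SC ≈ 0.86, angular
  deviation ≈ 30°, per-step speeds within the observed 0–70 m/h. Because
  the simulated frogs also dwell a full fix interval at every pool, their
  per-phase average speeds come out around 5 (transport) vs 4.7 (homing)
  m/h — slower than real tracked means near 10 vs 7, and with the
  move-state 1.41 speed ratio diluted by the stationary fractions. The
  speed-effect experiments therefore generate per-trajectory speeds at the
  target group means directly rather than through the walk.
* **Itineraries.** 1–4 pools; the next pool is the nearest available one
  with probability 0.7, otherwise a random reachable pool, which may be a
  removed one — frogs do approach removed pools, and deposit nothing there.
  Legs must clear all third pools by 12 m so that transit never runs over
  or past an unvisited pool (on a cross-shaped array the line between two
  same-arm pools passes exactly over the pool between them, and loosely
  concentrated walks wobble several metres off their chord; both would
  make ground-truth visit recovery ill-defined). The itinerary always ends
  at an available pool, where the remaining load is deposited.
* **Observation model.** Fixes subsample the walk at a per-frog interval
  drawn from 30–60 min inside the daylight window, starting from a random
  encounter point 20–60 % of the way to the first pool (the field protocol
  finds frogs already transporting); Gaussian position noise with
  sd 0.5 m; the tadpole count is recorded at every fix. Dwell at each pool
  lasts one fix interval plus 10 min so at least one fix falls inside every
  visit, and departure begins with a short determined dash so the fix after
  leaving is unambiguously outside the visit radius.
* **Covariates.** Per-3-h-interval temperature (sinusoid plus noise) and
  zero-inflated gamma rainfall, with optional log-linear effects wired into
  a gamma speed generator for selection-recovery experiments.

What the generator deliberately does **not** emulate: landscape
heterogeneity (rivers, slopes, vegetation), disturbance by the observer,
multi-transport histories per frog, tag loss, or attraction cues from
pools. Passing tests therefore demonstrate that the pipeline recovers the
truth of *this* generative model — unbiased phase segmentation, visit and
deposition recovery, metric monotonicity in the heading concentration, and
speed-effect recovery — not that the biological conclusions of any
particular field data set are correct.

A practical note on track duration: with `kappa = 1` the approach towards a
goal is slow (the mean heading cosine is ≈ 0.45) and clearance-constrained
routes are longer than straight-line hops, so a noticeable fraction of
walks legitimately needs more than the roughly five active days the longest
real tracks spanned; `max_days` defaults to 12, and the unreachable-goal
error remains for anything longer.

## Numerical choices

* Angles are radians internally, degrees at the interface; bearings are
  east = 0°, counter-clockwise, in $[0°,360°)$; absolute deviations in
  $[0°,180°]$.
* SC values above 1 by less than $10^{-9}$ (floating-point noise on exactly
  straight paths) are clipped to 1; larger excesses warn and are possible
  only under `anchor = "waypoints"`.
* The Rayleigh p-value series is clamped to $[0,1]$; its type-I error at
  n = 22 sits within half a percentage point of the nominal 5 % level.
* Durations are computed in seconds and converted to hours; the additivity
  of the TT/HT split holds to one second.
* Problem sizes used by the validation suite: 1,000 random tracks for the
  metric oracles, 10,000 replicates for the Rayleigh size check, 200
  transports per heading-concentration level, 200 replicate data sets for
  the speed-ratio and selection-rate experiments, 100 seeded
  simulate-then-analyse round trips.
* The heading-concentration recovery experiment runs with the fix jitter
  switched off: a 0.5 m position noise at a 30–60 min relocation interval
  imposes an angular-deviation floor of roughly 14° that masks the
  difference between the two highest concentration levels; the experiment
  is about the metric's response to the generative concentration, not
  about that floor. Study-condition defaults are unchanged everywhere
  else.

## Known limitations

* The visit radius cannot be validated against an observational visit
  definition beyond aggregate counts; it is a proxy with a documented
  default.
* Homing trajectories are cut at the first fix within `r_home`; the frog's
  final approach inside the territory is not analysed.
* The weather-covariate machinery is exercised on synthetic series only;
  no claim is made about any real weather data set.
* Model selection with the two-unit rule is conservative at this study's
  sample size (see the power note above).
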