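---
title: "Modelling and analysing rodent escape-jump trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing rodent escape-jump trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapekin)
```

## The scientific problem

Desert rodents facing ambush predators — rattlesnakes and owls that strike
once, fast, and rarely get a second chance — escape either by a rapid
vertical **jump** or by a **scramble**, a reorient-and-run manoeuvre.
Bipedal kangaroo rats (*Dipodomys*) jump readily; pocket mice
(*Chaetodipus*) are quadrupedal heteromyids that share enlarged hindlimbs
and auditory bullae; woodrats (*Neotoma*) and ground squirrels
(*Otospermophilus*) are quadrupeds that almost never jump when startled.
Field experiments elicit these responses with a spring-loaded strike
simulator that projects a cork at roughly a rattlesnake's strike speed,
filming the response with high-speed video and measuring the jump's
horizontal displacement with a tape measure.

`escapekin` implements the complete analysis that such trials require:

1. **Ballistic reconstruction** of jump kinematics from the two field
   measurements (horizontal displacement, airborne time).
2. **Censoring and exclusion rules** for the trial classes that cannot be
   scored (animal struck by the cork before reacting, reaction before the
   cork moved, off-screen landings, poor video).
3. **Allometric size correction**: residuals of log metric on log body
   mass, pooled over species.
4. **Inference**: a one-factor PERMANOVA on the size-corrected multivariate
   performance, one-way linear models with Tukey HSD letter displays for
   the timing metrics, and a logistic regression of jump probability on
   reaction time.
5. A **synthetic trial generator** that emulates the statistical structure
   of the field data, so the full pipeline runs and is testable without any
   field recordings.

## Ballistic model

A jump is treated as level-ground projectile motion of a point mass with
`g` = 9.8 m/s². From displacement `d` (m) and airborne time `t` (s):

$$v_h = d/t, \qquad v_v = g\,t/2,$$
$$\text{speed} = \sqrt{v_h^2 + v_v^2}, \qquad
  \theta = \arctan(v_v/v_h)\cdot 180/\pi, \qquad
  h = v_v^2 / (2g) = g\,t^2/8.$$

The vertical component follows from symmetry of an up-and-down flight that
starts and ends at ground level, which makes jump height a function of
airborne time alone. Assumptions worth keeping in mind: no air resistance
(negligible at < 3 m/s over < 0.5 s), take-off and landing at the same
height, and the digitized point (the toes) standing in for the centre of
mass. Take-off angles are reported in degrees. A zero displacement is
treated as the vertical-jump limit (angle 90°) rather than an error.

```{r}
compute_kinematics(displacement_m = 0.4, airborne_s = 0.2)
```

`forward_ballistics()` is the exact inverse and is what the generator uses,
so every simulated jump obeys these equations exactly before measurement
noise.

## What the generator emulates — and what it does not

`generate_trials()` simulates one strike trial per row, parameterized by a
species profile (see `default_species_profiles()` for the six study
species):

* **Escape mode** is Bernoulli in the species' jump propensity (0.625 to
  0.926 for the heteromyids, under 0.1 for woodrats and ground squirrels).
* **Reaction and take-off times** are truncated normal. Published tables
  give mean ± SE and the per-metric `n`, so the population SD is recovered
  as SE·√n. The truncation at 4 ms (roughly one frame) keeps draws
  physiologically possible. The distribution family is a modelling choice:
  only the first two moments are constrained by the source summaries, and
  a truncated normal is the simplest family matching them.
* **Mode-specific take-off times**: Merriam's kangaroo rat profile uses a
  jump mean of 88 ms and a scramble mean of 126 ms; the propensity-weighted
  mixture reproduces the published combined mean (≈ 102 vs 103.1 ms).
  Other species use one mean for both modes because no mode-specific
  values are published for them.
* **Jump performance**: take-off speed (truncated > 0) and angle
  (truncated to (0°, 90°)) are drawn per jump and converted to
  displacement and airborne time by forward ballistics. Species without
  published jump parameters (woodrat, ground squirrel) produce jumps with
  unmeasured displacement, exactly as in the field data.
* **Measurement noise**: displacement is rounded to 0.01 m (tape-measure
  precision, which the source does not state; 1 cm is the natural reading
  precision of a field tape), and every timing is quantized to the
  species' frame period (8.3 ms at 120 fps, ~4.2 ms at 240 fps) plus a
  uniform integer jitter in [−2, +2] frames, the stated digitization error
  of scoring event frames by eye.
* **Censoring**: independent Bernoulli flags per trial. The default rates
  (`censoring_rates()`: hit 0.10, premature 0.01, off-screen 0.04, poor
  video 0.05) are set once from the scale seen in field data sets — cork
  hits are by far the most common loss (about one trial in ten), premature
  reactions are rare (about 1%). A flagged trial has the affected fields
  set to `NA`: a hit hides both timings (the response to being struck is
  not a reaction time), a premature reaction hides reaction time,
  off-screen landings and poor video hide what they prevent measuring.

What the generator deliberately does **not** emulate: individual-level
covariance between metrics (each metric is drawn independently, whereas a
real animal that reacts fast may also jump fast), ambient light,
vigilance state, distance to the device, repeated structure across sites
and years, and any predator-side variation. Passing tests therefore show
that the *pipeline* is correct and calibrated — unbiased recovery of
group-level moments, correct type-I error — not that real escape data obey
truncated normals.

```{r}
trials <- generate_trials(default_species_profiles(), n_per_species = 30,
                          seed = 1)
jump_frequency(trials)
```

## Size correction and the multivariate test

Jump performance scales with body size, and species identity is confounded
with mass (an 18 g pocket mouse vs a 523 g squirrel). The analysis
therefore regresses the log of each performance metric on log body mass
over the pooled individuals and keeps the residuals ("overall
performance"). Natural logs are used; the log base cancels out of
residual-based inference. Residual columns are then scaled to unit SD so
that Euclidean distances weight each metric equally.

The PERMANOVA is implemented directly from the distance decomposition:
total SS is the mean squared pairwise distance over all pairs, within SS
the same within groups, and the pseudo-F compares their ratio on
`(a − 1, n − a)` degrees of freedom. The null distribution permutes group
labels; the p-value uses the `(r + 1)/(n_perm + 1)` convention that counts
the observed labelling among the permutations, so the attainable minimum
with 999 permutations is 0.001 and p is never zero. Raw labels are
permuted (not residuals), which is exact for this one-factor design.
Internally rows are sorted into a canonical order before permuting, making
the reported p invariant to the row order of the input for a fixed seed.
On univariate input the pseudo-F reduces algebraically to the classical
ANOVA F, which the test suite checks to 1e-9, alongside a cross-check
against `vegan::adonis2` and an exhaustive-enumeration oracle at n = 6.

Which metrics enter the multivariate test is configurable, because two
defensible sets exist: take-off time, take-off angle and jump height (the
default), or take-off velocity, jump height and angle. Both are runnable
via `analysis_config(metrics = ...)`; neither is asserted as canonical.

```{r}
report <- run_full_analysis(trials, analysis_config(seed = 2))
report$performance$permanova[c("pseudo_F", "df_between", "df_within",
                               "p_value")]
```

## Timing analyses, letters, and escape mode

Reaction time and take-off time are analysed raw (not size-corrected) with
one-way linear models across species, followed by Tukey HSD pairwise
comparisons. Samples are unbalanced, so the Tukey–Kramer form of the
standard error is used with the studentized-range distribution. Group
letters come from the insert-and-absorb algorithm: start with all groups
sharing one letter class, split the class on each significant pair, absorb
classes that become subsets, then assign letters in order of group means
(ties broken by mean, then label). Two groups share no letter exactly when
their adjusted p is below `alpha` (0.05 by default — the conventional
threshold, applied throughout).

```{r}
report$takeoff$tukey$letters
```

The relationship between escape mode and the timing metrics is examined
within the species that shows enough of both manoeuvres (by default the
species with the largest balanced sample, at least 5 per mode — with the
packaged profiles, Merriam's kangaroo rat): a logistic regression of
jumping on reaction time (odds ratio per ms) and a linear model comparing
take-off time between modes, which for two groups is the pooled-variance t
test (F = t²). A single-class outcome or complete separation raises an
error rather than returning a silently divergent fit.

## Numerical and design choices

* `g` = 9.8 m/s² exactly, matching the value used in the source analyses,
  not 9.80665.
* Jump percentages are rounded to the nearest integer with ties away from
  zero (62.5% → 63%), matching how such frequencies are conventionally
  reported.
* Zero variance in log mass makes the allometric slope unidentifiable;
  `size_correct()` then falls back to centering the log metric and flags
  the result (`degenerate_mass` attribute) instead of failing.
* Exclusions are counted by the first matching rule (hit, then premature,
  then poor video), so per-rule counts always sum to rows-in minus
  rows-analysed.
* Trials whose multivariate metric is censored (e.g. a cork-hit trial has
  measurable jump performance but no take-off time) are dropped from the
  PERMANOVA with an explicit `missing_metric` count.
* A species enters the multivariate comparison only with at least
  `min_perf_n` (default 2) fully measured jumps; with the packaged
  profiles this reproduces the exclusion of woodrats and ground squirrels.
* All randomness flows through explicit integer seeds; generation and
  permutation restore the session RNG state, and rerunning with the same
  seed and configuration yields a byte-identical JSON report.

Problem sizes used by the test suite were chosen to keep checks sharp but
quick: 500 noise-free trials for moment recovery, 200 trials per species
for end-to-end parameter recovery (within 3 SE of the generative means),
10,000 trials for censoring-rate convergence, and 1,000 null replicates at
99 permutations for the PERMANOVA type-I error, which must land in
[0.03, 0.07] at α = 0.05.

## Limitations

Simulated trials draw each metric independently within species, so the
multivariate null is more "spherical" than real data; the PERMANOVA's
power against realistic correlated alternatives is not characterized here.
The ballistic model ignores take-off/landing height differences and body
rotation, biasing heights slightly for animals that land on a mound or
extend their legs. The generator's censoring is independent of the
metrics, whereas in the field slow reactors are *more* likely to be hit by
the cork — analyses of reaction time conditioned on surviving trials can
therefore be mildly optimistic in real data in a way the simulation will
not reveal.
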