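# escapekin

Analysis of rodent escape responses to simulated predator strikes: ballistic
reconstruction of evasive jumps, trial censoring rules, allometric size
correction, and the multivariate/univariate inference layer — plus a
synthetic trial generator so the whole pipeline runs without field data.

## The problem

Field studies of antipredator behaviour startle free-living rodents
(kangaroo rats, pocket mice, woodrats, ground squirrels) with a
spring-loaded cork launcher that mimics a rattlesnake strike, film the
response at 120–250 fps, and measure each jump's horizontal displacement
with a tape measure. The scientific questions are whether species differ in
jump performance once body size is accounted for, whether they differ in
reaction time and take-off time, and whether jumping buys a faster escape
than scrambling. `escapekin` packages that entire analysis for
behavioural ecologists and biomechanists working with this kind of trial
data.

## The model

A jump is level-ground projectile motion with *g* = 9.8 m/s². From
horizontal displacement *d* and airborne time *t*:

    v_h = d/t            v_v = g·t/2
    speed = √(v_h² + v_v²)   angle = atan(v_v/v_h)·180/π   height = v_v²/(2g)

Performance metrics are size-corrected as residuals of log metric on log
body mass (pooled species), unit-standardized, and compared across species
with a one-factor PERMANOVA (Euclidean distance, label permutations,
p = (r+1)/(n_perm+1)). Reaction and take-off times are compared with
one-way linear models plus Tukey–Kramer HSD and compact letter displays;
escape mode is related to reaction time by logistic regression.

## Worked example

```r
library(escapekin)

compute_kinematics(displacement_m = 0.4, airborne_s = 0.2)
#>   v_h  v_v takeoff_speed takeoff_angle_deg jump_height_m
#> 1   2 0.98      2.227196          26.10485         0.049

trials <- generate_trials(default_species_profiles(), n_per_species = 30,
                          seed = 1)
report <- run_full_analysis(trials, analysis_config(seed = 2))
report
#> Escape-response analysis report
#>   trials: 180
#>   jump frequency:
#>   species jumps trials percent
#> 1    CHPE    28     30      93
#> 2    DIDE    25     30      83
#> 3    DIME    18     30      60
#> 4    DISP    27     30      90
#> 5    NEAL     0     30       0
#> 6    OTBE     3     30      10
#>   PERMANOVA: pseudo-F(3, 68) = 0.59, p = 0.737
#>   reaction time: F(5, 131) = 14.9, p = 1.39e-11
#>   take-off time: F(5, 131) = 8.97, p = 2.37e-07
```

Reading the output: the heteromyids (kangaroo rats DIME/DIDE/DISP and
pocket mouse CHPE) jump in most trials while the woodrat (NEAL) and ground
squirrel (OTBE) almost never do, so only the four jumping species enter
the multivariate performance comparison — which finds no species
difference after size correction (p = 0.74). Timing differs strongly
across species; the Tukey letters locate the differences:

```r
unlist(report$takeoff$tukey$letters)
#> CHPE DIDE DIME DISP NEAL OTBE
#>  "a" "ab" "bc" "bc"  "c"  "c"
```

Species sharing no letter differ significantly in take-off time: the
non-heteromyid quadrupeds ("c") are slower than the pocket mouse ("a")
because scrambling requires reorienting before escape.

A thin command-line wrapper over these functions is provided at
`inst/cli/escapekin.R` with `simulate`, `analyze` and `summarize`
subcommands.

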