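# smmteams

Shared mental model (SMM) similarity scoring and team-level inference for
small-team questionnaire studies.

Interprofessional teams — the motivating case is trauma resuscitation teams
of five to nine clinicians — coordinate better when members hold convergent
expectations about task responsibilities and communication patterns. A
standard way to quantify that convergence is to give all members the same
nominal questionnaire and measure within-team response similarity.
`smmteams` implements that measurement and the statistics built on it, for
researchers running pre/post team-training studies with teams as the unit of
analysis.

## What it computes

**Similarity scores.** For a team with *k* responders on an item, the score
is the mean pairwise agreement over all C(k, 2) unordered member pairs:

* single-choice items: a pair scores 1 if both picked the same option, else
  0 — so the item score is (# agreeing pairs) / C(k, 2);
* multiple-choice items: a pair scores the set overlap of the two
  selections, by default the Jaccard index |A∩B| / |A∪B| (Dice and overlap
  coefficient selectable).

Item scores average (unweighted) into domain scores — task responsibility
and communication — and the total score is their item-count-weighted mean,
identically the mean of all defined item scores. Scores live in [0, 1] and
report as percentages.

**Inference.** `smm_anova()` fits the two-way mixed repeated-measures ANOVA
(between factor: training group; within factor: time; units: teams) from an
unweighted-means (Type III–style) sums-of-squares decomposition, with F
tests against the stratum-appropriate error terms and partial eta squared
η²p = SS_effect / (SS_effect + SS_error) = F·df₁/(F·df₁ + df₂). It returns a
classed object with `print`, `summary`, `coef`, `predict`, `fitted`,
`residuals`, `simulate` and `plot` methods. Baseline balance tests
(uncorrected Pearson chi-square; summary-statistic two-sample t) and an
exact noncentral-t paired sample-size routine round out the toolbox.

**Simulation.** `simulate_study()` draws whole studies from a modal-response
model — each team holds a canonical answer per item and members adhere to it
with tunable probability — whose expected agreement has a closed form
(c² + (1−c)²/(m−1) for single-choice; exact subset enumeration for
multiple-choice overlap). `run_experiment()` runs type-I-error, power and
parameter-recovery experiments over the full simulate → score → fit
pipeline.

## Worked example

Simulate a 29-team two-arm study at the calibrated defaults, score it, and
fit the ANOVA on the total similarity score:

```r
library(smmteams)

cfg    <- simulation_config(seed = 42)   # 15 + 14 teams, 54-item instrument
study  <- simulate_study(cfg)
scores <- score_study(study)             # 58 rows: one per team x time
an     <- analyze_scores(scores)

an$descriptives[an$descriptives$outcome == "total", ]
#>   outcome     group  n mean_pre   sd_pre mean_post  sd_post
#> 5   total algorithm 14 71.45511 3.347988  77.06151 2.348307
#> 6   total checklist 15 69.98703 1.772998  77.13745 2.389286

an$anova$total
#> Mixed repeated-measures ANOVA (unweighted means)
#> outcome: total   teams: 29 (14/15)
#>
#>      effect        SS    df     F      p eta_p_sq
#>       group 0.0007017 1, 27  1.07  0.310     0.04
#>        time 0.0589200 1, 27 96.67 <0.001     0.78
#>  time:group 0.0008632 1, 27  1.42  0.244     0.05
```

Both arms start near 70–71 % total similarity and converge to ~77 % after
training: a large time main effect (F(1, 27) = 96.7, η²p = 0.78), no
credible group difference or time × group interaction — the generator's
default calibration encodes a strong shared training effect with only a
small difference between arms. `paired_pre_post_sample_size(d = 0.5)` gives
the a priori recruitment target for a paired design at medium effect size:
34 pairs (achieved power 0.808).

A file-based pipeline (`run_simulate()`, `run_score()`, `run_analyze()`,
`run_power()`, and the `inst/scripts/smm-pipeline.R` command-line front end
with `score` / `analyze` / `simulate` / `power` / `fixtures` subcommands)
wraps the same functions with CSV/JSON/YAML inputs and outputs, full
precision plus 2-dp percentage reports, and an auditable run log.

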