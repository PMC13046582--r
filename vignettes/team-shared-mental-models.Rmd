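---
title: "Quantifying shared mental models in small teams: scoring, inference, simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shared mental models in small teams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smmteams)
```

## The measurement problem

A shared mental model (SMM) is the degree to which members of a working team
hold convergent expectations about how the team operates — who is responsible
for which task, and who reports what to whom. In interprofessional healthcare
teams (the motivating setting is trauma resuscitation teams of five to nine
people), SMM convergence is measured by giving every team member the same
nominal questionnaire and quantifying how similar the answers are *within*
each team. Similarity is deliberately distinct from accuracy: a team can
agree on a wrong allocation of responsibilities; this package measures only
agreement.

`smmteams` implements the full analysis chain: item-level similarity scoring,
aggregation to domain and team level, a two-way mixed repeated-measures ANOVA
for pre/post training designs with teams as units, baseline-balance tests,
a priori sample size for paired designs, and a generative model of team
responses for calibration, power and type-I-error experiments.

## Similarity scoring

Two response modes require two scoring rules.

**Single-choice items** (typically task-responsibility items: "who is
responsible for X?", one answer allowed). For a team with $k$ responding
members, every unordered pair of members is compared; a pair agreeing on the
same option contributes 1, any other pair 0. The item score is the number of
agreeing pairs divided by $\binom{k}{2}$, the maximum possible number of
agreements — equivalently the mean of the pairwise 0/1 agreement over all
pairs.

**Multiple-choice items** (typically communication items: "who reports X to
whom?", any subset allowed). The pairwise score is a set-overlap proportion.
The default is the Jaccard index $|A \cap B| / |A \cup B|$, the canonical
"proportion of overlapping responses"; the Dice coefficient
$2|A \cap B|/(|A|+|B|)$ and the overlap coefficient
$|A \cap B|/\min(|A|,|B|)$ are selectable because the literature's verbal
definition does not pin the denominator down. The item score is again the
mean over all pairs. Which metric is in force never affects single-choice
items (`score_study(..., metric=)` is inert on them), and all three agree at
the extremes: 1 for identical sets, 0 for disjoint sets.

Aggregation: the **domain score** (task responsibility; communication) is the
unweighted mean of that domain's defined item scores; the **total score** is
the item-count-weighted mean of the two domain scores, which is algebraically
the plain mean over all defined item scores. With the default 54-item
instrument the weights are 26 and 28. All scores live in $[0,1]$ and are
reported as percentages in the presentation tables.

Missing data policy: a member with no recorded selection for an item is
excluded from that item's pair set only (listwise by item, not by member) —
this maximises usable pairs and treats an empty multiple-choice selection as
indistinguishable from missingness. An item with fewer than two responders in
a team/time cell is undefined (`NA`) and excluded from aggregation;
`validate_study()` reports all such cells without mutating anything, leaving
exclusion decisions to the analyst.

## The instrument

The bundled default instrument (`default_questionnaire()`, also shipped as
`inst/extdata/default_questionnaire.json`) mirrors the study-shaped design:
26 task-responsibility items (21 single-choice, 5 multiple-choice) and 28
multiple-choice communication items. The original item wording and option
counts are not public, so items carry placeholder labels and a configurable
per-item option count, defaulting to 5 — a typical role-roster size for a
five-to-nine-person team. Arbitrary instruments are supported through
`questionnaire_spec()`.

## The mixed repeated-measures ANOVA

Team-level scores at two time points, with teams nested in two training
groups, are analysed with the classical split-plot decomposition: a
between-team stratum (group, tested against teams-within-groups) and a
within-team stratum (time and time × group, tested against
time × teams-within-groups). With $n$ teams in total and two time points,
every effect has $df = 1$ and every error term $df = n - 2$.

For unequal group sizes the effect sums of squares use the unweighted-means
(Type III–style) solution — each hypothesis is a contrast of unweighted cell
means with the harmonic-mean cell size $\tilde n$. This is the convention of
the major behavioural-statistics packages; at a 15/14 imbalance it differs
from weighted means only in the third decimal. For the two-group case the
choice is provably immaterial for the interaction: the interaction F equals
the pooled-variance two-sample $t^2$ on team change scores, an identity the
test suite verifies to $10^{-10}$ relative error on hundreds of random
designs, and the balanced case reproduces `aov(y ~ group*time +
Error(team))` exactly.

Effect sizes are partial eta squared,
$\eta^2_p = SS_\text{effect}/(SS_\text{effect}+SS_\text{error}) =
F\,df_1/(F\,df_1 + df_2)$, with the usual small/medium/large anchors at
0.01/0.06/0.14. All p-values are two-sided. Sphericity is not an issue with
two within levels, and scores are analysed untransformed as bounded
proportions (an established exploratory convention at this design size); no
hospital-level random effects are modelled.

Numerical edge cases: a within-stratum error SS that is zero to within
$10^{-10}$ of its stratum total (possible on degenerate synthetic data with
constant change scores) is treated as exactly zero; the affected F is
reported as `Inf` with $p = 0$ and the fit carries a `zero_variance` flag
rather than failing. Teams missing a time point are rejected with an error
instructing exclusion — mirroring how incomplete teams are handled in
practice — and `analyze_scores()` automates that exclusion with a warning.

## Balance tests and sample size

Baseline comparability of the two arms is checked at the individual level:
Pearson chi-square **without** continuity correction for categorical
characteristics (the uncorrected statistic is what standard reporting of
multi-category baseline tables uses, and the published 2×2 gender p-value is
reproducible only without correction), and a summary-statistic two-sample t
test (pooled by default, Welch selectable) for continuous ones. A note on
conventions: for the published experience summaries (7.6 ± 9.8 vs 8.6 ±
8.98, n = 95/91) the two-sided pooled or Welch p is ≈ 0.47, while a
one-sided reading gives ≈ 0.23; the package reports two-sided values
throughout and does not chase any particular printed number.

`paired_pre_post_sample_size()` finds the smallest number of paired units
whose exact noncentral-t power (ncp $= d\sqrt n$, $df = n-1$) reaches the
target. For $d = 0.5$, $\alpha = .05$ two-tailed, power .80 it returns
n = 34 pairs (power .8078 at 34, .7958 at 33); tools that approximate the
noncentral distribution or round differently sometimes report 33. One-tailed
the answer is 27. `stats::power.t.test` is the cross-check in the tests.

## The generative model

`simulate_study()` draws team responses from a *modal-response* model chosen
because it has a closed-form expected agreement and one interpretable
convergence dial per mode:

* each team holds one canonical option (single-choice) or one canonical
  subset of size $s$ (multiple-choice) per item, fixed across time;
* a member answers a single-choice item with the canonical option with
  adherence probability $c$, otherwise uniformly among the other $m-1$
  options, giving expected pairwise agreement
  $a(c, m) = c^2 + (1-c)^2/(m-1)$ — invertible on $c \in [1/m, 1]$
  (`invert_agreement()`, closed form);
* on a multiple-choice item a member includes each canonical option with
  probability $p_\text{in}$ and each other option with probability
  $p_\text{out}$, independently. The expected pairwise Jaccard overlap,
  conditional on both selections being non-empty (an empty draw is recorded
  as missing), has no simple closed form; `expected_overlap_multi()`
  computes it *exactly* by enumerating all $2^m$ selection subsets
  ($m \le 12$), and `invert_overlap()` inverts it numerically in
  $p_\text{in}$.

Training effects are implemented as group-specific pre→post increases in
$c$ and $p_\text{in}$. The default `simulation_config()` reproduces the
study conditions: 15 + 14 teams, sizes uniform on 5–9, the 54-item
instrument, and convergence levels calibrated by the inversion utilities so
the expected domain similarities equal the published group × time
descriptives (task responsibility 61.3/62.3 % pre rising to 73.7/71.4 %
post; communication 80.8/80.4 % to 82.6/82.4 %). Because the five
multiple-choice task items share the communication inclusion parameters, the
single-choice adherence is solved from the 26-item domain identity
$26\,a_\text{task} = 21\,a_\text{single} + 5\,a_\text{multi}$. Calibration
makes the generator's *means* realistic; it is a documented default, not a
claim that simulated data are exchangeable with the real data.

What the generator does **not** emulate: correlation between domains beyond
the shared design (domains are simulated independently), profession- or
item-content structure, hospital-level clustering, response-order or
learning effects, and any accuracy notion. Passing tests therefore show that
the scoring and inference machinery is correct and well calibrated under a
plausible convergence process — not that the model describes real teams.

## Monte-Carlo experiments

`run_experiment()` wraps simulate → score → fit over replicates:

* `type1` / `power`: rejection rate of the time × group interaction (and the
  time main effect) at $\alpha = .05$, with exact binomial confidence
  intervals;
* `recovery`: the adherence $c$ recovered by inverting the mean single-choice
  item similarity, with bias and RMSE.

Problem sizes used by the shipped test suite were chosen to keep each run in
the low minutes while leaving Monte-Carlo error well below the tolerances
checked: the null-calibration suite uses 2000 replicates of a 15/14-team
study on a 16-item instrument (8 single + 8 multi; under the null the size
of the interaction test does not depend on instrument length, which only
shifts the outcome's variance), and recovery uses 200-team studies where the
moment inversion is accurate to within ±0.02. The acceptance script repeats
the null experiment at 1000 replicates.

## Design decisions worth knowing

* **Long response format** (one row per selected option) is the canonical
  storage; multiple selections need no delimiter conventions, and
  `wide_to_long()` converts spreadsheet-style data.
* Option identifiers are opaque strings; nothing orders them.
* Time points default to pre/post; the ANOVA engine itself accepts more
  within levels (unweighted-means solution throughout), but the study design
  is two-level and the generator follows it.
* Purely pairwise similarity — no modal-reference or accuracy scoring, and
  no member-level "sharedness with team" score.
* Reports round to 2 dp on the percentage scale while full-precision CSVs
  are always written, so presentation never limits testability.

## Known limitations

Bounded-proportion outcomes are analysed untransformed (a logit transform is
easy to apply to the score table before fitting, but is off by default to
match standard practice). Larger teams contribute more pairs and hence less
variable item scores; the team-level analysis does not reweight for that.
The unweighted-means decomposition is exact Type III for two groups but an
approximation for three or more groups with severe imbalance.
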