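---
title: "Methods: scoring, retention-curve fitting and inference for levels-of-processing forgetting studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, retention-curve fitting and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lopforget)
```

## The scientific problem

Levels-of-processing (LOP) experiments contrast memory for items encoded
under a *deep* (semantic) orienting task with items encoded under a
*shallow* (phonological or structural) task. The classic finding is a large
deep advantage immediately after study; the open question this package's
pipeline addresses is whether that advantage changes the *rate of
forgetting* — i.e. whether the deep and shallow retention curves have equal
slopes over delays of half an hour to a day. The answer matters both for
encoding theory and as a normal-forgetting baseline against which
accelerated long-term forgetting can be defined clinically.

The pipeline analyses old/new recognition data from designs in which every
participant takes an immediate test at `t = 0` on half of the studied
targets and a single delayed test on the other half with fresh distractors
(so no item is retrieved twice, avoiding testing effects), with the
retention interval varied between participants (0.5, 2, 24 h, or 0.5, 2,
6 h) and depth of encoding varied within or between participants.

## Scoring model

Recognition accuracy is scored with equal-variance signal detection theory.
For hit rate $H$ and false-alarm rate $FA$,

$$ d' = z(H) - z(FA), \qquad c = -\tfrac12\,[z(H) + z(FA)], $$

with $z$ the inverse standard normal CDF. Rates of exactly 0 or 1 make $z$
infinite, so counts are corrected log-linearly: $H = (\mathrm{hits} +
0.5)/(n_\mathrm{targets} + 1)$ and analogously for $FA$. The default applies
the correction to **every** cell, which keeps all cells on one scale; an
`loglinear_extremes_only` mode corrects only rates at 0 or 1, for
sensitivity analysis. The report records which mode was used. Neither mode
reorders two cells' raw rates.

Participants are excluded when their immediate test signals chance-level
responding ($d' \le 0$ under either encoding level; after correction a
continuous score never lands exactly on zero, so the rule uses $\le$) or an
aberrant response pattern (an immediate hit or false-alarm rate more than
2.5 sample SDs from the sample mean of that rate). The screen pools the two
encoding levels per rate — the natural reading when the two levels share a
response scale — and is applied to the corrected rates the pipeline carries;
the correction is monotone, so the screen's ordering of participants is the
same as on raw rates. With fewer than three participants the SD screen is
skipped with a warning, and a zero SD flags nobody.

## Retention functions and slope comparison

Four two-parameter forgetting curves are fitted per encoding level, with
delay $t$ in hours and performance $y$ in $d'$ units:

| form | equation |
|---|---|
| linear | $y = a - b\,t$ |
| power | $y = a\,(t+1)^{-b}$ |
| exponential | $y = a\,e^{-b t}$ |
| logarithmic | $y = a - b\,\ln(t+1)$ |

All four predict $y = a$ at $t = 0$: $a$ is the initial degree of learning
and $b$ the forgetting slope in form-specific units. Fitting minimises the
weighted squared deviation $\sum_i w_i\,(y_i - f(t_i))^2$. With unit weights
on participant-level points and with cell sample sizes as weights on cell
means the point estimates are identical (the within-cell component of the
total sum of squares does not depend on $(a,b)$), so published group means
with their $n$ are first-class inputs.

Numerically, the linear and logarithmic forms are solved in closed form.
For the power and exponential forms the intercept is profiled out —
$a(b) = \sum w y u / \sum w u^2$ with $u$ the slope basis — and the
one-dimensional profile RSS is minimised from a deterministic multi-start
grid of slopes (log-spaced over $0.01$–$4$, mirrored to negative values,
plus 0) followed by a BFGS step and a bracketed polish. Fits are therefore
reproducible without a seed; every nonlinear fixture in the test suite is
also checked against a brute-force $(a, b)$ lattice search at step $10^{-3}$.
The slope is deliberately *not* constrained to be positive: a negative
fitted slope is a model-health signal worth seeing.

Slope equality between encoding conditions is tested by a nested pair of
fits: the *constrained* model refits one condition with $b$ fixed at the
other condition's unconstrained estimate (a one-parameter linear projection,
closed form for all four forms). Under the Gaussian likelihood with profiled
variance the likelihood ratio is

$$ \chi^2(1) = N \ln\!\frac{RSS_\mathrm{constrained}}{RSS_\mathrm{unconstrained}}, $$

where $N$ counts underlying observations and both RSS values include the
within-cell component. When only cell means and standard errors are
available, the within-cell sum of squares is reconstructed per cell as
$(n-1)\,SD^2$ with $SD^2 = n\,SE^2$; this reconstruction is exact when the
SEs come from the sample itself and accurate to the rounding of printed
values otherwise.

Two calibration facts about this procedure, established by simulation in
the test suite:

* with the **true** slope imposed, the $\chi^2(1)$ reference distribution is
  accurate (measured type-I error 5.2% at nominal 5%, 1000 replicates);
* imposing a slope **estimated from a donor condition of similar size** —
  the usual study procedure — ignores the donor's sampling error and
  roughly doubles the rejection rate under equal true slopes (measured
  11.5%). Users should read non-significant results as reassuring and
  borderline significant ones with this inflation in mind.

Goodness of fit uses the full Gaussian likelihood with profiled variance:
$AIC = N\ln(2\pi\,RSS/N) + N + 2k$ and $BIC$ analogously with $k \ln N$,
where $k = 3$ (intercept, slope, residual SD) for unconstrained fits. $R^2 =
1 - RSS/TSS$ with TSS about the weighted grand mean, both including the
within-cell component. Published AIC/BIC tables depend on unpublished
trial-level residuals and on an unstated constant convention, so rankings —
which are invariant to those choices when $N$ and $k$ match — are the
meaningful comparison; with common $N$ and $k$, AIC, BIC and $R^2$ orderings
are all monotone in RSS and the package asserts their agreement. When a fit
summarises more observations than cells and no within-cell variability is
supplied, AIC/BIC are refused rather than silently mis-scaled ($R^2$ alone
is emitted).

Delays default to the nominal values (0.5, 2, 24 or 6 h) with the immediate
test at $t = 0$; mean actual delays can be passed instead via the cell
table's `delay_hours` column. At the precision of printed estimates the
fits are insensitive to this choice (we measured shifts of under 0.01 in
$a$ and $b$).

## ANOVA, effect sizes, post hocs, Bayes factors

The split-plot (mixed) ANOVA uses the classical univariate decomposition:
the between-participants stratum tests the delay-group effect against
subjects-within-groups; the within stratum tests the encoding-level effect
and the level x group interaction against the level x subject residual.
Because every participant contributes all within-factor levels, cell
frequencies stay proportional under unbalanced group sizes and the reported
sums of squares respect marginality (Type II; identical to Type I when
balanced). The fully between-participants factorial uses the
model-comparison definition of Type II directly (each main effect adjusted
for the other, the interaction adjusted for both), tested against the
full-model residual. Partial $\eta^2$ is $SS_\mathrm{effect} /
(SS_\mathrm{effect} + SS_\mathrm{error})$ with the error stratum the effect
is tested against. Sphericity corrections are not applied: the targeted
designs have a two-level within factor, for which sphericity holds
trivially; a warning is raised if a larger within factor is supplied.

Post hoc comparisons on the delay groups use Bonferroni-adjusted pairwise
$t$ tests (mixed designs, participant-level means across levels) or
Tukey-Kramer HSD on the studentized-range distribution (between designs).
Cohen's $d$ standardises the mean difference by the square root of the
pooled error mean square of the relevant stratum — the published variant is
unstated, so this choice is recorded here.

Bayes factors are computed by the BIC (unit-information prior)
approximation on nested linear models, $BF_{01} \approx \exp[(BIC_1 -
BIC_0)/2]$, mapped to the conventional evidence bins at 1, 3, 20, 150.
Reproducing default-prior ANOVA Bayes factors is out of scope; the
published claims this pipeline mirrors are categorical ("very strong" etc.),
which the approximation preserves, and every report labels the method. For
the split-plot design the nested models mirror the strata: group effect on
participant means, level effect as the intercept of the difference scores,
interaction as the group effect on difference scores.

## The generative simulator

`simulate_study()` draws full trial tables so every pipeline stage is
testable without participant data. The generative model is bi-normal
equal-variance SDT whose latent discriminability follows a retention
function:

* participant $i$ has a shared ability deviation $\delta_i \sim N(0,
  sd_a^2)$ giving $a_{i,\ell} = \max(0, a_\ell + \delta_i)$ per level
  $\ell$, and a criterion $c_i \sim N(\mu_c, \sigma_c^2)$ on the evidence
  axis;
* at delay $t$, latent $d'_i(t) = \max(0, f(t; a_{i,\ell}, b_\ell))$ —
  floored because the chance-level exclusion rule treats $d' = 0$ as the
  floor of true discriminability;
* target evidence $\sim N(d'_i(t), 1)$, distractor evidence $\sim N(0, 1)$,
  response "old" iff evidence $> c_i$ (the equal-variance assumption is
  exactly what the $d'$ and $c$ formulas presuppose);
* with probability `p_inattentive` a participant instead responds "old"
  with probability one half on every trial — the pattern the chance-level
  screen must catch;
* response times are log-normal per level, truncated at the 5-s response
  window.

The shared deviation $\delta_i$ (rather than independent per-level draws)
induces the positive within-participant correlation a split-plot analysis
assumes; with independent draws the within-participant error term would be
overstated. Targets of each level are randomly split between the immediate
and delayed tests per participant; each phase uses fresh distractors
(within-participant designs split them evenly between levels so per-level
false-alarm rates exist). Latin-square rotation of materials is simplified
to random assignment — it balances item effects that this simulator does
not model in the first place (no word frequency, concreteness or other
psycholinguistic structure, and no encoding-task accuracy).

Default parameters are the conditions of the first within-participants
experiment: the 2 x 3 mixed geometry with 30 participants per delay group,
10 targets per level per phase and 40 distractors per phase; power-law
retention with the published fitted parameters (deep $a = 2.47$, $b =
0.36$; shallow $a = 1.99$, $b = 0.44$); RT locations matching the printed
encoding RT means (2937 ms deep, 2115 ms shallow, $sdlog = 0.4$). Three
quantities have no published counterparts and were fixed once as
calibration choices: `sd_a = 0.25` d' units (so simulated immediate-cell
SEs land near the printed 0.06–0.07 once binomial measurement noise is
added), evidence threshold `criterion_mean = 1.10 +/- 0.30` (an observer
unbiased in the $c$ sense places the threshold near half the immediate
discriminability; a threshold near zero would imply a 40% false-alarm rate
and ceiling hit rates that no published cell shows), and `p_inattentive =
0.03` (reproducing exclusion counts of the order seen in the published
samples, 4 of 90 and 6 of 120).

What passing simulator-based tests do **not** show about real data: the
generator has no item effects, no encoding-task errors, no learning or
fatigue across trials, no RT--accuracy coupling, and its retention curve is
exactly the fitted form. Tests against it validate the *pipeline's
statistics*, not the psychology.

## Known limitations and numerical facts

* **Measured $d'$ is biased low in small cells.** With 10 targets per cell
  the log-linear correction caps $z(H)$ at $z(10.5/11) \approx 1.69$ and
  Jensen effects compress high rates; immediate cells are compressed more
  than delayed ones, so fitted slopes from simulated studies are biased
  down by roughly 0.03 at the default geometry. Slope-recovery error
  therefore shrinks with sample size only until it reaches this
  measurement-bias floor (the recovery test compares 10 vs 40 participants
  per group, 100 simulated studies each, where sampling noise still
  dominates).
* **LR reconstruction from printed summaries is rounding-limited.** The
  within-cell sum of squares scales with $n^2 SE^2$, so SEs printed to two
  decimals propagate an uncertainty of roughly $\pm 0.2$ into the
  reconstructed $\chi^2$ — larger than the difference between some printed
  and recomputed values.
* **Donor-slope inflation** of the LR test, described above.
* **BIC Bayes factors** approximate default-prior ANOVA Bayes factors only
  categorically.
* The bundled third-experiment cell table uses pre-exclusion 20
  participants per cell because the published report does not attribute its
  six exclusions to delay groups; supply your own `n` to override.

## Problem sizes used by the test suite

Simulation-based tests run at sizes chosen to keep Monte-Carlo error well
below the asserted margins: 2000 null replicates of the full
simulate--score--ANOVA pipeline for the interaction-size check (binomial SE
about 0.5 percentage points), 200 simulated studies for slope recovery, 400
replicates for LR calibration, and single large-sample runs (500
participants per group, 200 targets and 200 distractors per phase) for the
closed-form consistency checks of the simulator.
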