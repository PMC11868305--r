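# lopforget

Signal-detection scoring and retention-curve analysis for
levels-of-processing (LOP) forgetting studies.

## The problem this package addresses

LOP experiments contrast recognition memory for words encoded under a
*deep* (semantic) orienting task with words encoded under a *shallow*
(rhyme or consonant-vowel structure) task. Deep encoding reliably boosts
immediate performance; whether it also *slows forgetting* is a question
about the slopes of the two retention curves over delays of half an hour to
a day. That question matters for encoding theory and for defining normal
forgetting baselines against which accelerated long-term forgetting can be
diagnosed. `lopforget` packages the full analysis such studies need, for
memory researchers and clinicians who work with old/new recognition data:

* **SDT scoring** — per participant, encoding level and test phase:
  `d' = z(H) − z(FA)` and criterion `c = −½[z(H) + z(FA)]`, with log-linear
  correction of extreme rates and the pre-registered exclusion screens
  (chance-level immediate `d'`; hit/false-alarm rate beyond 2.5 SDs).
* **Retention-function fitting** — weighted least squares for the linear
  `y = a − bt`, power `y = a(t+1)^(−b)`, exponential `y = a·e^(−bt)` and
  logarithmic `y = a − b·ln(t+1)` curves (`t` in hours, `y` in d' units),
  with AIC/BIC/R² model ranking. Fits accept trial-level points or printed
  cell means weighted by `n` — the estimates are identical.
* **Slope-equality tests** — the constrained model refits one condition
  with the slope fixed from the other; the likelihood ratio
  `χ²(1) = N·ln(RSS_c/RSS_u)` tests whether forgetting rates differ, with
  within-cell variability reconstructed from printed standard errors when
  only summaries are available.
* **Inference** — split-plot (mixed) and factorial ANOVA with Type II sums
  of squares, partial η², Bonferroni and Tukey HSD post hocs, and
  BIC-approximate Bayes factors binned at the 1/3/20/150 evidence
  boundaries.
* **A generative simulator** of the study designs (bi-normal equal-variance
  evidence, latent d' decaying along a retention law, participant
  heterogeneity, inattentive responders, truncated log-normal RTs), so the
  whole pipeline is testable and calibratable without participant data.

## Worked example: refitting a published summary table

The package bundles per-cell d' summaries (mean, SE, n) from a published
three-experiment LOP forgetting study as worked-example inputs:

```r
library(lopforget)
head(lop_cell_summaries(1), 4)
#>   level     label delay_hours  n mean_dprime se_dprime
#> 1  deep immediate         0.0 86        2.61      0.07
#> 2  deep     30min         0.5 30        1.69      0.10
#> 3  deep        2h         2.0 28        1.59      0.11
#> 4  deep       24h        24.0 28        1.01      0.11

rep <- run_pipeline(list(
  mode  = "summary",
  input = system.file("extdata", "lop_exp1_cells.csv", package = "lopforget"),
  form  = "power"
))
rep
#> levels-of-processing forgetting analysis report
#>   config hash: 871f07d07bf8f5f7979e8e8afc9d441c
#>   selected retention form: power
#>   deep_unconstrained: a = 2.479, b = 0.358
#>   shallow_unconstrained: a = 1.996, b = 0.444
#>   shallow_constrained: a = 1.955, b = 0.358
#> slope-equality LR test: chi^2(1) = 2.426, p = 0.1193 (b from deep, N = 172)
```

Reading the numbers: the deep condition starts at `a = 2.48` d' and forgets
with power-law slope `b = 0.36`; the shallow condition starts lower
(`a = 2.00`) with a nominally steeper slope (`b = 0.44`). Refitting the
shallow data with the deep slope imposed costs little fit (`a` drops to
1.95) and the likelihood-ratio test does not reject equal slopes
(`χ²(1) = 2.43, p = .12`): deep encoding raises the curve without
flattening it. The ranking table confirms the power law fits best, the
logarithmic second:

```r
as.data.frame(rep$ranking$deep)[, c("form", "a", "b", "AIC", "BIC", "r_squared")]
#>          form        a          b      AIC      BIC r_squared
#> 1       power 2.478542 0.35822173 344.5925 354.0349 0.4442737
#> 2 logarithmic 2.395141 0.48104079 356.9489 366.3914 0.4028814
#> 3 exponential 2.283638 0.03998997 380.8434 390.2859 0.3138904
#> 4      linear 2.258262 0.05445628 384.7883 394.2308 0.2979723
```

The same `run_pipeline()` call accepts `mode = "simulate"` (full synthetic
study from `study_design()` + `generative_params()`, then scoring,
exclusion, ANOVA/Bayes factors, fits and slope tests end to end) and
`mode = "trials"` (your own trial-level CSV; see `?validate_trial_table`
for the schema). A thin command-line wrapper with `simulate`, `validate`
and `run` subcommands ships in `inst/scripts/lop-pipeline.R`.

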