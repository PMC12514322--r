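---
title: "Distributional delta-plot analysis of conflict-task reaction times"
author: "stroopdelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional delta-plot analysis of conflict-task reaction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stroopdelta)
```

## The problem

In a spatial Stroop task, a lateralized stimulus (an arrow, a pair of eyes,
or a face) points left or right while appearing on the left or right of the
screen; the participant reports the direction and must ignore the location.
Mean reaction times (RT) show a *standard congruency effect* (SCE) for
non-social targets — congruent trials are faster — while gaze-like social
targets often show a *reversed* congruency effect (RCE). Means, however,
hide where in the RT distribution the conflict acts. The distributional
approach implemented here works on quantiles:

1. **CDF dataset** — per participant, target type and congruency, RT
   quantiles at probabilities $p = .1, .3, .5, .7, .9$ (configurable;
   quartile- and decile-style grids are obtained by changing `probs`).
2. **Delta dataset** — the delta function
   $\Delta(p) = Q_{\text{incong}}(p) - Q_{\text{cong}}(p)$, with the
   delta-plot abscissa $\overline{RT}(p) =
   (Q_{\text{incong}}(p) + Q_{\text{cong}}(p))/2$. Positive values are an
   SCE, negative values an RCE.
3. **Three mixed models** on these datasets, pooled over studies:

   | model | fixed effects | random intercepts |
   |-------|---------------|-------------------|
   | RT    | target × congruency + target × quantile + congruency × quantile | study:participant, study:target, study:target:congruency:quantile |
   | delta | target × quantile | study:participant, study:target, study:target:quantile |
   | trend | target × poly(meanRT, 2) | study:participant, study:target, study:target:quantile-point |

   Participants are nested in studies and target type is treated as a
   study-specific feature, so between-study heterogeneity in overall speed
   and in target-specific distributions is absorbed by variance components
   rather than biasing the pooled fixed effects.

Group-level distribution summaries use *vincentization* (quantile
averaging): the arithmetic mean of participant-level quantiles at each
probability.

## Quantile estimation

Sample quantiles use the Hyndman–Fan Type-8 estimator,
$h = (n + 1/3)p + 1/3$ with linear interpolation between order statistics
(`hf_quantile8()`), the median-unbiased choice commonly recommended for RT
distribution work. `h` is clamped to $[1, n]$, so extreme probabilities in
small samples return the sample minimum or maximum. Ties are handled by
sorted order-statistic interpolation; no jitter is added. Cells with fewer
than `min_trials` (default 10) retained trials are skipped with a warning:
a `.9` quantile from a handful of trials is dominated by single
observations.

## Preprocessing rules and their order

`preprocess_trials()` applies, in a fixed order: (1) exclusion of
participants whose non-response proportion is at least
`nonresponse_threshold` (default 0.5 — pooled datasets occasionally contain
a participant who stopped responding, with rates around 64%); (2) removal
of non-responded trials; (3) the RT window, keeping the closed interval
[200, 1300] ms in `"trimmed"` mode ("shorter than 200 / longer than 1300"
are removed, so boundary values stay) or all responded trials in
`"nontrimmed"` mode; (4) the accuracy filter (correct trials only). The
final retained set is order-invariant for these filters; the fixed order
exists so that the removal report attributes each trial to one rule
deterministically. `removal_report()` is conservative by construction:
per study × target × congruency cell, removals plus retained equal the
input count.

## Inference layer

Models are fitted by REML via `lme4`/`lmerTest`. The quantile factor enters
the RT and delta models as an unordered five-level factor; the continuous
treatment of RT appears only in the trend model. Type-III F tests use
Satterthwaite denominator degrees of freedom by default;
`df_method = "kenward-roger"` is available where the small-sample
correction matters (point estimates are unaffected; only df and p change
slightly). For very large datasets the contrast layer falls back to the
asymptotic z scale (the `emmeans` size limits), which is reported in the
output columns. Effect sizes:

* $\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)$ per ANOVA term;
* Westfall's $d$ for contrasts: the estimate divided by the square root of
  the *summed* variance components (all random groupings plus residual).

Estimated marginal means use the equally weighted reference grid, so
unbalanced designs (studies contribute different numbers of participants
and not all targets) do not tilt the means. Pairwise contrasts are
Tukey-adjusted; one-sample delta-vs-zero tests are Bonferroni-adjusted
within each target type (five quantiles per family). Backward elimination
(`stepwise_reduce()`) removes, one at a time, the least significant fixed
term with $p \ge \alpha$ ($\alpha = .05$), never removing a main effect
while a retained interaction contains it and never touching the random
structure.

The trend model regresses delta on an orthogonal quadratic in the
delta-plot abscissa. Reported coefficients are on the raw millisecond
scale (ms of delta per ms of mean RT, and per ms²), evaluated at the mean
abscissa via `emmeans::emtrends` — the same convention used in the
published analyses this package mirrors, which is why the predictor is not
re-centred within target type. The printed random term grouping by a
continuous covariate is implemented as a random intercept per unique
study × target × quantile-point cell, its practical effect. A quadratic
delta profile can carry a sign ambiguity between the orthogonal and raw
parameterizations; `orthopoly_raw_coefs()` converts exactly (fitted values
agree to numerical precision), and no sign is hard-coded anywhere.

## The synthetic cohort generator

The generator exists so every downstream stage can be validated against
closed-form ground truth. Congruent RTs are ex-Gaussian,
$X \sim \mathrm{exG}(\mu, \sigma, \tau)$; incongruent RTs apply a
percentile-indexed shift to a fresh draw:
$$ g(x) = x + \delta(F(x)), \qquad \delta(p) = a + b p + c p^2 , $$
with $F$ the baseline CDF. When $g$ is strictly increasing — enforced at
profile construction on a $10^4$-point grid spanning baseline quantiles
$10^{-4}$ to $1 - 10^{-4}$, with zero tolerance — the incongruent
$q$-quantile equals $Q_{\text{cong}}(q) + \delta(q)$ *exactly*, so the
vincentized delta function has a known population value at every
probability. Study- and participant-level additive offsets cancel exactly
in each participant's delta. This generator is deliberately
phenomenological: it is not a dual-route or diffusion-model account of
conflict, and none of its parameter values is an empirical claim.

Defaults sketch a multi-study cohort of the kind the method targets:
11 studies × 64 participants × 80 trials per cell; arrows
$\mathrm{exG}(380, 40, 110)$ with a flat $\delta \equiv +31$ ms (an SCE
across the whole distribution); face and eyes $\mathrm{exG}(460, 45, 140)$
— roughly 100 ms slower — with negative, saturating profiles solving
$\delta(.1) = 0$ (face $b = -100$, $c = 35$; eyes $b = -75$, $c = 27.5$),
so the reversed effect is absent in the fastest responses and grows toward
the slow tail, with mean deltas near $+31 / -29 / -21$ ms. Nuisance
processes: 6% errors, 2% non-responses (RT missing), 1% contaminant RTs
uniform outside the analysis window. Study and participant offsets have
SDs of 30 and 40 ms.

What the generator does *not* emulate: participant-level heterogeneity of
the congruency effect, error-rate dynamics across the distribution
(conditional accuracy), fatigue or sequential effects, and
study-level differences in the *shape* (rather than location) of RT
distributions. Passing tests therefore show the pipeline recovers what it
claims under a clean generative model — not that the mixed-model standard
errors are exactly calibrated for arbitrary real data.

## Numerical and design choices

* **Optimizer**: `lme4` defaults (bounded nonlinear optimization on the
  relative-covariance scale). Singular fits are expected under degenerate
  fixtures (true zero variance components) and are flagged, not fatal;
  hard optimizer failure is an error carrying the diagnostics.
* **Determinism**: all generator randomness flows from one integer seed;
  identical configuration gives byte-identical trial tables, and
  `run_pipeline()` writes a manifest (seed, configuration, versions) that
  reproduces every output.
* **Degenerate inputs**: empty trial tables, cells missing one congruency
  (dropped with a warning rather than imputed), all-incorrect data and
  single-target cohorts (the trend model drops the target factor) are all
  defined behaviours with tests.

## Validation experiments and their sizes

The test suite regenerates everything from code; the problem sizes are
choices of this package:

* **Quantile oracle**: `hf_quantile8` against an independent reference
  implementation on 1000 random sample/probability pairs, to $10^{-9}$.
* **Vincentized recovery**: 200 participants × 400 trials/cell with
  $\delta(p) = 40 - 80p$; recovered group deltas within 3 ms of
  $(32, 16, 0, -16, -32)$. This experiment runs in non-trimmed mode: the
  200–1300 ms window would censor ~0.1% of the slow ex-Gaussian tail and
  bias the .9 quantile by about 1 ms, which is a property of trimming,
  not of the quantile engine under test.
* **Trend recovery**: 50 replicates of 20 participants × 100 trials/cell.
  The estimand is the derivative, at the mean abscissa, of the population
  least-squares quadratic through the five population
  $(\overline{RT}, \delta)$ points. Offsets are set to zero in this
  experiment: additive shifts translate each participant's delta-plot
  horizontally without changing its deltas, which attenuates the pooled
  trend — with them, the estimand itself changes. Coverage of the 95% CI
  exceeds 90%.
* **Calibration**: 1000 null replicates of the delta-model structure
  (4 studies × 6 participants × 2 targets × 5 quantiles) put the type-I
  error of the target × quantile F test inside [.035, .065]; REML
  variance components are recovered within 15% (participant SD 40 ms,
  residual 60 ms, 20 studies × 20 participants, 50 seeds); balanced-design
  EMMs equal cell means to $10^{-8}$.
* **Qualitative pattern**: a 6-study cohort with the flat-positive arrows
  profile and the early-null negative face profile reproduces the
  signature findings — SCE significant at every quantile for arrows, RCE
  non-significant at the first probability and significant thereafter for
  the social target, and a significantly more negative social linear trend
  (Bonferroni-adjusted).

## Known limitations

* The five quantile estimates of one participant × condition cell are
  computed from the *same* trials, so their errors are correlated. The
  mixed models assume independent residuals given the random intercepts;
  in consequence model-based standard errors for contrasts that average
  over quantiles are somewhat anti-conservative under the generator
  (empirically, CI coverage of RT-model congruency contrasts is ~80–90%
  rather than 95%, and Kenward–Roger does not repair it — the issue is
  the residual correlation, not small-sample df). Point estimates are
  unbiased; the suite tests exactly that. With real data, genuine
  between-participant effect heterogeneity loads on the same variance
  components and partially masks this.
* The single distributional variance component per model pools across
  target types; when targets differ strongly in tail weight (as the
  defaults do), the pooled SE understates the noisier target's
  uncertainty.
* Exact Kenward–Roger is available only through the installed `pbkrtest`
  backend; there is no from-scratch implementation, and no random slopes
  or crossed (non-nested) participant structures.
* Trimming interacts with extreme quantiles; robustness of conclusions
  should be checked with `mode = "nontrimmed"` and alternative probability
  grids, both of which are first-class options.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(n_studies = 4, participants_per_study = 12,
                  trials_per_cell = 60, seed = 11)
trials <- simulate_cohort(cfg)
fit <- delta_analysis(trials)
print(fit)
plot(fit, type = "delta")
summary(fit)

# persisted, reproducible run
run_pipeline(pipeline_config(sim = cfg, seed = 11), "run01")
```
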