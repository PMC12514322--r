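# stroopdelta

Distributional delta-plot analysis of reaction times from spatial conflict
(spatial Stroop) tasks pooled across studies, for researchers studying how
congruency effects unfold across the RT distribution — in particular the
contrast between non-social targets (arrows), which show a *standard
congruency effect* (SCE, congruent faster), and social targets (faces,
eyes), which can show a *reversed* congruency effect (RCE) that emerges
only in slower responses.

## What it computes

Starting from trial-level data (study, participant, target type,
congruency, RT, accuracy), the package builds:

1. the **CDF dataset** — per-participant RT quantiles at probabilities
   *p* = .1, .3, .5, .7, .9 (configurable), using the Hyndman–Fan Type-8
   estimator *h* = (*n* + 1/3)*p* + 1/3;
2. the **delta dataset** — the delta function
   Δ(*p*) = *Q*<sub>incong</sub>(*p*) − *Q*<sub>cong</sub>(*p*) with the
   delta-plot abscissa (mean of the two parent quantiles);
3. three **linear mixed models** with a study-nested random structure
   (participants nested in studies, target type as a study-specific
   feature):
   - RT model: `RT ~ target*congruency + target*quantile +
     congruency*quantile + (1|study:participant) + (1|study:target) +
     (1|study:target:congruency:quantile)`
   - delta model: `delta ~ target*quantile + (1|study:participant) +
     (1|study:target) + (1|study:target:quantile)`
   - trend model: `delta ~ target*poly(meanRT, 2)` with the same nesting,
     quantifying the delta-plot shape via raw-scale linear (ms/ms) and
     quadratic (ms/ms²) coefficients;
4. the **contrast layer**: estimated marginal means (EMM-RT, EMM-Δ),
   Tukey-adjusted pairwise contrasts, Bonferroni-adjusted delta-vs-zero
   tests per quantile, partial eta squared
   (η²p = F·df1/(F·df1 + df2)) and Westfall standardized effect
   sizes (estimate / √(sum of variance components)).

A synthetic multi-study cohort generator with ex-Gaussian baselines and a
closed-form percentile-indexed congruency shift δ(*p*) = *a* + *b p* +
*c p*² provides known ground truth for every stage: when the induced
transform *g*(*x*) = *x* + δ(*F*(*x*)) is strictly increasing, the
incongruent *q*-quantile equals *Q*<sub>cong</sub>(*q*) + δ(*q*) exactly.

## Worked example

```r
library(stroopdelta)

cfg <- sim_config(n_studies = 4, participants_per_study = 12,
                  trials_per_cell = 60, seed = 11)
trials <- simulate_cohort(cfg)   # 4 x 12 x 3 targets x 2 x 60 = 17,280 trials
fit <- delta_analysis(trials)
print(fit)
```

```
Distributional delta-plot analysis
  15785 trials retained, 48 participants, 4 studies; probs: 0.1, 0.3, 0.5, 0.7, 0.9
  df method: satterthwaite; window: [200, 1300] ms (trimmed)

Delta-model ANOVA:
            term       F df1 df2         p   eta_p     df_method
1             qq   6.980   4 658 1.662e-05 0.04070 satterthwaite
2    target_type 179.625   2 658 5.659e-63 0.35316 satterthwaite
3 qq:target_type   3.977   8 658 1.289e-04 0.04612 satterthwaite

EMM-delta by target type (ms):
 target_type    emmean       SE     df  lower.CL  upper.CL
 arrows       30.96081 2.816469 180.36  25.40334  36.51827
 eyes        -15.43494 2.816469 180.36 -20.99240  -9.87747
 face        -32.76168 2.816469 180.36 -38.31915 -27.20422

Trend coefficients:
  target_type    degree       coef        SE    df   lower_cl   upper_cl
1      arrows    linear  0.0187598 0.0272326 689.8 -3.471e-02  0.0722284
2        eyes    linear -0.1016494 0.0309129 699.7 -1.623e-01 -0.0409563
3        face    linear -0.1857169 0.0316746 699.7 -2.479e-01 -0.1235282
...
```

Reading the output: the delta-model ANOVA shows a target-type effect and a
target × quantile interaction; the EMM-Δ values say arrows carry a +31 ms
SCE while face (−33 ms) and eyes (−15 ms) carry an RCE — matching the
profiles the generator injected (+31 / saturating-negative). The negative
linear trend coefficients for the social targets (−0.19 and −0.10 ms of
delta per ms of RT) quantify the RCE growing toward the slow tail, while
the arrows trend is flat. `plot(fit, type = "delta")` draws the delta
plot, `plot(fit, type = "cdf")` the quantile CDF by condition;
`summary(fit)` adds the RT-model ANOVA and the Bonferroni-adjusted
delta-vs-zero tests per quantile. `run_pipeline(pipeline_config(...), dir)`
persists every table, both figures and a reproducibility manifest.

Real datasets enter through `read_trials(path, column_map)` (CSV/TSV with
flexible column naming), followed by the same `delta_analysis()` call;
preprocessing (participant exclusion, 200–1300 ms window, correct-only)
follows the conventions of the pooled spatial-Stroop literature and each
rule's removals are accounted per cell in the removal report.

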