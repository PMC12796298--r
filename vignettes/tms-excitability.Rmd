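---
title: "Ratio-to-baseline excitability metrics and the diagnostic pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-to-baseline excitability metrics and the diagnostic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single- and paired-pulse transcranial magnetic stimulation (TMS) of the
motor cortex evokes motor-evoked potentials (MEPs) whose peak-to-peak
amplitude is the standard functional proxy of corticospinal excitability.
Raw MEP amplitudes are notoriously variable within a subject, between
subjects and across sessions, so they are usually averaged before analysis —
which throws away the trial-level information a data-driven classifier
needs, and leaves the aggregate hostage to each subject's idiosyncratic
amplitude scale.

This package implements an alternative: every stimulation is expressed
relative to the single-pulse baseline of its own session. For a MEP
amplitude $X$ and the $m$ single-pulse amplitudes $T_1,\dots,T_m$ of the
same session,

$$\varrho = \frac{X\,m}{\sum_{i=1}^m T_i}, \qquad
  \delta = \frac{X}{m}\sum_{i=1}^m \frac{1}{T_i},$$

i.e. the amplitude divided by the arithmetic ($\varrho$) or harmonic
($\delta$) mean of the baseline. Both are dimensionless and invariant to any
positive rescaling of a session's amplitudes, so they cancel
subject- and session-level gain while preserving trial-level resolution. For
a paired pulse they directly quantify the intracortical facilitation
($>1$) or inhibition ($<1$) induced by the conditioning stimulus at that
interstimulus interval (ISI).

Two exact identities are worth keeping in mind (and are enforced by the test
suite to 1e-12):

* **AM–HM inequality.** $\delta \ge \varrho$ for every row, with equality
  exactly when the baseline amplitudes are all equal.
* **Conservation.** Because single pulses are members of their own baseline,
  within a session the mean of $\varrho$ over the singles is exactly 1 and
  the mean of $1/\delta$ over the singles is exactly 1. A leave-one-out
  baseline (each single referenced to the other $m-1$) is available via
  `annotate_metrics(leave_one_out = TRUE)` but is off by default, matching
  the definition above.

## The measurement model and the synthetic cohort

MEP amplitudes are modelled as Gamma random variables,
$X \sim \Gamma(\alpha, \theta)$ with shape $\alpha$ and scale $\theta$ in
microvolts. The generator (`generate_cohort()`) is purely distributional —
it draws amplitudes per protocol cell rather than simulating EMG physics —
because everything downstream consumes only the amplitude table. Stimulation
intensities (80% / 120% of resting motor threshold) are carried as protocol
metadata only.

The default protocol is one session per subject with 8 paired pulses at each
of ISIs 4, 5, 8, 10, 15, 20 ms randomly intermixed with 24 single pulses (72
pulses per session), for a cohort of 26 depressed (MDD) and 17 healthy
control (HC) subjects. The effective Gamma scale of a draw is

$$\theta_{\text{eff}} = \theta_0 \cdot s_{\text{subject}} \cdot
  g_{\text{group}} \cdot m_{\text{ISI}},$$

with the defaults:

| parameter | default | why |
|---|---|---|
| base shape $\alpha$ | 2 | right-skewed, strictly positive amplitudes with the heavy within-cell variability (CV $\approx$ 0.7) typical of trial-level MEPs |
| base scale $\theta_0$ | 150 µV | puts single-pulse means near 300 µV, a realistic suprathreshold MEP scale |
| subject multiplier $s$ | log-normal, log-sd 0.5 | between-subject amplitude heterogeneity of roughly $\pm$50%, which deliberately obscures raw amplitudes as a group marker |
| MDD scale factor $g$ | 1.25 (HC: 1) | a global hyper-excitability shift in the patient group |
| ISI modulation $m$ (HC) | 0.70, 0.75, 1.10, 1.30, 1.40, 1.20 | residual inhibition at short intervals, facilitation peaking at 10–15 ms |
| ISI modulation $m$ (MDD) | 1.00, 1.05, 1.45, 1.70, 1.80, 1.50 | reduced inhibition and enhanced facilitation, consistent with GABAergic-deficit accounts of depression |

These effect sizes are the package's own synthetic choices — they are *not*
estimates from any clinical dataset (no such estimates are publicly
available). They were fixed once, on physiological plausibility, with the
group signal deliberately placed in two places: the overall scale (so high
raw amplitudes lean toward MDD) and the ISI-specific paired/single ratios
(so $\delta$ and $\varrho$ carry information that survives the subject-level
gain noise). What the generator does **not** emulate: EMG waveforms and
artifacts, motor-threshold determination, multiple sessions or nights,
drift within a session, demographic covariates, and any real-data effect
sizes. Consequently, green tests demonstrate that the pipeline is correct
and that the qualitative study logic is reproducible under its stated
assumptions — they say nothing about clinical validity on real recordings.

Determinism contract: a cohort is a pure function of its
`cohort_config()` (including the seed), and the caller's RNG state is left
untouched.

## Preprocessing

Outliers are removed from raw amplitudes by the Tukey/IQR rule before any
metric is computed, so an outlier can never contaminate a session baseline.
`iqr_filter()` keeps values in $[Q_1 - k\,\mathrm{IQR},\, Q_3 +
k\,\mathrm{IQR}]$ with $k = 1.5$ by default. Two conventions are fixed and
documented because the removed-row count depends on them: quartiles use
linear interpolation (R's type-7, the default in most software), and the
fences are computed globally over all amplitudes. The global scope is the
minimal reading of "IQR criteria on MEP amplitudes"; per-subject and per-ISI
scopes are exposed through `build_feature_table(scope = )` for sensitivity
analyses, since amplitude distributions differ across subjects. A session
that loses every single pulse to cleaning is a hard error naming the
session — there is no defensible baseline to fall back on.

## Distributional checks

`gamma_cell_report()` averages amplitudes within subject, stratifies the
subject means by ISI × group, fits $\Gamma(\alpha, \theta)$ by maximum
likelihood per cell and runs a one-sample Kolmogorov–Smirnov test against
the fitted distribution. Two deliberate choices:

* The two-parameter Gamma (location fixed at 0) is fitted via
  `fitdistrplus` with a tightened optimizer tolerance; the estimates agree
  with a direct maximization of the likelihood to better than 1e-6
  (the test suite checks this against the exact score-equation solution).
* The default p-value treats the estimated parameters as known. This is the
  procedure as commonly practised, and it is *conservative*: estimating the
  parameters from the same sample shrinks the KS statistic, so the true null
  rejection rate falls below the nominal level (the acceptance suite
  verifies $\le 5\%$ at $\alpha = 0.05$ over 1000 simulations). A calibrated
  parametric-bootstrap p-value is available with
  `ks_gamma_test(bootstrap = TRUE)` for users who want nominal error rates.

Cells with fewer than three subject means are skipped rather than fitted
degenerately.

## The principal-component mixed-effects logistic model

MEP amplitude, $\delta$ and $\varrho$ are strongly collinear by
construction. Rather than putting three entangled predictors into one
regression, the pipeline z-scores the three columns, takes the first
principal component, and uses it as the sole predictor of diagnosis:

$$\mathrm{logit}\,P(y_{ij} = \mathrm{MDD}) = \beta_0 +
  \beta_1\,\mathrm{PC}^{(1)}_{ij} + b_{0j} + b_{1j}\,\mathrm{PC}^{(1)}_{ij},$$

with $j$ indexing the seven ISI levels (0 encodes single pulses) and
independent random intercept $b_{0j}$ and slope $b_{1j}$ per level. Design
choices:

* PCA runs on sample-level rows *first*; the scores are then averaged within
  subject × ISI to form the model's observations. The aggregated table has
  one row per subject × ISI present (43 × 7 = 301 when no cell is emptied by
  cleaning).
* The eigenvector sign is arbitrary, so it is anchored by a non-negative
  loading on MEP amplitude; $\beta_1 > 0$ then reads "higher excitability,
  higher odds of MDD".
* The random intercept and slope are modelled as independent
  (`(1|isi) + (0+pc1|isi)`): the model statement contains no correlation
  term, and with seven grouping levels a free correlation is weakly
  identified anyway.
* Estimation is maximum likelihood with the Laplace approximation
  (`lme4::glmer`). Variance estimates on the boundary (zero) are reported
  with a `boundary` flag, not an error — a boundary fit collapses to
  ordinary logistic regression, and the fixed effects then match `glm` to
  optimizer precision. Complete separation (where the inner PIRLS loop
  diverges) is caught and returned as a flagged non-convergence report
  carrying the plain logistic fit.

## The classifier comparison

Three gradient-boosted tree classifiers (250 trees, learning rate 0.1,
maximum depth 8, logistic loss, single-threaded and seeded) are trained on
identical 10-fold stratified splits, differing only in columns:

1. `mep_isi` — raw amplitude + ISI;
2. `deltarho_isi` — $\delta$, $\varrho$ + ISI;
3. `all` — all four features.

Folds are assigned to *rows* (individual stimulations), stratified on
diagnosis only. This replicates the study design being modelled, and it
matters for interpretation: a subject's pulses appear in both train and test
folds, so the all-features model can partly re-identify subjects (amplitude
and $\delta$ jointly encode a subject's baseline mean). That leakage is one
plausible reason the combined model outperforms both restricted ones.
`run_feature_set_comparison(group_by_subject = TRUE)` provides the honest
alternative that assigns whole subjects to folds.

Per fold, eight metrics are computed with MDD as the positive class and a
0.5 probability threshold for label metrics: accuracy, balanced accuracy
(mean per-class recall), Cohen's kappa, Matthews correlation, F1, recall,
ROC-AUC (rank/Mann–Whitney formulation, half credit for ties) and the area
under the precision–recall curve (interpolation-free step sum over
descending score thresholds, ties processed as one threshold). Conventions
for degenerate cases: kappa and MCC return 0 on a zero denominator; a
single-class test fold is an error (it cannot occur under stratified folds).
Fold-wise metrics are compared between consecutive models by two-sided
paired t-tests (pairing on fold); a constant difference vector leaves the t
statistic undefined and is reported as p = 1 with a `zero_variance` flag.

## Attribution

SHAP values for the all-features model are computed per fold on the held-out
rows only, then pooled; because $\delta$ and $\varrho$ are collinear their
contributions are additionally summed into a combined column. The
implementation in `src/treeshap.cpp` is the standard path-dependent TreeSHAP
recursion with cover-weighted conditional expectations, computed in double
precision so that local accuracy — bias plus contributions equals the model
margin — holds to numerical round-off (~1e-14) rather than to the
single-precision storage of the booster's own contribution output (~1e-6 at
this model size). Split comparisons are done in single precision to
replicate the booster's traversal exactly, and the unit tests cross-check
the contributions against `xgboost`'s native `predcontrib` at float32
tolerance. Gini importance is the per-model gain share (loss reduction
attributable to splits on each feature, normalised to sum to 1; features
never split on get exactly 0), averaged across folds.

## Orchestration and reproducibility

`run_pipeline()` chains the stages
(simulate → clean/annotate → distribution report → PC-GLMM →
comparison/attribution), writes every table as CSV and every report as JSON,
and ends with a manifest recording the full configuration and package
version. Reruns with the same config are byte-identical; the manifest
round-trips through `read_run_config()` so a run can be reproduced from its
own output. A thin command-line front end (`inst/cli/tmsmep.R`) exposes the
stages as subcommands over the same CSV/JSON schemas, so real recordings in
the stimulation schema can be substituted for the generator without code
changes.

## Problem sizes used by the test suite

The packaged checks run the full default cohort (3096 pulses) for the
end-to-end properties; 1e5 draws for Gamma parameter recovery (2%
tolerance); 1000 simulations for the KS null-rejection bound; 200 replicates
each for GLMM slope recovery (coverage ≥ 90%) and the type-I check; and 1000
random instances for the metric oracles at 1e-12. These sizes were chosen so
each property is tested with comfortable statistical margin while the whole
suite stays quick enough to run routinely.

## Known limitations

* The synthetic effect sizes are plausible, not estimated; absolute
  performance numbers on synthetic data are properties of the generator
  config, and only the qualitative structure (ordering of the three models,
  sign of effects) is a designed outcome.
* Row-level cross-validation leaks subject identity (see above); the
  subject-grouped mode gives systematically lower, more honest estimates.
* The default KS p-values are conservative by construction; use the
  bootstrap mode for calibrated inference.
* The GLMM's grouping factor is the ISI level (7 levels), not the subject;
  with so few levels, variance estimates are imprecise and frequently hit
  the boundary.
* $\delta$ and $\varrho$ require at least one surviving single pulse per
  session; sessions failing that are an error by design.
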