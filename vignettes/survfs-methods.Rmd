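---
title: "Selecting features from highly censored survival cohorts: the survfs model and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting features from highly censored survival cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survfs)
```

## The problem

Post-operative surveillance registries — the motivating case is follow-up
after endovascular aortic aneurysm repair (EVAR), where dozens of aortic
morphology measurements are taken per patient — routinely produce cohorts in
which 90% or more of patients never experience the event of interest within
the study window. The clinical question is which few of the ~45 measured
features predict five-year re-intervention risk, so that surveillance can be
risk-stratified and unnecessary measurements dropped.

Standard wrapper feature selection cannot be applied directly: a classifier
needs a class label per patient, and a censored patient (lost to follow-up
before five years, event-free) has none. The usual escapes — discarding
censored patients or calling them event-free — are badly biased at 90%
censoring. `survfs` implements a different route: *impute* the missing risk
label from the joint distribution of the features, then wrap a classifier
search around the imputed cohort while scoring candidate feature subsets
only on genuine (time, event) survival data via the log-rank test.

## The model

The pipeline has three layers.

**1. Factor-analysis reduction.** Morphology panels are strongly collinear
(diameters, volumes and angulations of the same anatomy). A common-factor
model with \(m\) factors is fitted to the standardized features by
principal-axis factoring and rotated by varimax; a variable's *communality*
\(h_i^2 = \sum_j \lambda_{ij}^2\) is the variance share explained by the
common factors and its *uniqueness* is \(u_i = 1 - h_i^2\). Features whose
uniqueness exceeds a cut-off load on no factor and are dropped before the
expensive wrapper search. The factor count is the smallest \(m\) whose
leading correlation-matrix eigenvalues explain 80% of total variance
(`select_n_factors`); adequacy is checked first by the Kaiser–Meyer–Olkin
statistic and Bartlett's sphericity test (`adequacy_tests`).

The cut-off itself is read off the histogram of uniquenesses (bin width
0.05 by default): the left edge of the first bin whose count falls to at
most half the preceding non-empty bin's count, provided mass remains above
it — the "first sudden drop". When no drop exists the conventional 0.25
communality rule is used. If the histogram rule would leave fewer than two
features, `survfs()` falls back to 0.25, then to no reduction, with a
warning.

**2. Bayesian-network uncensoring.** Uncensored patients at horizon
\(h = 5\) years split into a *high-risk* group (event at \(t \le h\)) and a
*low-risk* group (followed beyond \(h\)). Features are discretized into
equal-width bins (5 by default, learned on the high+low rows). One discrete
Bayesian network is learned per group — hill climbing over single-edge
moves under an MDL score, maximum-likelihood CPTs with a Laplace
pseudo-count — and each censored patient \(x_c\) receives the normalized
two-network posterior

\[
P(O^{high} \mid x_c) =
\frac{\hat P(O^{high})\,\hat\ell(x_c \mid B^{high})}
     {\hat P(O^{high})\,\hat\ell(x_c \mid B^{high}) +
      \hat P(O^{low})\,\hat\ell(x_c \mid B^{low})},
\qquad
\hat\ell(x_c \mid B) = \prod_i p(V_i = x_{c,i} \mid \pi(V_i)),
\]

computed in log space. The patient is labeled high risk when the posterior
exceeds the *censoring-correction threshold* \(P_{Th}\) (default 0.5). The
instance's own marginal probability cancels in the normalization, so the
posterior is invariant to any common scaling of the two likelihoods, and
the two posteriors sum to one.

**3. Stepwise ANN wrapper with nested cross-validation.** The classifier is
a three-layer sigmoid perceptron trained by full-batch gradient descent
with momentum (defaults: learning rate 0.1, momentum 0.9, 500 epochs) on
the imputed labels. A candidate feature subset is scored by
`nested_cv_pvalue`: each permuted replica of the outer training fold is
split into nested folds; *inside every inner split* the uncensoring is
re-run on the inner training portion only, the ANN is trained on it, the
inner test patients are assigned to predicted risk groups, and the log-rank
p between those groups on the inner test's true (time, event) data is
recorded; the average over all replica × fold evaluations is the subset's
score. The stepwise search (`stepwise_select`) eliminates the feature whose
removal gives the smallest averaged p, repeats until all features are
visited, and then offers eliminated features re-entry, committing additions
only when they beat the best averaged p seen so far. The outer loop
(`select_final_model`) runs this search per outer training fold and neuron
count, picks each fold's candidate by the inner criterion, scores the
candidates on their untouched outer test folds by log-rank p, and refits
the winner on the whole training center. Model transfer is judged on an
independent second center (`evaluate_on_center`): log-rank p of the
predicted groups, Harrell's concordance of the continuous score, Uno's
IPCW AUC at the horizon, and sensitivity against the uncensored high-risk
group.

## Parameters that matter

| Parameter | Default | Meaning / why |
|---|---|---|
| `horizon` | 5 years | clinical risk horizon defining the groups |
| `p_th` | 0.5 | posterior cut-off for imputing "high risk"; symmetric because neither error is privileged a priori |
| `n_bins` | 5 | equal-width bins; coarse enough for ~90-patient groups, fine enough to keep shape |
| `smoothing_alpha` | 1 | Laplace pseudo-count; pure ML (`alpha = 0`) is supported but yields \(-\infty\) likelihoods from sparse CPTs at these sample sizes |
| `max_parents` | 3 | caps CPT size at \(5^3\) rows per node, bounding variance |
| `prior_rule` | group proportions | \(\hat P(O^{high})\) from the uncensored groups; a uniform option exists |
| `outer_k`, `inner_k`, `replicas` | 5, 5, 5 | the full nested design: 25 inner evaluations per candidate subset |
| `neuron_grid` | 2–10 | hidden-layer sizes tried per outer fold |
| `lr`, `momentum`, `epochs` | 0.1, 0.9, 500 | conventional gradient-descent-with-momentum settings |
| `variance_fraction` | 0.80 | scree target for the factor count |
| `bin_width` | 0.05 | uniqueness-histogram resolution |

Tie-breaks and degenerate cases are deterministic: equal-scoring structure
moves resolve lexicographically by (parent, child, move type); equal
stepwise moves prefer the lexicographically first feature; an inner split
whose partition cannot support network learning (fewer than 5 patients in
either group), or whose predicted groups collapse to one, contributes
p = 1 — a conservative "no separation" verdict. ANN scores of exactly 0.5
classify low. Heywood cases in the factor fit are handled by flooring
uniquenesses at \(10^{-3}\) rather than aborting. Every stage derives its
randomness from one master seed, so the whole pipeline is reproducible
bit for bit.

## The synthetic cohort generator

Because the clinical EVAR datasets are not public, the package ships a
generator (`synth_config`, `generate_cohort`, `generate_two_centers`)
emulating their structure: 457 patients, 45 continuous features with a
six-factor latent structure (25 features load 0.8 on one factor each, 20
are pure noise — exercising the reduction step), Weibull event times with
shape 1.2 and scale 60 years whose log-hazard is linear in 3 informative
features, and independent Uniform(0, c<sub>max</sub>) follow-up, with
c<sub>max</sub> calibrated by root-finding so the expected event-free
fraction matches a target (0.91 by default). Uniform censoring mimics
staggered entry into a fixed-length study — the mechanism that produces
very high censoring alongside patients followed beyond five years, which a
memoryless censoring law cannot do. The ground-truth risk class is a
median split on the informative linear predictor, so under a null
(all-zero) hazard the truth grouping is independent of survival and
p-values are exactly null-calibrated.

What the generator does *not* emulate: real morphology marginals (units,
skewness), covariate-dependent censoring, inter-center differences beyond
a mean shift, and measurement error. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration, not clinical
performance.

## Design choices made where the design was open

* **Late events are low risk.** A patient with an event after five years
  did not need intervention within the horizon; the grouping is about the
  horizon, not lifetime outcome. A flag (`late_events_low = FALSE`)
  reclassifies them as censored instead.
* **Factor extraction** is principal-axis factoring on standardized
  variables — the standard common-factor choice, stable at n ≈ 457; no
  oblique rotation is offered because uncorrelated rotated factors are the
  point of the varimax step.
* **Class priors** for the posterior default to the uncensored-group
  proportions; they are the only empirical estimate of the horizon risk
  available before imputation.
* **Re-uncensoring inside every inner split** is deliberate: learning the
  networks once per replica would let inner-test patients influence their
  own labels, a leakage path the nested design exists to close.
* **MDL score** for structure search is log-likelihood minus
  \((\log N / 2)\) per free parameter (the BIC-type description length).
* **Neuron count per fold** is chosen by the inner criterion; outer test
  folds only arbitrate *between* fold candidates, never inside a search.
* **Cox baselines** use Breslow tie handling everywhere, BIC with
  log(events) as the sample-size term (survival convention), lasso via the
  standard coordinate-descent path, and SCAD (a = 3.7) by local linear
  approximation around that path with the tuning parameter chosen by
  10-fold cross-validated partial likelihood. Mean-risk-score thresholding
  converts each Cox score to risk groups: the training-center mean is the
  threshold, applied unchanged to the second center.
* **Concordance SE** is the infinitesimal-jackknife estimator from the
  `survival` package's pair-counting routine.

## Problem sizes used by the test and acceptance runs

The statistical checks run at sizes chosen to make their Monte Carlo error
small relative to the asserted margins while remaining single-CPU friendly:
oracle equivalences on ≤30-patient fixtures; factor recovery at n = 2000;
censoring calibration at n = 5000; the wrapper-recovery study at the study
scale (n = 450, 20 features, 3 informative, 85% censoring) with a reduced
nested design (2 replicas × 2 nested folds, 5 hidden neurons, 300 epochs);
null calibration with 100 seeded end-to-end runs (2 outer folds, 1 replica
× 2 nested folds, 5 hidden neurons trained for 1000 epochs — enough
capacity that the null classifier fits its noise labels rather than
collapsing to a constant, whose degenerate one-group prediction would pile
p-values at 1); and the acceptance script's full pipeline at the default
study conditions (457 + 274 patients, 45 features, 91% censoring) with 3
outer folds, 1 replica × 2 nested folds and neuron grid {3, 5, 7}. The
full 5 × 5 × 5 design with the 2–10 neuron grid remains the package
default for analyses.

## Known limitations

* The log-rank criterion judges *separation*, not calibration; the ANN
  score is not a calibrated five-year risk probability.
* Equal-width discretization is sensitive to outliers (bins learned on the
  training rows are clamped for new data, mitigating but not removing
  this).
* With very few events per inner fold the criterion saturates at p = 1 and
  the search loses direction; the stratified splits protect the event
  budget but cannot create events.
* Uno's AUC needs the censoring survival curve to stay positive up to the
  horizon in the training center; it is reported as missing otherwise.
* Imputation quality degrades when the high/low groups are tiny (tens of
  patients): the networks then rarely learn edges and the posterior leans
  on the class prior.

## A worked miniature

```{r example, eval = FALSE}
cfg <- synth_config(n = 300, p_total = 10, n_noise = 3, n_factors = 2,
                    informative_idx = 1:2, beta = c(1.5, 1.5),
                    censor_rate_target = 0.6, seed = 7)
pair <- generate_two_centers(cfg)
fit <- survfs(data = pair$center1,
              cfg = fs_control(outer_k = 2, inner_k = 2, replicas = 2,
                               neuron_grid = c(3, 5), epochs = 300,
                               seed = 7))
summary(fit)
evaluate_on_center(fit, pair$center2)
```

The same flow at full defaults is what `run_pipeline()` executes, together
with the four Cox baselines, producing the method × center comparison
table.
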