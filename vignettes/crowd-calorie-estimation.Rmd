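---
title: "Crowdsourced calorie estimation: models, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowdsourced calorie estimation: models, generator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdcal)
```

## The problem

People are asked to guess the calorie content of pictured foods whose true
energy is known. Each response is a triple (participant, food, estimate in
kcal), bounded by the quiz interface to 50–800 kcal. From these responses the
package computes accuracy and bias statistics, aggregates crowds, fits
mixed-effects bias regressions, and builds a food-by-food error-correlation
network. The packaged `"table1"` quiz holds the 20 foods used in the original
online study: 12 single-ingredient items and 8 mixed dishes, energies 100–720
kcal, six photographed next to a reference object for scale.

## Error measures

With estimate $\hat c$ and ground truth $c$:

* error $e = \hat c - c$ (kcal; positive = overestimate),
* percent error $\eta = e / c$ (stored as a fraction; scale-free),
* absolute error $|e|$,
* discrete accuracy $D$ = the number of a participant's answers with
  $|\eta| \le 0.20$.

"Within 20%" is treated as *inclusive* at the boundary. The original study
does not say whether exactly 20% counted; including it is the natural reading
of "within", and the choice is centralized in a single internal constant so a
different convention would be a one-line change.

## Quality control

Participants reporting a BMI below 15 or above 50 kg/m², or no gender, are
removed; estimates outside the 50–800 kcal answer range are removed. All
rules are strict inequalities (BMI exactly 15 or 50 and estimates of exactly
50 or 800 are retained), matching the "less than / more than" phrasing of the
original exclusion rules. A participant who loses some responses to the range
filter keeps the rest: responses were excluded, not their owners.
Participants with *missing* BMI are also removed (counted with the invalid
BMI removals): the original study removed participants with "missing or
invalid demographic data", and there is no imputation in this package.

## The synthetic cohort

The original survey's raw responses were never deposited, so the package
ships a generator with the statistical structure the analyses assume. For
participant $i$ and food $j$:

$$\log \hat c_{ij} = \log c_j + \beta_d z_j + \beta_m \mathbf 1[\text{male}_i]
  + \beta_a a_i + \beta_{bd} (\text{bmi}_i - 25) z_j + u_i + v_j +
  \varepsilon_{ij}$$

with $z_j$ the centered log energy density, $a_i$ the 0-based age-bin index,
$u_i \sim N(0, \sigma_u^2)$ and $v_j \sim N(0, \sigma_v^2)$ random intercepts,
and $\varepsilon_{ij} \sim N(0, \sigma^2)$ multiplicative noise. Noise is
multiplicative (log scale) because estimates are positive and percent error
is the study's preferred scale for response bias. Estimates outside the
answer range are redrawn (noise only) up to `max_resample` times and then
clipped, mirroring a quiz interface that forces answers into bounds without
distorting the bulk of the distribution; estimates are rounded to whole kcal
because participants typed integers.

Defaults and why:

* `sigma_noise = 0.45`, `sd_participant = 0.25`, `sd_food = 0.15`: chosen
  once so that a default cohort's error magnitude is in the ballpark of the
  reported crowd (mean absolute percent error around 50–60%). They are not
  fitted values — the raw data needed to fit them do not exist publicly.
* all `beta_*` default to 0: the study reports the *signs* and p-values of
  its bias effects but no log-scale effect sizes, so the default world is
  bias-free and effects are injected explicitly where needed.
* `p_female = 0.62`, `bmi_mean = 27.5`: echo the reported cohort skew
  (62% women, mean BMI 27.5 kg/m²).
* `p_invalid_bmi = 0.025`, `p_missing_gender = 0.02`: deliberate QC bait at
  roughly the rate at which the original study discarded participants
  (97 of 2125, about 4.6% in total).
* age bins 13–17 … 65+ with numeric midpoints: the original survey collected
  an age *group* but never printed its bins; these are a package convention,
  skewed young by default as in the social-media cohort.
* experts are drawn from the same distribution as nonexperts (the study
  found no expert advantage) and merely flagged.

A single master seed drives demographics, random intercepts, and noise
through deterministic substreams, so regenerating one stage does not shuffle
the others and a fixed seed reproduces the cohort byte for byte.

What the generator does *not* emulate: heaping on round numbers (people
guess "300", not "287"), participant drop-out mid-quiz, anchoring from the
reddit comment thread, and any real covariance between demographics and
noise level beyond the injected effects. A green test on synthetic data
therefore establishes that the estimators recover the stated generative
structure — not that the original study's specific coefficient values are
reproduced. The study's cohort-level numbers (mean D = 5.15, crowd D = 7,
best-expert |e| = 130.2 kcal, the 4.6 kcal reference-object coefficient)
appear in documentation as context only.

`simulate_block_errors()` is a separate, deliberately minimal generator for
the network module: foods in a block share a unit-variance per-participant
factor plus independent noise, giving a known within-block error correlation
of $1/(1+\sigma_w^2)$ and zero between blocks — a planted partition with an
exact target for cluster recovery.

## Crowd aggregation and the bootstrap test

A crowd of size $k$ is a *set* of participants drawn without replacement,
shared across foods; its consensus per food is the mean (default; the median
is available because the study separately notes the median error). Crowd
discrete accuracy is computed by exactly the same metric rules as individual
accuracy, applied to the consensus estimates — one code path.

`bootstrap_crowd_test()` asks whether a crowd of $k_1$ is any more or less
accurate than a crowd of $k_2$. Each of $B$ iterations draws independent
crowds of both sizes and records the difference of their mean $|e|$ across
foods. The p-value is an exact two-sided sign test on those $B$ differences:
does the difference cross zero more or less often than chance? Two other
constructions were considered and rejected:

* *proportion form* ($2\min(\text{prop} \le 0, \text{prop} \ge 0)$ with a
  continuity correction): structurally conservative. With $k_1 = k_2$ the
  difference distribution is centred at zero, the proportion concentrates at
  ½, and the p-value is always near 1 — its null rejection rate is ~0, not
  $\alpha$, so it fails a type-I calibration study by construction.
* *studentized mean of the differences*: calibrated under the null, but its
  power grows with $B$, a Monte-Carlo parameter rather than a property of
  the data.

The sign test keeps the "crosses zero" reading, is exactly calibrated when
$k_1 = k_2$ (the difference is symmetric by exchangeability), and its power
for $k_1 \ne k_2$ reflects how consistently one crowd size beats the other.
Ties at exactly zero are dropped; a fully degenerate cohort (all responses
identical) yields p = 1.

## Bias regressions

All four registered models are linear mixed models with random intercepts
for participants and foods, estimated by REML via lme4 — the same model
family the original analysis used:

| name | outcome | fixed effects |
|---|---|---|
| `reference_object` | \|e\| | has_reference_object |
| `density_bias` | e | centered log energy density |
| `bmi_density_interaction` | η | (BMI − 25) × centered log density |
| `demographics` | \|e\| | gender + age midpoint |

Numerical choices:

* Energy density enters as centered log(kcal/g). The original analysis does
  not state a transform; the log respects the multiplicative error model and
  centering keeps the intercept interpretable. `density_transform = "raw"`
  switches to centered raw density.
* Fixed-effect p-values use the large-sample normal approximation on the t
  statistic. The original p-value method is unstated; at the study's scale
  (~2000 × 20 observations) the approximation is standard. For food-level
  covariates there are only 20 clusters, so these p-values are mildly
  anticonservative — the calibration tests budget for that explicitly.
* $R^2$ is the squared correlation between the outcome and the model's
  conditional predictions ("proportion of the variance described by the
  models' predicted values", the only definition the original text gives).
  It is invariant to affine rescaling of the outcome and equals 1 when the
  outcome is replaced by the predictions.
* A model whose outcome has exactly zero residual variance is ill-posed for
  lme4; the fit is reported with `converged = FALSE` and the optimizer's
  diagnostics, never silently replaced. Singular (boundary) variance
  estimates, by contrast, are legitimate — e.g. when a random-intercept
  variance is truly zero — and do not clear the `converged` flag.
* No multiple-testing correction across the four models, matching the
  original per-model α = .05.

One confound worth knowing: in the real food layout the six reference-object
foods average 472 kcal versus 230 kcal for the others, so on the kcal scale
their absolute errors are mechanically larger even when the generative
reference-object effect is exactly zero. The `reference_object` model
measures the association, confound included — as the original post hoc
analysis did. Calibration studies for this model therefore randomize the
flag assignment across foods; with the real layout a "null" rejection rate
near 1 is the expected behaviour of the world, not an estimator defect.

`density_mass_correlation()` reports the Pearson correlation between energy
density and portion mass across the quiz foods (−0.70 for the packaged
table): the dense foods were photographed in small portions, which is part
of why density bias and portion-size assumptions are hard to disentangle.

## The error network

The food-by-food matrix holds Pearson correlations of per-participant
percent errors (η rather than raw e, so food scale is removed and
"underestimates broccoli ⇒ underestimates cauliflower" is about
proportional bias; `measure = "e"` switches). Pairs with fewer than 3 common
respondents are missing and never become edges. The graph connects pairs
with $r \ge 0.3$ by default (the original figure states no threshold) and
attaches the correlation distance $1 - r$; negative correlations never
produce edges but remain in the exported matrix. Clustering is average-
linkage agglomerative on $1 - r$ with the tree cut at 0.7; missing
correlations are treated as 0 (distance 1), so unobserved pairs cannot
merge, and an all-missing matrix yields all singletons. The adjusted Rand
index used to score cluster recovery is implemented from the pair-counting
formula because no installed package provides it.

## Pipeline and reproducibility

`run_pipeline()` executes load → (simulate) → QC → metrics → crowd → bias →
network, writing one text artifact per stage plus a manifest with MD5
checksums and a `report.json` of headline numbers. The manifest deliberately
contains no timestamps: identical config and seed produce a byte-identical
bundle, which is tested. In analyze mode the input is a response CSV (long
single-file or two-file dialect); in simulate mode the master seed overrides
the simulation config's seed so one integer reproduces everything.

## Known limitations

* Generator parameters are order-of-magnitude conventions, not fits; only
  qualitative claims about the original cohort transfer.
* The default synthetic crowd is less biased than the real one (per-food
  biases that do not average out are opt-in via `beta_density` and
  `sd_food`), so its consensus accuracy is optimistic relative to the
  reported crowd.
* Discrete accuracy for participants answering fewer than 20 items is a
  count over answered items with `n_answered` reported alongside; the
  original quiz forced 20 answers.
* The network stage outputs the graph and clusters; the map-style drawing of
  the original figure used an external layout system and is out of scope.
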