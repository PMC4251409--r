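---
title: "Methods: Bayesian heart-age estimation from ECG outputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian heart-age estimation from ECG outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartage)
```

## The estimand and the model

Heart age is a latent quantity: we never observe it, only chronological
(body) age $x$ and a vector of $k$ ECG-derived outputs $\mathbf{y}$. The
package treats heart age $a$ as a parameter with prior

$$a \mid x \sim N(x,\ \sigma_a^2), \qquad \sigma_a = 7.5 \text{ years},$$

i.e. absent ECG information a healthy adult's heart age is expected to lie
within about 15 years of body age. The default scale is supported by an
external calculation the package reproduces: coronary-artery-calcium-based
adjustments to Framingham risk scoring amount to about 4.5 risk points at
the CAC extremes, at roughly 2 years of age per point, hence a $\pm 9$ year
adjustment; equating the "above the 75th percentile" group with the 87.5th
percentile of a Normal distribution gives an implied standard deviation of
$9 / \Phi^{-1}(0.875) \approx 7.8$ years (`grundy_prior_sd()`), close to
the 7.5 default. `sigma_a` is configurable everywhere it appears.

Each output is modelled, conditional on $x$ and $a$, as a quadratic in
body age plus a *drift* in the heart-age offset:

$$y_j \mid x, a = \beta_{0j} + \beta_{1j}x + \beta_{2j}x^2
  + \theta_j (a - x) + \epsilon_j, \qquad
  \boldsymbol{\epsilon} \sim N(\mathbf{0}, \Lambda).$$

The quadratic mean reflects mild non-linear age trends seen in ECG
outputs; $\theta_j$ (output units per year) measures how strongly output
$j$ responds to a heart older or younger than the body; $\Lambda$ is pure
within-subject measurement noise.

Because prior and likelihood are both Normal and the likelihood is linear
in $a$, the posterior is Normal with closed-form moments

$$\hat a = x + \frac{\boldsymbol\theta^{\mathsf T}\Lambda^{-1}
  (\mathbf{y} - \boldsymbol\beta \underline{x})}
  {1/\sigma_a^2 + \boldsymbol\theta^{\mathsf T}\Lambda^{-1}\boldsymbol\theta},
  \qquad
  \mathrm{sd}(a \mid x, \mathbf{y}) =
  \left(1/\sigma_a^2 +
  \boldsymbol\theta^{\mathsf T}\Lambda^{-1}\boldsymbol\theta\right)^{-1/2},$$

with $\underline{x} = (1, x, x^2)^{\mathsf T}$. The package exposes the
posterior standard deviation even though only the mean is usually
reported: the posterior is exactly Normal, so the two moments are a
complete summary. The posterior sd never exceeds $\sigma_a$ — data cannot
inflate prior uncertainty — and it does not depend on $\mathbf{y}$.

A useful derived quantity is the shrinkage weight

$$w = \frac{\boldsymbol\theta^{\mathsf T}\Lambda^{-1}\boldsymbol\theta}
  {1/\sigma_a^2 + \boldsymbol\theta^{\mathsf T}\Lambda^{-1}\boldsymbol\theta}
  \in [0, 1),$$

the fraction of a subject's true heart-age offset recovered by the
posterior mean on average (`shrinkage_weight()`; about 0.90 for the
published male model). Regressing predicted offsets on true offsets in a
simulated cohort recovers $w$ as the slope (`shrinkage_slope()`), which is
the package's main end-to-end diagnostic.

## Estimating the parameters

Nothing in the fit requires observing heart age:

* **$\boldsymbol\beta$, $\sigma_\nu^2$** — per output, OLS of $y_j$ on
  $(1, x, x^2)$ over a *healthy* cohort (`fit_age_regression()`). The
  residual variance uses the quadratic model's residual degrees of
  freedom, $\hat\sigma_\nu^2 = \mathrm{SSE}/(n-3)$, hence the requirement
  of $n \ge 4$ subjects and $\ge 3$ distinct ages per stratum.
* **$\Lambda$** — from $m$ subjects with two ECGs taken a month apart
  (`estimate_lambda()`). Heart age cannot change materially in a month, so
  session differences $d_i$ are pure noise with
  $E(d_i d_i^{\mathsf T}) = 2\Lambda$, giving the unbiased estimator
  $\hat\Lambda = \sum_i d_i d_i^{\mathsf T} / (2m)$.
* **$\boldsymbol\theta$** — comparing the marginal and conditional models
  shows $\nu_j = \theta_j (a - x) + \epsilon_j$, so
  $\sigma_{\nu j}^2 = \theta_j^2 \sigma_a^2 + \lambda_{jj}$ and
  $\hat\theta_j = \mathrm{sgn}(\hat\beta_{1j})
  \sqrt{(\hat\sigma_{\nu j}^2 - \hat\lambda_{jj})}/\sigma_a$
  (`estimate_theta()`). The sign comes from the linear age trend: an
  output that rises with body age should rise with heart age.

`fit_heart_age_model()` chains the three steps, stratified by gender
(male and female hearts age differently; the published constants differ
materially by gender). $\Lambda$ is shared across genders by default
because repeatability samples are small ($m = 15$ in the source data);
`share_lambda = FALSE` stratifies it when enough pairs exist per gender.

### Edge cases and numerical choices

* $\hat\sigma_\nu^2 \le \hat\lambda_{jj}$: the square root is undefined
  (no age-drift variance remains). The package sets $\hat\theta_j = 0$
  with a warning; the output then contributes nothing and predictions for
  it fall back to the prior. This is the conservative resolution.
* $\mathrm{sgn}(0) = +1$: a deterministic tie-break; $\hat\theta$ is at or
  near 0 there anyway.
* Non-positive-definite $\hat\Lambda$ (possible for $m < k$ or unlucky
  small samples): `estimate_lambda()` errors by default, instructing the
  diagonal fallback; the fitting pipeline uses `nonpd = "diagonal"` (keep
  per-output variances, warn), consistent with estimating each $\theta_j$
  from $\hat\lambda_{jj}$ alone.
* All-zero difference matrices (identical sessions) are returned as-is;
  the positive-definiteness requirement is enforced where it matters, in
  the model constructor.
* Angles in the composite features are degrees, converted by $\pi/180$;
  logarithms are natural. Ages enter unscaled, in raw years.
* The posterior-density oracle (`posterior_density()`) evaluates prior
  $\times$ likelihood pointwise on a user grid and normalizes by the
  trapezoid rule, without using the completed-square closed form; it
  requires the grid to span $x \pm 5\sigma_a$ and errors if more than
  $10^{-6}$ of the posterior mass falls in the edge cells. It is the
  independent check on the closed-form mean (agreement to well below
  $10^{-6}$ years on randomized instances).

## Composite ECG outputs

The published model uses $k = 2$ composite outputs built from eleven raw
advanced-ECG variables. `transform_features()` assembles the two fixed
7-vectors (intercept; T-wave axis; P duration; $\sin$ of the
vectorcardiographic QRS axis; logs of high-frequency power, RMS voltage
sum and spatial JT interval — and correspondingly QT-variability indices,
QRS axis, P duration, spatial QRS-T angle and log intradipolar ratio), and
`composite_scores()` takes their dot products with the logistic-regression
coefficient vectors $\gamma_1, \gamma_2$ (healthy non-athletes coded 0,
disease coded 1 in the source fit). Both $\gamma$ vectors ship digit-for-
digit in a versioned JSON resource; `fit_composite_coefficients()` refits
the same kind of logistic regression on labeled data, with an explicit
complete-separation error. Raw-variable units are taken as provided and
must match those used when the coefficients were fitted; records with
missing raw fields are rejected rather than imputed, since the dot product
is undefined on partial vectors.

## The synthetic-cohort generator

No subject-level dataset accompanies the published constants, so the
package validates itself on synthetic cohorts drawn from exactly the
generative model above (`simulate_cohort()`): $x \sim$ Uniform(20, 80) (or
uniform within age bands), $\delta \sim N(\delta_0, \sigma_\delta^2)$ with
$a = x + \delta$, and $\mathbf{y} = \boldsymbol\beta\underline{x} +
\boldsymbol\theta\delta + \boldsymbol\epsilon$. Healthy cohorts use
$\delta_0 = 0$ and $\sigma_\delta = \sigma_a = 7.5$ — the prior is the
population distribution, so the model is correctly specified.
`simulate_repeats()` draws one latent subject and two independent noise
vectors per pair.

`make_group_scenarios()` mirrors the published evaluation groups in size,
female fraction and age-band mix (545/183 healthy non-athlete train/test,
48 athletes, 221 risk-factor, 441 disease subjects). The offset means for
the non-healthy groups (2, 8 and 18 years for athletes, risk-factor and
disease groups) are calibration defaults chosen so the simulated fractions
with $\hat a > x$ land near the qualitative findings for those groups
(slightly above half, about three quarters, nearly all); they are
configurable and are not estimates of any published quantity.

What the generator does *not* emulate: real raw-ECG variables (simulation
operates at the composite-output level the estimator consumes),
non-quadratic age trends, heteroscedastic or non-Normal noise,
gender-specific $\Lambda$, and any correlation between group membership
and measurement quality. Passing tests therefore demonstrate internal
consistency — correct formulas, unbiased estimators, calibrated
predictions *under the assumed model* — not clinical validity on real
ECGs.

## Problem sizes used in the checks

The package's own validation uses: 200 randomized closed-form-vs-grid
oracle instances ($k \in \{1,2,3\}$, grid step 0.02 years over $x \pm 60$);
2,000 replicates of $\hat\Lambda$ at $m = 15$; 100 simulation seeds of
545-per-gender cohorts for full-pipeline $\beta/\theta$ recovery; a
100,000-subject male cohort for the shrinkage slope; and 200 replicates of
545-subject healthy cohorts for calibration of the fraction above body
age. These sizes give Monte-Carlo error comfortably below the tolerances
they are checked against while keeping the whole suite fast.

## Known limitations

* The gender-specific vs pooled comparison (`compare_gs_ngs()`) reports a
  paired $t$ interval conditioned on one cohort. That interval quantifies
  subject-level spread of the difference between two *fixed* fitted rules;
  it is not a valid confidence interval for the zero difference under
  identical gender parameters, where fit-estimation noise dominates. Use
  it as the descriptive contrast it is (its sign behaviour under genuinely
  distinct gender models is reliable), not as a calibrated test of "no
  gender effect".
* $\hat\theta_j$ is slightly biased near $\sigma_\nu^2 \approx \lambda^2$
  (the square root is concave and the clamp at 0 is one-sided); with
  outputs as informative as the published ones the bias is negligible at
  cohort sizes of a few hundred.
* The model is built for healthy adults (ages $\ge 20$): $\beta$ must be
  fit on healthy subjects, and predictions for diseased groups are
  exploratory extrapolation.
* No Bayes-factor model comparison and no MCMC are provided; the posterior
  is exact and closed-form under the stated assumptions.
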