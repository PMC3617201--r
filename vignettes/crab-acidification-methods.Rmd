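---
title: "Models and methods for long-term crab acidification cohorts"
author: "crabacid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for long-term crab acidification cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crabacid)
```

crabacid packages the statistical machinery needed to analyse a long-term
(roughly 200-day) rearing experiment in which juvenile crabs are held
individually in flow-through seawater at three pH treatments (ambient
control near 8.0, and CO2-acidified 7.8 and 7.5), censused daily for death
and molting, measured at each molt, and assayed terminally for dry mass and
mineral content. This vignette is the package's own account of each model,
its assumptions, the tunable parameters, and the numerical and design
choices made where the design was genuinely open.

## Mortality: censored exponential hazards and a three-model ladder

Each crab contributes one record: its treatment, entry day, last check day,
and whether it died or was right-censored (alive at the end; terminal
sacrifice is censoring, not an event). Survival to day $t$ under a constant
daily hazard $r$ is $S(t) = e^{-rt}$. Because deaths are only detected at
the daily check, a crab found dead on day $t$ contributes the interval
probability

$$S(t-1) - S(t) = e^{-r(t-1)}\left(1 - e^{-r}\right),$$

and a censored crab contributes $S(t)$. An algebraically identical per-day
Bernoulli reading (survive each day with probability $e^{-r}$) is exposed
as `mode = "bernoulli"` and asserted equal in the tests; `mode = "exact"`
treats event times as exact and is used as a closed-form cross-check
(`rate = deaths / crab-days` for complete data).

Treatment structure enters through three nested hazard maps — one shared
rate, control versus acidified, and one rate per treatment ($K = 1, 2, 3$)
— fitted by maximum likelihood and ranked by AICc. Hazards are estimated
on the log scale, which enforces positivity; the likelihood factorizes
over parameter groups, so each rate is a one-dimensional optimization
(golden-section search started at the closed-form `deaths/crab-days`
value, argument tolerance near machine precision, then a local polish).
Standard errors come from the numerically observed information (central
second differences on the log scale, step $10^{-4}$, delta method back to
the rate scale). A parameter group with zero deaths is reported as rate 0
with an undefined SE and an explanatory flag rather than an error.

Two conventions deserve note:

* **Effective sample size for AICc.** The experiment does not dictate
  whether $n$ is crabs or crab-days. The package defaults to the number of
  crabs — the independent units — and exposes `n_aicc` for the other
  conventions. Model *ranking* is insensitive to this choice whenever all
  models are fit to the same records, because the correction term is close
  to common across $K = 1\ldots3$ at either $n$.
* **Small-sample bias.** The ML hazard estimator with $D$ events carries
  the classic $\approx 1/(D-1)$ upward relative bias (about 3% at 30
  events). The recovery suite verifies bias stays below 5% of truth at the
  study's sample sizes; no bias correction is applied, matching standard
  practice.

## Growth: a degree-day clock, linear carapace length, exponential wet mass

Molting and growth in ectotherms track accumulated temperature, so time is
measured in degree-days: the sum of daily mean temperatures above a base
(default 0 °C, configurable) over the interval — at the experiment's mean
of 9.1 °C, 192 days is 1747.2 °C·day.

**Carapace length** is modelled linearly in degree-days with Treatment
fully crossed with Time and Crab nested within Treatment (fixed effects).
A significant Treatment × Time interaction (sequential F test, $\alpha =
0.05$) is read as a difference in growth rates, after which each treatment
is regressed separately with crab intercepts and the per-treatment slope
and mean intercept are reported. Crabs with fewer than three measurements
are excluded, and initial (molt-0) sizes are dropped because the molt
stage at entry is unknown.

**Wet mass** follows $WM = a\,e^{bt}$ with additive Gaussian errors on the
mass scale and per-crab intercepts $a$ always free. Wet mass is measured 7
days after each molt, so wet-mass observations are timestamped at the
degree-days of molt + 7 days (the `t_wm` column), not at the molt itself.
Four variants form the ladder: shared $b$; treatment-structured
intercepts $a(T)$; treatment-specific $b(T)$; and both. Because per-crab
intercepts absorb any treatment-level mean, $a(T)$ is structurally
confounded with $a$: the $a(T)$ variants are treatment-mean
reparameterizations with identical likelihood and parameter count, and are
reported as such (ties in the ranking). For fixed $b$ the intercepts have
a closed-form profile (least squares of $WM$ on $e^{bt}$ per crab) and the
residual sd is profiled as $\sqrt{RSS/n}$, leaving a one-dimensional
search in each $b$ over $(-0.005, 0.005)$ per degree-day — an order of
magnitude wider than biologically plausible growth coefficients; optima
pinned to the boundary are flagged as non-converged. $K$ counts per-crab
intercepts, growth coefficients and the residual sd (36 crabs, shared $b$
→ $K = 38$). AICc for this ladder defaults to $n$ = observations, since
$K$ exceeds the number of crabs and a subject-based $n$ would make the
small-sample correction's denominator negative. A multiplicative
(log-scale) error mode exists for robustness comparisons but is not the
default.

Percent contrasts between treatments are evaluated from fitted curves at a
common horizon; with a shared intercept the exponential contrast reduces
to $e^{(b_A - b_B)t} - 1$, independent of $a$ (asserted in tests).

## Morphometrics: correlation-matrix PCA and a nested ANOVA on scores

Landmark measurements (5 for red king crab, 8 for Tanner) are standardized
to zero mean and unit sd (n−1 denominator) and decomposed by
eigendecomposition of the correlation matrix. Juvenile carapaces are
dominated by a single size axis, and the field convention is that size
loads negatively on PC1; each component's sign is therefore flipped so
the majority of its loadings are negative (ties broken by forcing the
first loading negative), making results bit-reproducible across runs and
linear-algebra backends. Scores are the projections of the standardized
rows; eigenvalues sum to the number of landmarks.

PC scores are then analysed with a fixed-effects model of Treatment
crossed with Molt number plus Crab within Treatment, with Fisher LSD
contrasts of treatments within each molt. Molt stages reached by fewer
than 20% (configurable) of any treatment's crabs are excluded before
fitting — sparse final molts carry little information and unbalance the
design; an empty treatment × molt cell after filtering drops the
interaction term with a warning.

## Terminal endpoints

The condition index is dry mass (g) divided by the cube of the reference
carapace dimension (mm): carapace length for red king crab, width for
Tanner. Every endpoint — condition index, percent calcium and magnesium,
per-molt size and mass, intermolt duration — runs through one gated test:
Levene's test (classical mean-centered form, $\alpha = 0.05$) decides
between a one-way ANOVA with LSD contrasts and a Kruskal–Wallis test with
unadjusted pairwise rank-sum contrasts (the analysis that motivated the
gate is silent on a post hoc under KW; rank-sum pairs are the natural
analogue). Percent differences are ratios of arithmetic group means,
$100\,(\bar{x}_A/\bar{x}_B - 1)$; whether reported contrasts of this kind
use means or model predictions is not stated in the source analyses, and
arithmetic means are the assumption here. Species whose molt counts are
too low for a trajectory fit (the Tanner case) are handled purely
cross-sectionally: sizes compared per molt and intermolt degree-day
durations compared between consecutive molt pairs.

## Carbonate chemistry

With pH (free scale) and DIC both measured, the CO2 system is closed-form:
no iteration is needed. Constants follow the standard surface-pressure
formulations — Lueker et al. (2000) $K_1/K_2$ (total scale), Dickson
(1990) $K_B$ and $K_S$, Millero (1995) $K_W$, Weiss (1974) $K_0$, Mucci
(1983) solubility products — with explicit free↔total scale bookkeeping
via $1 + S_T/K_S$. The tests freeze the published check values at 25 °C,
S = 35 (pK1 5.8472, pK2 8.9660, pKB 8.5975, KS 0.1003, K0 0.02839, and
the two solubility products) to four significant digits. Alkalinity is
assembled as $[\mathrm{HCO_3^-}] + 2[\mathrm{CO_3^{2-}}]$ + borate +
$[\mathrm{OH^-}] - [\mathrm{H^+}]_F$; nutrient terms are omitted because
phosphate and silicate were not measured. Saturation states use
$[\mathrm{Ca^{2+}}] = 0.010285\,S/35$ mol/kg. Salinity was not reported
with the carbonate measurements; the default of 32, typical of coastal
Gulf of Alaska surface water, is exposed as an explicit argument, and the
qualitative structure (pCO2 ordering, saturation classifications with a
±0.15 band around Ω = 1) is verified across salinities 30–33. A
round-trip test feeds the computed TA and DIC to an independent
root-finding inversion and recovers the input pH to ±0.001.

## The synthetic cohort generator

`simulate_cohort()` emulates the full experimental design under one seed:
three treatments × 30 crabs (red king crab preset: 192 days, hazards
0.0023/0.0047/0.025 day⁻¹, intermolt 450 ± 119 °C·day, 5 landmarks;
Tanner preset: 199 days, 0.0010/0.0023/0.0050 day⁻¹, 873 ± 198 °C·day, 8
landmarks, at most 3 molts). Daily temperature is a piecewise-cosine
through 9.3 °C at the start, 11.9 °C at the day-100 peak and 4.4 °C at
the end (192-day mean ≈ 9.4 °C), with optional seeded jitter. Death days
are exponential draws discretized to the daily census; molts fall where
cumulative degree-days cross successive truncated-normal intermolt draws
(floor 150 °C·day, below the smallest plausible intermolt); carapace
length is linear in degree-days with 0.1 mm Gaussian noise; wet mass is
$a_{crab} e^{bt}$ at molt + 7 days with 5% proportional noise and
lognormal per-crab intercepts (10% cv); landmark vectors are a size
scalar times a fixed loading vector plus isotropic noise (5% noise
share); terminal condition index and percent calcium come from
treatment-multiplied baselines (control +25% CI, +10% Ca — the magnitude
of reported treatment contrasts) for crabs alive at the end. Where the
study conditions left a value unstated (CL/WM parameters for pH 7.5,
where no fit was possible; baseline CI and %Ca levels; noise scales) the
defaults are fixed once at values a crustacean biologist would call
realistic for ~2–5 mm juveniles and are not tuned.

Deliberate simplifications, hence what passing recovery tests do *not*
show about real data: death and molting are independent (no
condition-dependent mortality); hazards are time-constant although the
real mortality divergence emerged after 50–70 days; morphometric noise is
isotropic (no shape axes beyond size); temperature is shared across
treatments and cells; and no tank or cell spatial structure exists.

## Problem sizes and calibration checks

The regression suite runs each fitter against the generator at the study's
own scale: 500 cohorts of 30 crabs per hazard for recovery (bias < 5%,
and the mean-versus-truth check at 2 Monte-Carlo SEs where the
estimator's small-sample bias permits it), 200 replicates for structure
selection (3-rate design selects all-different; equal rates select
all-same) and for the wet-mass ladder (b(T) selected, coefficients within
10%), 10,000-shuffle permutation and 1,680-assignment exhaustive oracles
for the ANOVA and KW p-values, and 1,000–2,000-replicate null simulations
holding type-I error at 0.05 ± 0.015 for ANOVA, KW and the growth
interaction F. Exhaustive grid search (step $10^{-5}$ over
$10^{-5}$–0.2 day⁻¹) pins the survival ML to one grid step. At three
observations per group the Kruskal–Wallis chi-square reference is only
accurate to a few percent against the exact permutation distribution —
an inherent property of the approximation, checked at its actual
accuracy.

## Known limitations

* The fixed-effects crab terms treat per-crab intercepts as nuisance
  parameters; a mixed-model treatment would shrink them but is out of
  scope.
* The hazard model excludes time-varying and covariate-dependent rates,
  and no Kaplan–Meier estimator is provided.
* The carbonate module fixes one constant family; user-selectable
  formulations and pressure corrections are not implemented.
* Percent contrasts of endpoint means are descriptive; no uncertainty is
  propagated onto them.
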