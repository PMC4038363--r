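---
title: "Projecting individual 5-year melanoma risk: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting individual 5-year melanoma risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melrisk)
```

## The problem

Melanoma control in New Zealand leans on early diagnosis, and early
diagnosis is most efficient when surveillance is concentrated on people at
genuinely high risk. A list of risk factors does not do that job: risk
factors combine multiplicatively and what a clinical decision needs is an
*absolute* probability over a planning horizon, not a relative one.
`melrisk` implements a sex-specific pipeline that turns a short risk-factor
profile into the probability of a first cutaneous melanoma within five
years, for fair-skinned New Zealand adults aged 20 and over.

## The model in three stages

### 1. Relative risk from case–control odds ratios

Sex-specific logistic models estimated from a population-based case–control
study supply adjusted odds ratios per factor level. Melanoma is rare on a
5-year horizon (annual incidence is of order 10–300 per 100,000), so odds
ratios are treated as relative risks. An individual's combined relative
risk is the product of their levels' odds ratios,

$$ r = \prod_v OR_v(x_v), $$

with the men's large-mole count entering as $OR^{\text{count}}$
(1.15 per mole). The women's model uses skin colour, a categorical
right-arm large-mole count (0/1/2/3+), first-degree family history of
large moles, and personal NMSC history; the men's uses the age group
(≤50/>50), occupation location up to age 18, the mole count, birthplace,
and NMSC history. The packaged parameter files transcribe the published
estimates, including the women's family-history reference level
"don't know".

Multiplying ORs *printed to 2 decimals* does not exactly reproduce the
published combined RRs, which were formed from unrounded coefficients; the
products agree within about 0.5% for the female and male medium profiles
and the female high profile, and within about 1.6% for the male high
profiles. Functions therefore accept either a covariate profile (the RR is
recomputed as a product) or a directly supplied `rr`, which is how the
published example RRs (e.g. 189.38, 70.31) are consumed.

### 2. Attributable risk and the baseline hazard

The rate table packaged with `melrisk` is *population* incidence. A
profile's relative risk multiplies the hazard of a person with *no*
modelled risk factors, so the population incidence must be discounted by
the attributable risk of the modelled factors:

$$ h_1(t) = I(t)\,(1 - AR), \qquad
   AR = 1 - \sum_j \frac{\rho_j}{RR_j} = 1 - \mathrm{mean}_{\text{cases}}\left(\frac{1}{r_i}\right), $$

the Bruzzi case-based estimator: $\rho_j$ is the proportion of *cases* in
joint exposure stratum $j$ and $RR_j$ its relative risk. It needs only the
cases' covariates plus the fitted ORs — no control exposure distribution —
which is exactly what a case–control study provides. The published values
(0.89 women, 0.85 men) are the prediction defaults; `bootstrap_ar()`
re-estimates the AR with either fixed parameters (cases resampled) or full
model refits (both arms resampled), returning percentile intervals.

An interpretation note: the alternative reading of the rate table as
*already AR-discounted baseline* incidence cannot reproduce the published
absolute-risk examples; only population incidence combined with
$h_1 = I(1-AR)$ does, which is why the discounting lives in the risk
engine rather than in the data.

### 3. Absolute risk under competing mortality

Between ages $a$ and $a+\tau$ a person can develop melanoma (cause-specific
hazard $r\,h_1(t)$) or die of something else (non-melanoma mortality
$h_2(t)$). With both hazards piecewise constant on the rate table's 5-year
age bands, partitioning $[a, a+\tau)$ at band edges into intervals $k$ of
width $\Delta_k$ gives the closed form

$$ \pi = \sum_k \frac{r h_{1k}}{r h_{1k} + h_{2k}}
   \exp\Big(-\sum_{j<k}\Delta_j (r h_{1j}+h_{2j})\Big)
   \Big(1 - e^{-\Delta_k (r h_{1k} + h_{2k})}\Big). $$

Each term is the probability of surviving both causes to the start of
interval $k$, times the probability some event occurs in $k$, times the
chance that event is melanoma. Zero-hazard intervals contribute zero (the
limit convention). Two limits anchor the implementation and its tests:
with $h_2 = 0$ and one band, $\pi = 1 - e^{-\tau r h_1}$ exactly; as all
hazards shrink, $\pi \to \tau\, r\, h_1$.

The projection anchor is the *exact* age: a 5-year horizon started at a
band-start age (20, 40, 60, 80 — the published example ages) uses a single
band, while other ages split across two. Projections that run past the
last closed band (80–84) fall back to the open 85+ band and say so.
Ages below 20 are refused — outside both the rate table and the study's
recruitment range — while the 20–79 recruitment range itself is not
enforced for prediction.

## The synthetic cohort: what it emulates, what it does not

The original individual-level study data were never deposited, so the
package carries a generator whose defaults encode the study conditions:
arm sizes 182/139 (women) and 186/131 (men); control-arm level prevalences
for each covariate taken from the published control margins; generating
odds ratios equal to the published model estimates; controls
frequency-matched to cases on 5-year age band and region by stratified
sampling with largest-remainder rounding.

Choices the published margins do not pin down, fixed once here:

* **Independence across covariates.** Only marginal prevalences are
  published, so covariates are drawn independently. Real phenotype
  variables (skin colour, freckling, moles) are correlated; parameter
  recovery on these synthetic data is therefore an easier problem than on
  real data, and passing it shows correctness of the estimator, not
  real-world robustness.
* **Men's mole count**: Poisson with mean 0.6, truncated at 20. Only a
  per-mole OR is published; the mean was chosen so roughly half of men
  report at least one large mole, in line with the women's categorical
  margin, and it is config-overridable.
* **Women's family-history split.** Only the "yes" margin (40%) is
  published for the three-level variable; the remainder is split 55% "no",
  5% "don't know".
* **Disease intercept** $-6.2$, putting marginal prevalence near 1–2% —
  the rare-disease regime in which the OR-as-RR reading the risk engine
  relies on is accurate. Simulation-heavy tests that need many cases per
  dataset raise the intercept (to $-4$) rather than inflating $n$.
* Exact ages are uniform within their 5-year band; the dichotomous age
  group is derived at 50, so age effects and age-based matching stay
  mutually consistent.

## Model building and validation choices

* Univariate screening keeps candidates with $p < 0.25$ (chi-square for
  categorical variables without continuity correction — required to
  reproduce the published candidate-table statistics — and a Wald test on
  the per-unit logistic coefficient for counts).
* Backward elimination drops the largest likelihood-ratio $p$ until all
  remaining variables have $p \le 0.05$; the stay threshold is an argument
  because only the criterion, not the threshold, is fixed by the source
  analysis. Candidate removals carry their AIC in the trace so non-nested
  recodings can be compared; plain AIC is used (no small-sample
  correction). Forward selection and within-arm bootstrap refitting
  (default $B = 1000$, seeded) serve as internal-validation
  cross-checks. Complete cases only; nothing is imputed.
* The C-statistic uses the tie-corrected rank-sum identity at every $n$
  rather than switching to exhaustive $O(n^2)$ pair counting below a size
  cutoff: the two are algebraically identical, and the exhaustive count is
  kept as the independent oracle in the test suite.
* Hosmer–Lemeshow groups are deciles of predicted risk with tied
  predictions never split across groups (categorical covariates tie
  heavily), $g-2$ degrees of freedom, and automatic merging of groups with
  zero expected events or non-events.
* The classification cutoff defaults to 0.5. The published classification
  percentages and C-statistics are properties of the original dataset and
  are not reproduction targets on synthetic data.

## Numerical notes

* Rates are stored exactly as printed (per 100,000 person-years) and
  divided by $10^5$ only at lookup, keeping the packaged CSV diffable
  against the source table.
* Band-splitting is exact: subdividing any band into sub-intervals with
  identical rates leaves $\pi$ unchanged to $10^{-12}$, and the piecewise
  closed form agrees with a fine-grid Runge–Kutta integration of the
  two-cause system to $10^{-6}$ across randomised sweeps.
* Separation or non-convergence in a logistic fit is flagged on the fit
  object rather than raised, because bootstrap resamples routinely produce
  sparse cells; degenerate resamples are redrawn and counted.
* Seeds parameterise every stochastic routine; identical config and seed
  give byte-identical datasets and reports.

## Problem sizes used by the test suite

Stochastic properties are checked at sizes chosen to make Monte-Carlo
bands tight while keeping the default suite quick: parameter recovery on a
50,000-person synthetic population (3-SE criterion per coefficient); the
AR estimator against an exact enumeration oracle on a 200,000-person
population; refit-mode bootstrap CI coverage over 150 outer replicates of
a study-sized (368/270) sample with $B = 199$, accepted within 3 binomial
SEs of 95%; Hosmer–Lemeshow null uniformity over 120 seeds at $n = 4000$
(Kolmogorov–Smirnov at 0.01).

## Known limitations

* The published odds ratios come from a 1992–94 study and 1996–2006 rates;
  behaviour-linked exposures (e.g. sun-bed use) have shifted since, so
  absolute risks are historical unless recalibrated to current incidence.
* The model applies to fair-skinned New Zealand adults only; dark-skinned
  phenotypes were excluded at the design stage.
* Internal validation (bootstrap stability, calibration on the fitting
  data) cannot substitute for external validation on an independent
  cohort, which the package does not attempt.
* Rates are banded; no smoothing or interpolation within bands is offered,
  so $\pi$ has small jump discontinuities as a function of starting age at
  band edges.
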