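---
title: "Methods: multistate life tables for compression of disability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multistate life tables for compression of disability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(disablife)
```

This vignette is the package's account of its statistical machinery: the
five-state model, what the synthetic-panel generator does and does not
emulate, how annual probabilities are estimated from biennial observation,
the weighting scheme for nonresponse, the life-table accounting identities,
and the numerical choices behind each. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The five-state annual model

Disability in a domain (mobility loss, IADL, ADL) is modelled as a
discrete-time Markov chain on an annual clock with states `ND` (never
disabled), `STD` (short-term disabled, onset within the last year), `NDH`
(not disabled with history), `LTD` (long-term disabled), and absorbing
`DEAD`. The two bridge states `STD` and `NDH` exist because remission after
recent onset is common in panels of adults in their 50s and 60s; `STD`
lasts exactly one cycle by construction.

Four annual probabilities drive the chain, each logistic in age with a sex
main effect: onset and death-if-non-disabled (shared by `ND` and `NDH`),
remission and death-if-disabled (shared by `STD` and `LTD`). Two modelling
decisions deserve emphasis:

* **Mortality depends on current disabled status only**, not on disability
  history. This matches how the input rates are stratified ("mortality by
  incident disability") and keeps the parameter count identifiable from
  status-by-wave data.
* **Long-term disabled persons can recover**, at the same annual remission
  probability as the short-term disabled. The alternative (absorbing
  `LTD`) is not identifiable from biennial status observations either, and
  the estimated remission probabilities pool both durations; using one
  probability for both is the consistent choice.

A consequence used throughout the package: because `ND`/`NDH` and
`STD`/`LTD` share parameters, the chain's *observable* disabled /
non-disabled / dead status is itself Markov on the annual clock. The bridge
states matter for the life-table bookkeeping, not for the dynamics.

## 2. The synthetic-panel generator

The generator emulates the structure of a biennial U.S. aging panel: two
birth cohorts (1931–41 interviewed from 1992, 1942–47 from 2002; baseline
ages 51–61 and 55–60), six biennial waves, item-level disability reporting
(5 mobility, 5 IADL, 5 ADL difficulty flags), self-reported diabetes
diagnosis (prevalent at baseline plus incident diagnoses), death years
observed exactly for everyone (emulating death-index linkage), lognormal
sampling weights normalized to mean one, and wave-level nonresponse.

Default transition curves are anchored at published annual rates for these
cohorts: with diabetes, onset near 6 per 100 person-years at age 50 rising
slowly, remission near 18 falling with age, mortality near 1.2 (non-
disabled) and 2.8 (disabled) per 100 rising steeply (logit slopes 0.05–0.07
per year); without diabetes roughly a third the onset and half the
mortality. Cohort 2 applies logit shifts (−0.55 onset, +0.45 remission,
−0.15/−0.10 mortality) reproducing the direction and rough magnitude of the
published cohort-2 improvements. Women have higher onset and lower
mortality than men (±0.25–0.35 on the logit scale).

**One latent process, three item views.** The generator simulates a single
latent disability process per person and draws the three domains' items
conditionally on it: given "disabled", mobility items are drawn uniformly
over the patterns with ≥ 4 difficulties and IADL/ADL over patterns with
≥ 1; given "not disabled", over the complementary patterns. The threshold
classifier therefore reproduces the latent state exactly, which makes
classify-then-estimate an identity in expectation while still exercising
item-level coding. Independent per-domain disability processes were
rejected: with state-dependent mortality they imply three inconsistent
death processes for one person. The cost is that the three domains are
perfectly concordant in the generator — cross-domain heterogeneity (e.g.
different onset slopes per domain) is *not* emulated, and per-domain
estimates from one synthetic panel are three correlated views of the same
truth, not replicates.

**Missingness.** Baseline always responds; deaths are always recorded. At
follow-up waves the response log-odds are linear in age (−0.15 per year),
sex (−0.20 men), disability at the previous wave (−0.80), and previous-wave
response (+1.00), intercept 2.12 — per-wave follow-up response ≈ 83–85%,
at the low end of the response rates reported for the survey being
emulated. The steep age gradient is deliberate: it is the design
requirement that makes inverse-probability weighting *necessary* (see §4).
Nonresponse masks the item fields only; the record's vital status remains
known.

**Diabetes grouping.** Analysis assigns the diabetes group as
ever-diagnosed during the study period, fixed for the person's whole
record. The generator runs each person's dynamics under their eventual
group's curves from baseline; a person diagnosed late who dies before
reporting it is analyzed as non-diabetic — the same contamination the
fixed-two-populations design accepts with real data.

## 3. Estimating annual probabilities from biennial waves

Person-periods are consecutive-wave intervals with an observed start state;
death intervals need no end-wave response. Intervals spanning a skipped
wave are excluded from fitting — their absence is exactly what the IPW
response model reweights for. Persons prevalent-disabled at baseline in a
domain are excluded from all four of that domain's fits, matching the
incident-disability framing of the input rates.

Each transition is fitted by maximum likelihood on the **annual** scale:
the k-year interval outcome has probability $1-(1-p_a)^k$ with
$\operatorname{logit} p_a = \beta_0 + \beta_1(\text{age}-50) +
\beta_2\,\text{male}$ — the constant-hazard complement-root convention. At
k = 1 this is exactly pooled logistic regression. Variances are
cluster-robust by person (score sandwich), satisfying the GEE contract
(point estimates equal the pooled fit, standard errors account for repeated
measures); the working-correlation choice is immaterial for the point
estimates at this model size.

**Within-interval dynamics correction.** The complement-root convention
ignores that a person can onset *and* recover (or die) within one two-year
interval. With remission near 16–26% per year this biases the naive annual
onset and remission probabilities down by roughly 0.005–0.015 — enough to
distort disabled-years estimates. Because the observable status process is
Markov (§1), the naive estimand has a closed forward map: for example

$$P(\text{disabled at } t{+}2 \mid \text{non-disabled at } t,\ \text{alive})
= \frac{p_a(1-r_{a+1}-d^{dis}_{a+1}) + (1-p_a-d^{nd}_a)\,p_{a+1}}
       {1 - P(\text{dead by } t{+}2 \mid \cdot)}$$

and analogously for the other three transitions. `predict_probability_set()`
inverts this map. Numerically, the inversion is solved *parametrically*:
both the fitted naive curves and the annual curves they estimate are
logit-linear in age, so the solver finds the two anchor values (ages 50 and
70) of each transition's logit-linear annual curve whose forward-mapped
naive values reproduce the fitted ones, by a damped fixed point
(contraction ≈ 0.5, a few dozen iterations to 10⁻¹¹). An age-by-age
inversion was rejected: the age-coupled system is non-normal and a boundary
error at the oldest age amplifies ≈ 1.3× per year of backward recursion.
Monte Carlo draws pass through the same inversion, so intervals reflect it.

Predicted probabilities are clipped to the row-simplex constraint
($p_{onset}+p_{die} \le 1$, proportionally, with a warning) and zero-event
strata are reported as probability zero with infinite logit variance.

## 4. Nonresponse weighting

The response model is logistic in age, sex, disability at the previous
observed wave, and previous-wave response; weights are reciprocals of the
fitted probabilities (ridge-penalized refit on separation). Two weight
products are attached: mortality models get the start-wave factor only
(their outcome is observed for everyone), onset/remission models get start
× end factors. Applying an end-wave factor inside a mortality risk set
would up-weight survivors relative to deaths and bias mortality down.

Under the Markov dynamics of §1, this MAR mechanism is *ignorable* for any
estimand that conditions on start state, exact age, and sex — the
age-specific logit-linear fits are consistent with or without weights. The
bias that IPW exists to remove lives in the **age-marginalized** summaries:
the grouped annual rates for age bands (50–60, 61–70, 50–70) average over
an age distribution that complete-case analysis tilts young, biasing the
steeply age-dependent rates (mortality above all) low. The package's
weighting experiment (`ipw_bias_comparison()`) therefore compares weighted
and unweighted grouped rates against the same realization's full-response
estimate, as a *precision-standardized* total deviation — standardizing
each cell by its standard error stops the noisiest low-information cells
from drowning the signal. Weighted beat unweighted in 18 of 20 development
replicates at n = 20,000.

## 5. Life-table accounting

Person-years for each cycle are credited to the state occupied *entering*
it (cycle-start accounting, no half-cycle correction), so

$$\text{DFY} + \text{DY} + \text{LYL} = \text{horizon}$$

holds exactly — as it does, to rounding, in every row of the published
tables this design mirrors. Disability-free years include `NDH` (recovered)
occupancy, and the average onset age is *defined* as baseline age + DFY.
These two choices are forced jointly: the published rows satisfy
onset = baseline + DFY in every cell, which a first-passage-time definition
would violate whenever recovery is possible. Corner cases follow from the
accounting: with certain first-year death, DFY is 1 (the entry year is
lived in `ND`), not 0; a zero-hazard transition matrix is the identity
except that the one-cycle `STD` state empties into `LTD`.

## 6. Monte Carlo uncertainty

Coefficient vectors are drawn multivariate-normal from the cluster-robust
covariances (eigenvalue-floored when numerically indefinite), pushed
through prediction, correction, simplex projection, and the cohort model.
Intervals are empirical percentiles (the estimator is smooth and the
ensembles near-symmetric; percentile is the transparent choice given no
stated convention to match). Contrasts between cohorts or diabetes groups
use independent ensembles — the underlying samples are disjoint — with
two-sided p-values $2\min(\Pr(\Delta\ge 0), \Pr(\Delta\le 0))$ capped at 1
and floored at $2/n_{draws}$. The full reporting convention is 5,000 draws
per sex; tests and the coverage experiment run 500 per sex, flagged as the
scaled-down setting.

## 7. Validation experiments and problem sizes

The suite validates the pipeline at these sizes, chosen to make each check
informative at interactive runtimes:

* Engine vs an independent 200,000-walker microsimulation at the flat
  published operating point (onset 0.067, remission 0.159, mortality
  0.029/0.045): per-cycle, per-state agreement in binomial standard-error
  units, with a family-wise allowance because ~100 cells are compared.
* End-to-end ground-truth recovery at n = 20,000 (missingness off):
  estimated disability-free years within 0.3 years of the generating-truth
  closure in every sex × group × baseline-age stratum.
* IPW experiment at n = 20,000 over 10 replicates (§4).
* Percentile-CI coverage for DFY over 100 generator replicates at
  n = 3,000 and 500 draws/sex; and null-calibration of contrast p-values
  over 40 replicate pairs at n = 1,500.

## 8. Known limitations

* Domains are perfectly concordant in the generator (§2): passing tests
  demonstrate correctness of the estimation machinery, not robustness to
  cross-domain heterogeneity in real data.
* The generator's waves are exactly biennial with MAR nonresponse; real
  panels have proxy interviews, variable gaps, and potentially
  outcome-dependent (MNAR) nonresponse that IPW cannot fix.
* Sampling weights are generic positive weights; no post-stratification or
  design-based (strata/PSU) variance is attempted — inference is
  cluster-robust by person only.
* The interval-dynamics inversion assumes the logit-linear model class; if
  annual curves were strongly non-linear in age, the parametric inversion
  would inherit that misspecification.
* Everything stops at age 70 by design; the model says nothing about the
  older ages where most age-related disability occurs.
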