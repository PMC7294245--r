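---
title: "Methods: aggregate distributional cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregate distributional cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcea)
```

## The model

`dcea` implements aggregate distributional cost-effectiveness analysis
(DCEA) for health benefits packages: given intervention-level
cost-effectiveness inputs and survey-derived socioeconomic distributions, it
asks not only *how much* health a set of interventions buys, but *who gets
it*, and values the answer with an explicit inequality-aversion parameter.
The analysis runs in four stages.

**Stage 1 — distributional net health benefit.** Each intervention is
described by its eligible population per year $A$, incremental cost per use
$C$ (USD), and incremental benefit per use $B$ (DALYs averted). Three
per-subgroup vectors distribute these aggregates over $G$ socioeconomic
subgroups (five wealth-asset-index quintiles, or urban/rural residence):

* prevalence shares $D_g$ (each subgroup's share of survey-reported cases,
  $\sum_g D_g = 1$),
* uptake rates $E_g \in [0,1]$ (cases that use the service over cases), and
* opportunity-cost shares $F_g$ ($\sum_g F_g = 1$), proxied by the
  socioeconomic distribution of utilization at public and church-based
  providers across all disease.

Direct benefit in subgroup $g$ is $A B D_g E_g$ (the same benefit per use in
every subgroup — an equal-efficacy assumption). Spending displaces health
elsewhere at the marginal productivity of health expenditure $k$ (USD per
DALY; base case \$61), distributed by $F$:
$\mathrm{oc}_g = F_g \cdot \mathrm{cost}/k$. Net health benefit is
$\mathrm{nhb}_g = A B D_g E_g - F_g \cdot \mathrm{cost}/k$.

Three costing conventions are exposed because published worked examples are
not always internally consistent: `per_treated` ($A C \sum_g D_g E_g$, the
package default — cost is incurred only for delivered services),
`per_eligible` ($A C$), and `fixed` (a supplied total used verbatim). The
packaged rotavirus worked example (`run_box1_fixture()`) reproduces its
published table only under `fixed`, because the printed total cost
(\$809,318) matches neither formula ($A C$ = \$359,697); the fixture pins
the printed value and reports all three conventions side by side rather than
guessing which generated downstream published aggregates.

**Stage 2 — baseline health.** Survey respondents' reports of sibling
deaths (all ages) and offspring deaths (ages 0–35) proxy the socioeconomic
pattern of mortality, with the respondent's subgroup standing in for the
deceased's. Per 5-year age band to 55 plus a single 55–75 band, subgroup
death rates are normalized to population-weighted mean 1 and multiply a
reference mortality schedule. Abridged lifetables use
$n q_x = n\,m_x / (1 + (n - a_x)\,m_x)$ with mid-interval deaths
($a_x = n/2$) in every band, including infancy — a documented
simplification; no separation factors are assumed. The table is **closed at
75**: deaths above 75 are not modelled, so life expectancy is bounded by 75.
An open terminal interval ($L = l_{75}/M$) is available when a terminal rate
is supplied, but truncation is the default because the death reports the
pattern is estimated from exclude ages above 75. The Sullivan method then
discounts person-years by the proportion lived with disability:
$\mathrm{HALE} = \sum_x {}_nL_x (1 - \mathrm{yld}_x) / l_0$, where YLD rates
are dimensionless proportions of band person-years (this keeps the product
well-defined for any band scheme). The population YLD schedule is split over
subgroups by disease shares: subgroup rate = total rate × share$_g$ /
population-share$_g$, conserving the population mean in every band.

**Stage 3 — inequality valuation.** The equally distributed equivalent
(EDE) of a grouped health distribution $h_g$ with population weights $w_g$
under inequality aversion $\varepsilon$ is

$$h^{EDE} = \Big[\sum_g w_g\, h_g^{\,1-\varepsilon}\Big]^{1/(1-\varepsilon)},$$

with the weighted geometric mean as the $\varepsilon = 1$ limit and the mean
at $\varepsilon = 0$. The Atkinson index is $1 - h^{EDE}/\bar h$, and
$\bar h - h^{EDE}$ is the cost of inequality in healthy years per person.
The base-case aversion is 10, a deliberately strong value used in the
absence of a local elicitation; 2 and 25 bracket it in the scenario grid.
Each intervention's $\mathrm{nhb}_g$ is converted to healthy years per
person ($\mathrm{nhb}_g / n_g$) and added to the baseline HALE distribution;
the intervention's population net health benefit
$\Delta NHB = N\,\Delta\bar h$ and EDE change $\Delta EDE = N\,\Delta
h^{EDE}$ place it on the equity impact plane, with inequality impact
$\Delta EDE - \Delta NHB$ on the x axis. Evaluation is grouped (five
quintile blocks or two residence blocks with fixed weights), not
person-level: subgroups are treated as homogeneous, which is the aggregate
in aggregate DCEA.

**Stage 4 — scenario sensitivity.** Scenarios are declarative transform
lists over disjoint inputs: equalize or tilt prevalence, uptake, or
opportunity-cost shares; replace $k$ (37 or 116); switch the mortality
pattern to offspring deaths under age 20 only; replace $\varepsilon$ (2 or
25). Tilts multiply the two poorest quintiles' entries by 1.1 and the two
richest by 0.9; sum-constrained vectors are then renormalized to 1 (uptake
is clipped at 1 instead and never renormalized). Whether the original
analysis renormalized its ±10% tilts is not stated; renormalization is the
default here because tilted *shares* must remain shares, and the
non-renormalized variant is exposed via `renormalize = FALSE`. Equalized
uptake is the prevalence-weighted population mean (total utilization over
total cases). Transforms are pure: each scenario restarts from untouched
base-case inputs.

## Properties the tests pin down

The suite asserts, among others: conservation ($\sum_g$ eligible $= A$,
$\sum_g \mathrm{oc}_g = \mathrm{cost}/k$, $\sum_g \mathrm{nhb}_g$ identity)
to 1e-9 relative; EDE $\le$ mean with equality iff flat, and the transfer
principle (mean-preserving transfers toward worse-off groups never reduce
the EDE) on 1,000 random instances; agreement of the abridged lifetable
with the exponential closed form $(1-e^{-75\mu})/\mu$ under fine
sub-banding (1e-6); and Sullivan linearity
($\mathrm{HALE} = (1-y)\,\mathrm{LE}$ under constant YLD $y$).

One commonly assumed property is *false* and deliberately not asserted: a
uniform per-person addition $c$ does **not** raise the EDE by at most $c$.
The EDE is concave and homogeneous of degree one, hence superadditive, so
$h^{EDE}(h + c\mathbf{1}) \ge h^{EDE}(h) + c$: adding the same amount
everywhere *reduces relative inequality* and the EDE gains slightly more
than the mean does. The tests assert the correct bounds
$[c,\; c + (\bar h - h^{EDE})]$.

## The synthetic survey generator

No microdata ship with the package. `synthetic_config()` /
`generate_survey()` emulate the *structure* of the household surveys such an
analysis consumes: households with a latent wealth score uniform on
$[0,1]$, urban residence with probability 0.15, a binary asset battery,
members with two-week-recall disease codes, care seeking with provider
codes, and respondent-reported sibling/offspring deaths. All randomness
flows from one configured seed.

Design choices that matter:

* **Asset battery.** 30 assets with ownership thresholds evenly spaced over
  the wealth range and a logistic discrimination of 40. This makes the
  equal-weight asset index (score $= 100 \times$ assets owned / battery
  size, the simplified wealth-index convention used by `compute_wealth_index()`)
  an accurate *ranking* of latent wealth — about 90% of households land in
  their true quintile. That fidelity is a requirement, not a nicety: the
  package guarantees that its estimators recover the generator's prevalence
  shares, uptake rates and opportunity-cost shares to within ±2 percentage
  points at 20,000 households (seed-averaged over five seeds), and index
  misclassification biases estimates toward uniformity. A real asset index
  is a noisier instrument; the generator models an informative one by
  design, so recovery failures signal estimator bugs rather than instrument
  noise.
* **Gradients.** Disease prevalence, uptake and mortality hazards are base
  rates times per-quintile multiplicative factors, clipped to $[0,1]$ with a
  warning. Default gradients are smooth and monotone (e.g. prevalence
  factors 1.5, 1.2, 1.0, 0.8, 0.6) at base two-week prevalences of
  0.12/0.12/0.10 across three stylized conditions — levels at which every
  quintile observes enough cases that the ±2pp recovery guarantee is
  comfortably inside sampling noise. Strongly jagged patterns (as raw survey
  tables sometimes show) remain available through configuration, and the
  catalog generator's default *prevalence pattern* (0.36, 0.16, 0.23, 0.13,
  0.12) reproduces that published flavour directly, since catalog share
  tables are inputs rather than survey estimates.
* **One disease code per member per recall window**, matching
  single-answer survey questions; at most one provider code, present only
  when care was sought.
* **What is not emulated:** survey design (weights, clustering,
  non-response), household demography beyond a Poisson size model, recall
  and social-desirability bias, and any calibration to real national
  marginals. Passing recovery tests therefore show the estimators are
  correct on clean simple-random samples — not that a real survey would be
  free of design effects or reporting bias.

The reference mortality and YLD schedules under `inst/extdata/` are
**synthetic** (filenames say so): stylized single-country tables chosen so
the truncated-at-75 life expectancy (≈59.3 years) and mean HALE (≈52.7
healthy years) sit in the range reported for a low-income, high-burden
setting. They stand in for published burden-of-disease tables, which are not
redistributed here.

## Numerical choices

* Report tables round half-up to whole persons/DALYs and two decimals for
  proportions — matching the presentation convention of published worked
  examples — while all pipeline arithmetic keeps full precision
  (`round_half_up()` is applied only at the reporting edge).
* The EDE power form is ill-conditioned as $\varepsilon \to 1$; within
  $|\varepsilon - 1| < 10^{-6}$ the geometric-mean limit is used, which
  keeps the limit check tight to 1e-9.
* Wealth-quintile boundaries are person-weighted (each quintile holds one
  fifth of *people*, not households); the analysis is silent on this in most
  published work, and person-weighting matches how population shares enter
  every later stage. Ties in the asset score are broken by household
  identifier after sorting by score, for determinism.
* Missing share cells are `NA`, never 0: wholly missing prevalence vectors
  get the renormalized element-wise mean of observed vectors; missing uptake
  *entries* get that subgroup's mean uptake across interventions (observed
  entries are kept — the minimal per-entry extension of the whole-vector
  imputation rule, flagged in the output).
* Pipeline outputs are written with 15 significant digits so manifest
  digests are reproducible across platforms.

## Problem sizes

The shipped tests run the full pipeline at 73 interventions and 1,500–2,500
households (seconds), and the parameter-recovery check at 20,000 households
× 5 seeds (~5 s), sizes chosen so the statistical guarantees are sharp while
the suite stays fast. The same code runs unchanged at larger sizes.

## Limitations

Grouped evaluation ignores within-subgroup inequality; benefits per use are
equal across subgroups by assumption; a single year of implementation is
modelled with no discounting; wealth and residence dimensions are evaluated
separately, never jointly; and the scenario grid is deterministic — no
probabilistic sensitivity analysis.
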