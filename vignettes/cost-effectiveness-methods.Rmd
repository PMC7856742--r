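---
title: "Methods: a Markov cost-effectiveness model for early breast cancer surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-effectiveness model for early breast cancer surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebccea)
```

## The decision problem

Three surgical strategies for early breast cancer are compared over a
lifetime horizon: mastectomy (`MAST`), breast-conserving therapy (`BCT`),
and mastectomy with immediate reconstruction (`MAST_RECON`). The cheaper
option differs from the others mainly in quality of life (health
utilities) and in post-metastasis survival, so the trade-off is a classic
cost-per-QALY question, judged against a willingness-to-pay (WTP)
threshold of 3× per-capita GDP ($27,931.04/QALY).

## Model structure and assumptions

The cohort model has four clinical states — disease-free survival (DFS),
local recurrence (LR), distant metastasis (MET), death — with annual
cycles and these structural hypotheses:

* from DFS a patient can move to LR or to MET (competing exits);
* from LR a patient can move to MET;
* breast-cancer death occurs only from MET;
* death is absorbing, and the whole cohort starts disease-free.

First-year costs and utilities of DFS and of LR differ from later years,
but only four clinical states are named; the standard encoding is used:
`DFS_Y1` and `LR_Y1` are **single-cycle tunnel states** that every entrant
occupies for exactly one cycle before advancing to `DFS_PLUS` / `LR_PLUS`.
Both members of each pair share the same exit probabilities; only their
rewards differ.

Two structural gaps in the inputs required decisions:

* **LR beyond the first year.** The input table prices and values only the
  *first* recurrence year. By default `LR_PLUS` reverts to the strategy's
  annual follow-up cost and its subsequent-year DFS utility; passing
  `lr_plus = "lr_y1"` to `assemble_cost_schedule()` / `utility_set()`
  instead holds the first-year recurrence values. The state is reachable
  only for `BCT` and `MAST_RECON` (`MAST` converts recurrences to
  metastasis with probability 1).
* **Other-cause mortality.** The model's source asserts that patients face
  non-breast-cancer death risk but provides no life table, so the default
  model has *no* background mortality. `run_cohort()` accepts an optional
  per-cycle probability stream, applied competitively (every living
  state's transitions scaled by `1 − q`, with `q` routed to death). This
  toggle is the leading explanation for why the package's absolute totals
  exceed otherwise comparable published totals: with no other-cause death,
  disease-free survivors accrue costs and QALYs for the full 60 years.
  The package therefore treats absolute totals as *not* reproducible and
  validates structure instead: occupancy conservation (to 1e-10 over 60
  cycles), the closed-form discounted annuity in the degenerate
  no-transition model, cost/QALY orderings, the position of the ICER
  relative to the WTP, and extended dominance.

## Rewards, discounting, half-cycle correction

Per-cycle state costs: the first DFS year carries surgery-year hospital
and outpatient costs plus transportation (visits × 80 CNY / 6.93 CNY/USD)
and lost-work costs (days × annual wage / 365 — the /365 convention
reproduces the published daily wage of $25.59 to the cent); later DFS
years carry the annual follow-up cost; the first LR year carries the
recurrence costs; each MET year the annual metastasis costs. The
three-months-before-death cost is a **one-time flow reward** on the
MET→death transition, accrued at the cycle of transition.

Cycle *t* rewards are discounted by $(1+d)^{-t}$ with the first cycle at
$t = 1$ and $d = 0.03$/year, so the degenerate model with constant
utility $u$ and no transitions yields exactly
$u \sum_{t=1}^{60} (1+d)^{-t}$ — the oracle used in the tests. With the
half-cycle correction (default on) state rewards accrue on the average of
start- and end-of-cycle occupancy; flow rewards are deliberately *not*
half-cycle corrected (they are flows, not occupancies). The corrected
total always lies between the start- and end-of-cycle evaluations, and
equals their average.

## Transition probabilities from competing-risks data

Patient-level event histories are summarised per transition with the
clock reset at state entry (the cohort model is memoryless): DFS→LR with
metastasis as the competing first transition, DFS→MET with recurrence
competing, then LR→MET and MET→death on the sub-cohorts entering those
states. Cumulative incidence is estimated by the Aalen–Johansen estimator
(via `survival`'s multi-state machinery; `cmprsk` serves as an
independent cross-check in the tests), with tied event times processed
simultaneously. The terminal cumulative incidence $P_1$ over the
follow-up span $t_1$ (years) converts to an annual probability by
$r = -\ln(1-P_1)/t_1$, $P = 1-e^{-r t_2}$, $t_2 = 1$. Two conventions
matter:

* $P_1$ is the cumulative incidence itself. For the mastectomy
  local-recurrence example (incidence 0.031 over 94 months) the formula
  gives `r signif(annual_probability(0.031, 94/12), 6)`; the published
  value 0.004019 differs in the fourth significant digit, consistent with
  rounding in the source, and the package reproduces the formula.
* Degenerate estimates are taken at face value: a terminal incidence of 1
  is clamped to $1-10^{-12}$ before conversion (yielding an annual
  probability of 1), and a zero-event curve yields 0.

Group differences are tested with Gray's K-sample statistic (computed by
`cmprsk::cuminc`) but with a **permutation p-value** (default 2,000 label
shuffles; exact enumeration whenever the number of distinct label
arrangements is no larger) rather than the asymptotic chi-square — the
permutation reference is exact at any sample size and costs little at
these n.

## The synthetic registry

No patient-level data ship with the package. The generator emulates what
the downstream stages need:

* **Covariates** drawn from the published post-matching marginals: age as
  a truncated normal on [18, 90] (mean ≈ 38.8, sd ≈ 7.2) and nine
  categorical covariates (insurance, lesion location, histology, TNM
  stage, BMI class, hormone receptor, patient source, neoadjuvant
  chemotherapy, targeted therapy) drawn independently — the source
  reports marginals only, so no covariate correlation is emulated.
* **Treatment assignment** either balanced per group, or by a multinomial
  logit on age, BMI, TNM stage and neoadjuvant therapy with intercepts
  giving roughly 75/8/17% shares — deliberately confounded, so the
  matching stage has selection bias to remove.
* **Event histories** as competing exponential clocks per transition,
  rates $r = -\ln(1-p)$ from the annual probabilities (a probability of 1
  is represented by a capped rate of $-\ln(10^{-12})$/year, i.e. a
  near-immediate transition), with administrative censoring at 94 months
  — the constant-hazard process is exactly the generative counterpart of
  a time-homogeneous annual transition matrix. Hazards vary by strategy
  only; optional covariate effects on hazards are out of scope by
  default, since the source gives no covariate–outcome model.

One master seed drives separate sub-streams for covariates, assignment
and events, so each stage is independently reproducible. Passing tests on
this generator demonstrate internal consistency of the pipeline
(parameter recovery at 5,000 patients per arm stays within three
delta-method standard errors of each generating probability, and within
15% for the dominant metastasis transitions); they do not demonstrate
robustness to features real registries have — covariate-dependent
hazards, non-exponential waiting times, informative censoring.

## Matching

Propensities come from a multinomial logit on all registry covariates
(`nnet::multinom`); matching is greedy 1:1 nearest-neighbour without
replacement, reference group `MAST_RECON` (the smallest), on the pairwise
linearised score $\log p_{\text{ref}} - \log p_{\text{comp}}$, reference
patients processed in descending score order, distance ties broken toward
the lowest patient id (so matching is deterministic and seed-free), no
caliper by default. Greedy matching is the convention of standard PSM
software but is not globally optimal: on interleaved score
configurations it can exceed the minimal-total-distance assignment, which
the tests acknowledge by asserting equality only on separated-cluster
instances and the published toy example. Balance is reported as the
maximum pairwise standardized mean difference per covariate (max over the
three group pairs, and over levels for categoricals) plus ANOVA /
chi-square / Kruskal–Wallis p-values. Note the noise floor: with ~200
patients per matched group, the max-pairwise SMD of even perfectly
matched groups fluctuates around 0.1 for multi-level covariates, so only
the strongly confounded covariates are expected below the conventional
0.1 line; the p-value table is the more interpretable summary at this
size.

## Sensitivity analysis

**One-way:** each parameter in turn is set to its published lower and
upper bound (the discount rate to 0 and 5%) with everything else at
baseline, and the BCT-vs-MAST ICER is recorded; bars are sorted by width.
**Probabilistic:** each iteration independently re-draws every
distribution-family parameter — beta for probabilities and utilities,
lognormal for costs, each moment-matched to mean = baseline and
sd = (upper − lower)/3.92, treating every printed range as a central 95%
interval (the source does not distinguish true confidence intervals from
±20% constructions row by row, so one uniform convention is used). The
discount rate is a `constant` entry and stays fixed. Degenerate entries
(range of zero width, or a beta baseline on the support boundary — the
0.000000 and 1.000000 transition rows) become point masses, the latter
with a warning. Strategy selection is by highest net monetary benefit
$\text{NMB} = \text{WTP}\times\text{QALY} - \text{cost}$, which provably
agrees with the frontier-plus-threshold classification (property-tested
on 1,000 random instances). The analysis scripts run 1,000 iterations;
the test suite's calibration check runs 10,000.

A known, deliberate limitation: the PSA mean is *not* an unbiased
estimate of the base case. Every sampler is exactly mean-matched to its
baseline, but lifetime cost is a convex function of the transition
probabilities (expected metastasis sojourn behaves like
$1/p_{\text{MET}\to\text{death}}$), so the Monte-Carlo mean cost sits a
fraction of a percent above the deterministic total — a Jensen gap that
becomes statistically visible around 10,000 iterations. This is a
property of any PSA that re-draws transition parameters, not an
implementation artifact; the linear-regime check (costs varied,
transitions fixed) converges to the base case as expected.

## Numerical conventions

* Extended dominance by the iterative sequential-ICER algorithm on the
  cost-sorted frontier; equal sequential ICERs are *kept* (collinear
  points survive); identical cost/QALY points resolve toward the
  earlier-listed strategy.
* Probability/rate conversions use `log1p`/`expm1`, making the
  round-trip exact to 1e-12 and the $t_1 = t_2$ case the identity.
* Transition matrices validate row sums to 1e-12; DFS exit probabilities
  summing above 1 are an error naming the state.
* Parameter ranges absent from an input file are filled at ±20% of
  baseline, clamped to the family's support; beta-family entries must lie
  in [0, 1], lognormal entries must be positive, and every violation
  names the offending parameter.
* Currency is USD throughout at 6.93 CNY/USD; CNY appears only at the
  transportation boundary. One inconsistency in the source is documented
  rather than resolved: the narrative lost-work cost for `BCT` ($940.71)
  disagrees with its own input table ($997.85 = 39 days × wage); the
  packaged table follows the input table.

## Problem sizes

The shipped configuration uses the study's own scale: 60 annual cycles,
administrative censoring at 94 months, ~200 patients per matched arm in
the analysis scripts (from a 4,000-patient synthetic registry), 1,000 PSA
iterations in the scripts. The test suite chooses sizes per purpose:
5,000 patients per arm for parameter recovery, 10,000 PSA iterations for
the calibration check, exact enumeration for the small-sample permutation
tests.
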