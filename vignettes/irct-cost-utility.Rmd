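---
title: "Cost-utility microsimulation of surgery for irreparable rotator cuff tears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility microsimulation of surgery for irreparable rotator cuff tears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irctcea)
```

## The decision problem

Massive irreparable rotator cuff tears (IRCTs) that fail nonoperative
management can be treated by four common procedures: superior capsular
reconstruction (SCR), lower trapezius tendon transfer (LTTT), subacromial
balloon spacer implantation (SABS), and reverse shoulder arthroplasty (RSA).
The procedures differ substantially in upfront cost, in the shoulder
function they restore, and in their annual rates of arthroscopic revision
and of conversion to RSA. `irctcea` implements a probabilistic Markov
microsimulation that weighs these trade-offs in quality-adjusted life years
(QALYs) and US dollars from the payer perspective.

The package is organised in five layers, each independently testable:

1. **Configuration** (`model_config`, `builtin_irct_config`): the decision
   problem as data -- strategies, transition probabilities, costs,
   utilities, global settings -- with strict validation and YAML
   serialization.
2. **PSA distributions** (`build_psa_specs`, `sample_parameter_set`):
   method-of-moments sampling distributions for every input.
3. **Markov engine** (`simulate_patient`, `simulate_arm`,
   `cohort_expectation`): patient-level simulation plus its deterministic
   oracle.
4. **CEA statistics** (`cea_table`, `ceac`, `nmb`, `dominance_and_icers`,
   `confidence_ellipse`): league tables, acceptability curves, dominance
   and ellipses.
5. **Synthetic scenarios** (`generate_random_config`,
   `enumerate_trajectories`): random valid decision problems and an
   exhaustive-enumeration oracle that pins down the engine's semantics
   exactly.

## Model structure

Each simulated patient pays the strategy's upfront cost at cycle 0 and then
moves through annual cycles over a 10-year horizon. Four health states are
distinguished:

* **index success** -- at risk: each year the patient may undergo
  arthroscopic revision (probability `p_reoperation`) or conversion to RSA
  (`p_conversion`); otherwise they accrue the strategy's success utility;
* **post-revision success** -- absorbing: after an arthroscopic revision
  (cost: the strategy's upfront cost plus the 5% revision uplift) the
  patient accrues the strategy's success utility for the remaining years;
* **converted to RSA** -- after conversion (cost: the RSA upfront cost) the
  patient accrues RSA's success utility;
* **post-RSA-revision success** -- absorbing, used when post-conversion
  revision risk is enabled (below).

The RSA strategy itself is modelled as `p_conversion = 0` with
`p_reoperation` equal to the annual revision-RSA probability; its revision
event books the uplifted RSA cost. In the cycle an event occurs the patient
accrues the shared failure utility (0.35) instead of a success utility.
Costs and QALYs of cycle *t* are discounted by $(1+d)^{-t}$ at $d = 3\%$
per year; the index cost is booked undiscounted at $t = 0$. No half-cycle
correction is applied and no background mortality is modelled over the
10-year horizon.

Utilities are derived from Constant-Murley shoulder scores scaled by 1/100
(`utility_from_cms`), so a mean score of 76 after SCR becomes a utility of
0.76.

### Structural choices

Three aspects of the pathway are not fully determined by the published
description, and the package fixes them as follows.

**One event of each kind per pathway.** Revision states are absorbing by
default: a patient revised arthroscopically faces no further risk, and the
same holds after a revision RSA. A `repeat_events` settings flag re-opens
the at-risk states for sensitivity analysis; the enumeration oracle refuses
that variant because the outcome space is no longer finite-small.

**Conversion to RSA is terminal by default.** Whether converted patients
face the annual revision-RSA hazard for their remaining years is a genuine
structural unknown. We calibrated the choice against the published
cost-accumulation pattern using the deterministic cohort oracle: with
post-conversion revision risk active, the strategies with material
conversion probabilities (SABS, LTTT) accumulate roughly 14--16% more
expected cost than the published means, while with conversion treated as
terminal all four expected costs sit within 10% and the SCR-vs-SABS
incremental ratio within 8%. The terminal-conversion structure is therefore
the default, and the at-risk variant remains available as
`model_settings(post_conversion_revision = TRUE)` -- the engine, the cohort
oracle and the enumeration oracle all support both.

**Revision-RSA uplift.** The 5% revision surcharge is stated for
arthroscopic revisions; we apply it to revision RSA as well for symmetry.
`model_settings(uplift_rsa_revision = FALSE)` switches that assumption off.

A consequence of the branching structure worth knowing: expected QALYs are
*not* globally monotone in `p_reoperation`. Because an arthroscopic
revision absorbs the patient into a success state, a higher revision hazard
can shield patients from later conversion to the lower-utility RSA state
and thereby slightly *raise* expected QALYs. Monotonicity does hold for
each competing risk in isolation, and that is what the property tests
verify.

## PSA input distributions

Input uncertainty follows the conventional family assignment, with
parameters derived by exact method of moments:

* costs: gamma, $\mathrm{shape} = (\mu/\sigma)^2$,
  $\mathrm{scale} = \sigma^2/\mu$, with $\sigma = 0.20\,\mu$ (hence shape 25
  for every cost input);
* probabilities: beta, $\alpha = \mu\nu$, $\beta = (1-\mu)\nu$,
  $\nu = \mu(1-\mu)/\sigma^2 - 1$, with $\sigma = 0.20\,\mu$; a probability
  of exactly 0 (RSA's conversion) is a degenerate point mass, since a beta
  distribution has no mass at a zero mean;
* utilities: normal with absolute $\sigma = 0.05$, clipped (not resampled)
  into $[0,1]$ -- at these SDs the clip probability is below $10^{-10}$, so
  the moment distortion is negligible.

Draws are mutually independent within an iteration; no rank correlation is
induced. If a sampled `p_reoperation + p_conversion` exceeds 1 the pair is
rescaled proportionally (never triggered at base-case magnitudes), and a
sampled failure utility is capped at the smallest sampled success utility
so every sampled parameter set is itself a valid configuration.

`quantile_range` returns analytic 10th/90th percentiles of each
distribution, and `psa_spec_table` tabulates all of them next to the base
values for reconciliation against the published input table. The published
10--90% ranges behave like *empirical* percentiles of a finite PSA sample
(about 1000 draws): they deviate from the analytic quantiles by amounts
comparable to the sampling error of an order statistic at that sample size
(up to a few hundred dollars on cost inputs), not by rounding alone. The
reconciliation test therefore allows half a printed rounding unit plus
three standard errors of an $n = 1000$ empirical percentile, computed
analytically per row.

## Microsimulation, oracles and reproducibility

`run_psa` performs the two-level loop: each of 1000 iterations draws one
parameter set and microsimulates 1000 patients per strategy arm (the
simulation is vectorized across patients; one uniform draw per patient per
cycle). Iteration *i* runs under its own derived seed, so results are
independent of batching; `(config, seed)` determines every output byte.

Two deterministic oracles validate the engine:

* `cohort_expectation` propagates the state-occupancy distribution forward
  and accrues expected discounted cost/QALYs -- the exact mean of the
  microsimulation;
* `enumerate_trajectories` lists every distinguishable patient pathway
  (event kind x event cycle x optional second event) with its exact
  probability and totals; probabilities sum to 1 and the expectation equals
  the cohort oracle to $10^{-9}$.

The test suite checks microsimulation means against the cohort oracle on 50
random synthetic configurations and the empirical outcome frequencies
against the enumerated distribution by a chi-square goodness-of-fit test.
The synthetic scenario generator (`generate_random_config`) produces
structurally identical random decision problems (2--6 strategies, bounded
joint annual risk, valid utilities), which is what makes those checks
independent of the built-in base case. Synthetic scenarios share the real
model's *structure* but not its empirical anchoring: passing them shows the
engine computes the specified process correctly, not that the base-case
inputs describe any particular patient population.

## Cost-effectiveness statistics

Per-strategy results are summarised across iterations
(`aggregate_psa`), classified for dominance (`dominance_and_icers`:
absolute dominance pairwise, extended dominance by pruning non-monotone
frontier ICERs), and assembled into a league table (`cea_table`) whose
incremental columns are relative to the cheapest strategy, the convention
of published league tables (dominated rows therefore carry negative
ICERs). Net monetary benefit is $\mathrm{NMB} = \mathrm{QALY} \cdot
\lambda - \mathrm{cost}$ at willingness-to-pay $\lambda$, with
$\lambda = \$50{,}000$/QALY as the conventional threshold.

**Iteration-level vs patient-level shares.** The probability that a
strategy is optimal can be evaluated at two levels: the share of PSA
*iterations* whose arm means give it the maximal NMB (standard
acceptability-curve practice), or the share of individual simulated
*patients* for whom it has the maximal NMB (the per-patient reporting of
microsimulation software, which folds patient-level event noise into the
comparison). The two differ materially here -- patient-level noise flattens
the curves -- and the published headline shares (60/31/9/0 at
$50,000/QALY) correspond to the patient-level reading, which is the
package default; `level = "iteration"` selects the other. The same switch
applies to `ceac` and `cea_table`. `crossover_wtp` locates the
willingness-to-pay at which one acceptability curve first overtakes
another, with linear interpolation between grid points (default grid $0 to
$100,000 in $1,000 steps, covering the usual reporting range).

Confidence ellipses on the incremental cost-effectiveness plane use
normal-theory geometry: semi-axes $\sqrt{\lambda_i \,\chi^2_{2,0.95}}$
($\chi^2_{2,0.95} = 5.991$) along the covariance eigenvectors.

## Numerical and degenerate-input conventions

* Moment inversions are closed-form and exact; feasibility
  ($\sigma^2 < \mu(1-\mu)$ for beta, positivity for gamma) is checked with
  explicit errors naming the constraint.
* Ties in NMB maximisation go to the earlier strategy in configuration
  order; strategy sets with exactly duplicated (cost, QALY) points keep the
  lexicographically first on the frontier.
* A degenerate covariance (all incremental pairs identical) flags the
  ellipse rather than fabricating axes.
* Occupancy conservation in the cohort oracle is maintained to $10^{-12}$
  per cycle.
* YAML configuration parsing is strict: unknown keys and missing fields are
  errors naming the field path, so silent misconfiguration cannot occur.

## Problem sizes

The reference analysis is 1000 iterations x 1000 patients (what
`scripts/acceptance.R` runs; about 10--15 s on one CPU). The test suite
exercises the same pipeline at 200 iterations x 500 patients, which keeps
the whole suite under a minute while leaving Monte Carlo error well inside
the tolerances being asserted; oracle-agreement tests use 2,000--100,000
patients per arm as precision requires.

## Known limitations

* No background mortality, no death state, and no adverse events beyond
  revision and conversion; the 10-year horizon keeps these omissions mild
  but they bias against strategies with late failures.
* The published RSA mean QALY (3.78) lies *below* the event-free analytic
  bound $0.59 \times \sum_{t=1}^{10} 1.03^{-t} = 5.03$ implied by RSA's own
  stated success utility, so it cannot be reproduced by any structure
  consistent with the published inputs; the model here yields about 4.9.
  Cost and dominance conclusions are unaffected (RSA is absolutely
  dominated either way), and RSA's QALY is excluded from numeric
  validation.
* Costs are single per-procedure payer amounts as published; follow-up and
  rehabilitation costs are not separately modelled, and no inflation
  adjustment is applied.
* Sampling distributions are uncorrelated; if real parameter uncertainty
  is correlated (e.g. costs co-moving across strategies), iteration-level
  spread is understated.

## A worked base case

```{r base-case}
cfg <- builtin_irct_config()
run_base_case(cfg)
```

The deterministic expectations already show the pattern the PSA confirms:
SABS is by far the cheapest arm, SCR buys the most QALYs, and LTTT and RSA
are both more expensive and less effective than at least one alternative.

```{r psa, eval = FALSE}
psa <- run_psa(cfg, seed = 1)          # 1000 x 1000, ~10 s
cea_table(psa)                         # league table, patient-level shares
cv <- ceac(psa, wtp_grid = seq(0, 50000, 1000))
crossover_wtp(cv, "SCR", "SABS")       # WTP where SCR overtakes SABS
```
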