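---
title: "Model and methods: three-state cost-effectiveness model of TAVI versus SAVR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: three-state cost-effectiveness model of TAVI versus SAVR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tavicea)
```

## The decision problem

Severe symptomatic aortic stenosis at intermediate surgical risk (STS
predicted mortality 4–8%) can be treated by transcatheter aortic valve
implantation (TAVI) or by conventional surgical aortic valve replacement
(SAVR). TAVI is far more expensive per episode; its clinical benefit in
this risk band is equivocal, with early advantages that attenuate over
five years. `tavicea` implements a three-state Markov model — *no stroke*,
*stroke* (disabling/major stroke with long-term sequelae), and *death*
(absorbing) — on monthly cycles, evaluated either as a deterministic
cohort trace or as a first-order microsimulation, to estimate the
incremental cost per quality-adjusted life year (QALY) of TAVI over SAVR
from a healthcare-system perspective (costs in 2020 US$).

The base case uses five-year PARTNER 2A transfemoral intention-to-treat
milestone probabilities (30 days, 1, 2 and 5 years) for all-cause
mortality, disabling stroke and ten further adverse events (AEs);
stroke-vs-no-stroke mortality hazard ratios by month since stroke onset;
Singapore episode and AE treatment charges; and PARTNER 2A EQ-5D
utilities. All inputs ship as versioned YAML files under
`inst/extdata/` and are never hard-coded in logic.

## From milestone probabilities to transition probabilities

Trial readouts arrive as cumulative probabilities $C(m)$ at milestone
months $m \in \{1, 12, 24, 60\}$. Within an interval the monthly
incidence rate is assumed constant, giving the conditional per-cycle
probability $p$ solving $(1-p)^{n} = S(m_1)/S(m_0)$ with $S = 1 - C$
(`interval_monthly_prob()`). The generic transition formula is the
conditional-probability form $p_t = 1 - S(t)/S(t-1)$; the orientation
with $t$ and $t-1$ exchanged, which is sometimes printed, yields negative
values for any decreasing survival curve and is treated as a typo.

Two bridging modes are available for the extrapolated portion of
all-cause mortality (`settings$mortality_bridge`):

* **linear** (default): cumulative mortality increases linearly in time
  within intervals starting at or after `mortality_linear_from`
  (month 24 in the base case, where the 2→5-year segment rests on a
  point estimate rather than an observed curve);
* **constant**: geometric (constant-rate) bridging throughout.

Both reproduce every milestone exactly; they differ only mid-interval.
Linear bridging is the default because the five-year mortality segment
is explicitly an extrapolation under a linear-increase assumption, and
because the timing of the TAVI–SAVR mortality crossover (the model's key
qualitative behaviour, cycle 45 ≈ 3.75 years) depends on the
within-interval shape: constant-rate bridging moves the crossover to
cycle 42. The switch makes the sensitivity of results to this choice
directly checkable.

Paravalvular aortic regurgitation (PAR) is reported as a *prevalence*
(it falls between 2 and 5 years in the TAVI arm, 8.27% → 6.44%), which a
cumulative incidence cannot do. PAR therefore uses `kind: prevalence`:
per-cycle new incidence is the positive part of the prevalence
increment spread over the interval, floored at zero — decreasing
prevalence generates no events and no cost refunds, since AE costs are
one-time at incidence.

### Splitting mortality by stroke status

Patients in the stroke state carry an elevated death hazard for the
first 15 months after stroke onset (hazard ratios 8.5 falling to 1.16),
and the no-stroke hazard thereafter. With whole-cohort monthly mortality
$M$, stroke-state proportion $X$ and hazard ratio $RR_S$, the no-stroke
mortality is the unknown:

$$M_{NS} = \frac{M}{X \cdot RR_S + (1 - X)}, \qquad M_S = RR_S \cdot M_{NS}.$$

Because the hazard ratio is indexed by *time since stroke onset*, not
model time, the implementation tracks stroke duration: the cohort trace
stratifies the stroke state by months since onset (microsimulation
tracks it per patient), and the split generalises to the
duration-weighted mixture
$M_{NS} = M \cdot \text{alive} / (\text{ns} + \sum_d s_d \, RR_d)$.
Using the model's own deterministic composition in the denominator makes
the implied all-cause survival reproduce every milestone to $10^{-9}$ by
construction. If a capped stroke-stratum probability saturates at 1
(possible only in degenerate inputs), the remainder is re-solved over
the uncapped strata so total deaths still match. Beyond 15 months
post-stroke the excess hazard is removed ($RR = 1$): the stated
behaviour is "no difference in the hazard of death" between states, and
reverting to a *lower* background-population hazard would contradict the
all-cause milestone constraint.

AE incidences apply independently of health state, conditional on being
alive at cycle start.

## Engine: accrual rules

Per cycle, in order: AE draws → incident stroke → death. The cycle's
utility and follow-up cost are forfeited on death within the cycle; AE
costs already incurred that cycle are kept. Specifically:

* **Index episode** (TAVI 54,301; SAVR 26,109) charged once,
  undiscounted, at entry.
* **AE costs**: one-time mean treatment charge per incident event
  (including 14,243 per incident stroke), on the population alive at
  cycle start.
* **Follow-up**: one cardiologist visit per year (372), spread as
  372/12 per surviving cycle; one neurologist visit per quarter (243/3
  per cycle) while in the stroke state.
* **QALYs**: end-of-cycle occupancy × utility × 1/12.
* **Discounting**: $(1.03)^{-t/12}$ at cycle $t$ (3% per annum for both
  costs and outcomes; OWSA varies 0–5%).
* No half-cycle correction by default (`half_cycle_correction` flag
  available); the original analysis gives no indication one was used.

Utilities interpolate linearly between the month-1, month-12 and
month-24 nodes; beyond month 24 both arms receive the TAVI month-24
value (0.78), so no between-arm utility difference persists past two
years. No AE disutilities apply in the base case (the trial utilities
already reflect AE burden); scenario 4 switches them on — one-off QALY
decrements at incidence, except stroke, whose 0.161 decrement applies
every cycle spent in the stroke state. Both rules are configurable.

Microsimulation draws each patient's events from the same per-cycle
schedule, so the cohort trace is its exact expectation; agreement at the
$O(1/\sqrt{n})$ Monte Carlo rate is asserted in the test suite. Fixed
seeds give identical results, and both arms reuse the seed (common
random numbers).

## Analyses

* **Base case** (`base_case()`): both arms over 60 months, ICER
  $= \Delta C / \Delta E$, dominance labels when signs disagree, and
  incremental net monetary benefit $INB = \lambda \Delta E - \Delta C$
  at the willingness-to-pay $\lambda$ = US\$34,091/QALY.
* **One-way sensitivity analysis** (`owsa()`): each parameter at its
  95% CI bounds where the input tables provide one, otherwise ±20%
  (discount rate: 0–5%), evaluated in cohort mode to isolate parameter
  effects from first-order noise; ordered for a tornado diagram. The
  original tornado separates implant and procedure cost components; only
  the combined episodic charges are published, so the combined charge is
  varied here and the component split is out of reach.
* **Probabilistic sensitivity analysis** (`psa()`): 5,000 second-order
  draws by default. Month-1 event probabilities and utilities are beta
  distributed, AE costs gamma distributed, all parameterised by method
  of moments from the published means and SDs/CIs. Probabilities with no
  published CI take ±20% as a 95% interval (sd $= 0.2\mu/1.96$) —
  consistent with the ±20% deterministic range used elsewhere. Month-1
  draws that would break cumulative monotonicity are re-drawn (bounded
  retries). Draws are independent; no correlation structure is
  published. Each draw is evaluated in cohort mode (exact inner
  expectation; inner microsimulation is available behind a flag). The
  mean probabilistic ICER is the ratio of mean increments, robust to
  near-zero $\Delta E$ draws; the unstable mean-of-ratios alternative is
  available and flagged as such. The CEAC reports the fraction of draws
  with positive INB on a willingness-to-pay grid.
* **Scenarios** (`run_scenario()`): (1) PARTNER S3i one-year outcomes
  extrapolated to five years; (2) SURTAVI two-year outcomes with both
  arms projected beyond 24 months at the SAVR second-year rate; (3) a
  20-year horizon on base-case inputs; (4) AE disutilities on. For
  scenario 3, per-cycle probabilities beyond month 60 continue at the
  last interval's constant monthly rate, and utilities and follow-up
  costs continue at their final values — the mortality crossover then
  compounds for 15 further years, which is what turns TAVI dominated.

The scenario 1/2 milestone files and the AE disutility table are
**synthetic reconstructions** (`*_synthetic.yaml`): the exact tables
used originally are not published in accessible form, so they are
rebuilt from the source trials' published outcomes plus the anchor
values quoted alongside the original scenario results. Scenario outputs
should be read as reconstructions of the analysis design, not verbatim
reproductions.

## Synthetic data generator

`synthetic_cohort_spec()` defines two-arm cohorts with known
piecewise-constant monthly hazards; `generate_milestone_table()` reads
the exact survival function $1 - e^{-\Lambda(t)}$ at the milestone grid,
or the empirical cumulative incidence of a simulated finite cohort
(inverse-transform piecewise-exponential event times) when a KM cohort
size is given. `make_synthetic_model_spec()` assembles a fully valid
model spec usable by every downstream module, which supports end-to-end
recovery tests: constant hazards must come back as constant per-cycle
probabilities to $10^{-6}$ and life-years must match the geometric
closed form.

The noise model is binomial sampling at milestone times only — there is
no censoring process, because the emulated inputs are digitised
milestone probabilities, not patient-level event times. Passing tests on
synthetic cohorts therefore validate the transition calculus and engine
arithmetic, not robustness to censoring or digitisation error in real
KM curves.

## Numerical choices and degenerate inputs

* Milestone round-trip tolerance $10^{-9}$; mixture conservation
  $10^{-12}$; closed-form recovery $10^{-6}$.
* Cumulative incidence reaching 1 mid-horizon: later intervals emit
  probability 0 (the cohort is already extinct for that event).
* Beta sampling at mean 0 or 1 is skipped (the value is kept);
  infeasible beta moments are an explicit error, never clamped.
* PSA cost draws may fall outside the printed 95% CI; the perturbed
  spec drops the CI fields (which encode second-order uncertainty, not
  bounds), while user-supplied specs keep strict CI validation.
* Tie-break order within a cycle is AEs → stroke → death; reversing
  AE/stroke order would change nothing (AEs are state-independent), and
  placing death first would only relabel the forfeiture convention.

## Verification and validation

The test suite asserts, among others: trace occupancies summing to one
with non-decreasing death occupancy; exact milestone round trips for
every bundled table; mixture conservation; microsimulation convergence
to the cohort expectation; OWSA-at-base identity; CEAC monotonicity; and
the degenerate-SD PSA collapsing exactly to the deterministic base case.
`scripts/acceptance.R` recomputes the headline quantities (per-arm
discounted costs, incremental QALYs, ICER, mortality crossover) from the
bundled inputs at run time.

Problem sizes follow the original analysis settings: 10,000 first-order
iterations, 5,000 second-order draws, seed 1.

Against the published results, the reconstruction reproduces the
mortality crossover exactly (cycle 45, 3.75 years), per-arm discounted
costs within a few percent, and the incremental QALY gain within its
reported precision, while the ICER and INB land roughly 15% above and
below their published values respectively. The residual discrepancy is
itemised as follows, in decreasing order of importance:

1. **Milestone granularity.** The original model consumed full
   WebPlotDigitizer-extracted monthly KM curves for mortality and
   stroke; this package — deliberately — takes only the four printed
   milestone values per arm. The between-arm survival gap at
   sub-milestone resolution (surgical mortality and disability are
   front-loaded in ways four points cannot encode) is the main source of
   the smaller QALY gain here, and no bridging rule can recover it.
2. **PAR prevalence costing.** Costing only positive prevalence
   increments yields ~8.3% cumulative costed PAR incidence in the TAVI
   arm; treatments of the decreasing prevalence column that re-cost each
   readout would roughly double the TAVI-side PAR cost and close most of
   the incremental-cost gap. The positive-increment rule is kept because
   it is the only reading consistent with one-time costs at incidence.
3. **AE cost timing and repeats.** AE probabilities apply to everyone
   alive, so high-incidence events (e.g. surgical bleeding) can recur;
   together with the no-half-cycle-correction default this perturbs both
   arms' AE totals by a few hundred dollars.

## Limitations

Beyond the residual discrepancies above: the stroke-mortality hazard
ratios come from higher-risk populations than the modelled cohort; the
stroke and no-stroke states share utilities in the base case; scenario
1/2 inputs are reconstructions; and the 20-year scenario extrapolates a
five-year trial threefold, so only its qualitative conclusion
(dominance) is meaningful. Currency is 2020 US$ throughout; the S$
conversion (×1.32) is a reporting convenience only, and no inflation
adjustment is applied.
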