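---
title: "Methods: partitioned survival cost-effectiveness analysis from published curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned survival cost-effectiveness analysis from published curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

# The decision problem

`psmcea` evaluates a new oncology treatment against a comparator when only
published evidence is available: Kaplan–Meier figures for overall survival
(OS) and progression-free survival (PFS), numbers-at-risk tables, and
summary cost and utility inputs. The motivating application is sacituzumab
govitecan (SG, an antibody–drug conjugate dosed at 10 mg/kg IV on days 1
and 8 of a 21-day cycle) versus single-agent chemotherapy of the
physician's choice (TPC: eribulin, vinorelbine, capecitabine, or
gemcitabine) in metastatic triple-negative breast cancer, assessed from a
national-payer perspective with a willingness-to-pay (WTP) threshold of
USD 102,120 per QALY.

# Model structure

## Partitioned survival

The economic model is a three-state partitioned survival model (PSM):
progression-free (PFS), progressed disease (PD), and dead. Unlike a Markov
model, the PSM needs no transition probabilities; state occupancy is read
directly off the two survival curves at each cycle:

$$\text{pfs}(t) = \min\{S_{PFS}(t), S_{OS}(t)\}, \qquad
  \text{pd}(t) = S_{OS}(t) - \text{pfs}(t), \qquad
  \text{dead}(t) = 1 - S_{OS}(t).$$

The `min` clamp handles digitized curves that cross (estimated
$S_{PFS} > S_{OS}$ is possible with noisy curves even though it is
impossible at the subject level); it guarantees non-negative occupancies
that sum to one exactly, which `occupancy()` preserves to machine
precision and the tests assert at 1e-12.

## Cycles, horizon, discounting

The base settings are a 1-month cycle over a 10-year (120-month) horizon
with costs and QALYs discounted at 3% per year,
$d(t) = (1 + 0.03)^{-t/12}$. Occupancy is evaluated at cycle *midpoints*
by default (`half_cycle_correction = TRUE`). The source analysis does not
state its within-cycle convention; midpoint evaluation is standard PSM
practice because it approximates the continuous-time integral with
second-order accuracy — on exponential test curves the discrete accrual
agrees with numerical integration on a 1000× finer grid to well under 1%,
which the test suite checks. Cycle-end evaluation is available by turning
the flag off.

## Accrual

Per cycle, with $u_{PFS}$, $u_{PD}$ the state utilities and cycle length
$c$ months:

* cost $= [\text{pfs}\cdot(\text{drug} + \text{administration} +
  \text{assessment}) + \text{pd}\cdot \text{pd\_cost}]\cdot d(t)$,
* QALY $= [\text{pfs}\cdot u_{PFS} + \text{pd}\cdot u_{PD}]\cdot
  (c/12)\cdot d(t)$.

Drug acquisition cost accrues while progression-free — the source costing
assigns drug cost to the PFS state and no separate time-on-treatment curve
is modelled. Grade ≥ 3 adverse events enter once, in cycle 1, weighted by
an incidence fraction: a one-off cost and a one-off utility decrement
(default 0.28) applied over the first cycle's duration, i.e.
$0.28 \times c/12 \times \text{incidence}$ QALYs. Incidence fractions are
configuration inputs; when AE burden is specified without an incidence the
whole cohort (1.0) is assumed and a warning is emitted, since that choice
materially overstates AE burden.

## Dosing and drug cost

Doses are computed from a patient profile (defaults: 57.3 kg body weight,
1.72 m² body surface area, reflecting the modelled female population) as
exact milligrams — no vial rounding, as no vial data are modelled.
A regimen's cost per model cycle is
`mg × unit price × administrations × (cycle days / regimen cycle days)`
with 30.4375 days per model month (365.25/12). Where a drug's labelled
dose is a range (capecitabine 1000–1250 mg/m², gemcitabine 800–1200
mg/m²), the configured midpoint is the intended default. Utilities default
to 0.85 (SG, PFS), 0.58 (TPC, PFS) and 0.52 (PD) in the shipped example
configurations.

# Curve reconstruction

`reconstruct_ipd()` inverts the product-limit estimator: within each
interval of the numbers-at-risk table it chooses event counts at the
digitized click times and uniformly spaced censoring times so that (a) the
KM estimate of the reconstructed records passes through the digitized
points and (b) the implied number at risk matches the published table at
the next interval boundary, iterating on the censoring count until both
hold. Design choices the published algorithm leaves open:

* **Deterministic allocation.** Events are placed at the click times and
  censorings on a uniform grid; no random allocation, so reconstruction is
  exactly reproducible. Rounding ties resolve toward earlier event
  placement.
* **Digitization repair.** Real click data are noisy, and the inversion
  needs a valid survival function, so `clean_digitized_curve()` sorts,
  deduplicates (keeping the lower survival at a duplicated time), clamps
  to [0, 1], replaces local increases by the running minimum, and anchors
  the curve at (0, 1).
* **Interpolation.** A risk-table time falling between clicks gets its
  survival by log-linear interpolation — consistent with
  piecewise-exponential behaviour between clicks; the curve extends flat
  beyond the last click.
* **Noise tolerance.** Click noise can make the curve and the risk table
  mildly contradictory (a few more implied events than the at-risk counts
  admit). Small excesses — up to the larger of 3 subjects or 10% of the
  interval's starting at-risk count — are absorbed by dropping the latest
  in-interval events; larger contradictions raise an error naming the
  offending interval, since they indicate mis-digitized inputs rather
  than noise.
* **Tail handling.** Everyone still at risk at the last risk-table time is
  censored there; reconstructed records never extend beyond the table.
  The published total event count can optionally be enforced
  (`total_events`), implemented as a deterministic flip of the latest
  censored/event records; it is off by default because the source analysis
  does not report using it.
* **Ties.** Events precede censorings at equal times — the standard KM
  convention, mirrored by `km_estimate()` (a wrapper around
  `survival::survfit()`).

Round-trip fidelity (reconstruct, re-estimate, compare at every click) is
held to 0.02 absolute survival for a 200-subject arm in the tests.

# Parametric extrapolation

Four two-parameter families are fitted to the reconstructed records by
censored maximum likelihood,
$\ell = \sum_{\text{events}} \log f(t) + \sum_{\text{censored}} \log S(t)$:
Weibull, gamma and log-logistic in shape–scale form
($S_{\text{wei}}(t) = e^{-(t/\sigma)^k}$,
$S_{\text{llog}}(t) = 1/(1 + (t/\sigma)^k)$, gamma via the regularized
upper incomplete gamma) and the lognormal as meanlog–sdlog. The source
names the families only; the parameterizations are fixed here and reported
in every output.

Optimization runs on log-transformed parameters (positivity by
construction) with quasi-Newton BFGS from method-of-moments / log-scale
starting values, relative tolerance 1e-8 on the objective, and a
Nelder–Mead fallback; non-convergence is an error, never silent. At least
two events are required — all-censored data leave a two-parameter family
unidentifiable. The test suite verifies closed-form agreement on
exponential data (the closed-form check uses n = 20,000 so sampling noise
in the free shape cannot mask optimizer error), parameter recovery within
10% under 20% censoring at n = 1000, local optimality under ±1%
perturbations, and agreement with an independent implementation
(`flexsurv`) where available.

Model selection minimizes AIC (default) or BIC; both are always reported,
and ties break in the fixed order weibull < gamma < lognormal <
log-logistic. Because the source combined statistical criteria with a
clinical plausibility judgement, the configured `forced_family` can
override the criterion per arm and endpoint.

# Decision metrics

With intervention totals $(C_1, E_1)$ and comparator totals $(C_0, E_0)$:
$\Delta C = C_1 - C_0$, $\Delta E = E_1 - E_0$,
$\text{ICER} = \Delta C / \Delta E$ when $\Delta E > 0$, and
$\text{NMB} = \lambda E - C$ at threshold $\lambda$, so the incremental
NMB is positive exactly when the ICER is below $\lambda$. Dominance
conventions are stated explicitly because probabilistic draws land in all
four quadrants of the cost-effectiveness plane: "dominant" (cheaper, more
effective), "dominated" (costlier, less effective), an explicit undefined
status at $\Delta E = 0$, and a flagged ratio in the south-west quadrant.
Published NMB columns in the motivating analysis are not reproducible from
its stated threshold; the package always computes NMB from the definition
above. Report rounding is whole USD for money and two decimals for QALYs.
Foreign thresholds convert at `amount / (units per USD)`, rounded to whole
USD.

# Sensitivity and scenario analysis

* **One-way (tornado).** Each parameter alone moves to 0.7× and 1.3× of
  base (utilities additionally capped at 1), the full model re-runs, and
  entries sort by the induced ICER range. Because a PFS-state unit cost
  enters $\Delta C$ linearly, the ICER is affine in it — a property the
  tests exploit as an oracle.
* **Probabilistic.** 1000 Monte-Carlo draws by default: costs from gamma
  distributions and utilities from beta distributions, moment-matched to
  mean = base value with SD = 25% of the mean for costs and 10% for
  utilities. These dispersions are not stated in the source; they are
  common practice defaults and are exposed in the configuration. An
  infeasible beta SD (only possible for means near 0 or 1) is shrunk into
  the feasible region. Draws are independent — the source gives no
  correlation structure — and survival parameters are held at their point
  estimates, since the source lists sampling distributions for costs and
  utilities only. The CEAC reports, on a WTP grid from 0 to 200,000 by
  2,000, the fraction of draws with positive incremental NMB; occupancy is
  computed once and reused across draws, which is exact under
  cost/utility-only sampling.
* **Scenarios.** Price reductions multiply the intervention drug's unit
  price only (other direct medical costs unchanged); threshold scenarios
  replace the WTP value (explicit values, not percentage labels, because
  published percentage labels are ambiguous); subgroup scenarios pass a
  different input bundle.

Determinism: the PSA is bit-reproducible under its seed, and `run_all()`
regenerates every output file identically from (configuration, seed).

# The synthetic trial generator

`simulate_trial()` draws, per subject, a death time and a latent
progression time from configurable parametric families and sets observed
PFS to min(progression, death), so PFS ≤ OS holds at the subject level by
construction — the same coupling that justifies the PSM's clamp. Subjects
accrue uniformly over an accrual window and are censored administratively
at the follow-up cut-off; a PFS record is censored whenever follow-up ends
before both progression and death. `emulate_digitization()` samples the KM
step function at survival-quantile-spaced times (clicks cluster where the
curve drops, as a careful digitizer's do) and adds truncated-normal click
noise (truncated at 2 SD) before the standard cleaning.
`make_risk_table()` counts subjects still under observation at the report
times.

The shipped study conditions use Weibull arms with shape 1.2 and medians
of 14/6 months (OS/PFS, intervention) versus 7/3 months (comparator),
n = 200 per arm, 10 months' accrual, 36 months' follow-up — trial-like
magnitudes for this disease setting; no published arm medians exist to
copy, so these are the package's own defaults and are fully configurable.
What passing tests on such data do **not** show: real digitized curves
carry correlated (not independent) click noise, published risk tables can
disagree with the figure, and real extrapolation error is structural
(wrong family) rather than sampling noise — the generator covers none of
these, which is why the reconstruction tolerances above are deliberately
loose relative to the generator's own noise level.

At these desk-scale effect sizes (a fraction of a QALY gained rather than
several), absolute ICERs are necessarily much larger than in the
motivating analysis, whose QALY totals rest on digitized trial curves and
long extrapolated tails. The acceptance script therefore reports, besides
the fixed published-table arithmetic, scale-free quantities of the
synthetic study: reconstruction error, estimator recovery, conservation
error, the tornado rank of the drug cost, and the drug-price multiplier at
which the ICER crosses the threshold (with the PSA probability at that
price, which sits near 50% by construction of the crossing).

# Problem sizes and numerical choices

The test suite uses n = 200–1000 subjects for reconstruction and recovery
checks, 20 seeds for the end-to-end recovery property, 200 replicates for
the AIC selection-consistency check, and 300–1000 PSA draws; the
acceptance script uses 200 subjects per arm and 1000 draws. These sizes
keep the whole suite under a minute while leaving comfortable margins on
every tolerance. Other numerical conventions: survival values are clamped
to [0, 1] before partitioning; the median is the smallest time with
S(t) ≤ 0.5 (`NA` when not reached); zero-valued costs are left degenerate
by the gamma sampler, and utilities of exactly 0 or 1 by the beta sampler.

# Known limitations

* No spline/cure/piecewise-hazard extrapolation and no covariate
  adjustment; the four standard families only.
* Two-strategy comparisons; no efficiency frontier over three or more
  strategies, no EVPI.
* No explicit time-on-treatment curve; drug cost follows the PFS state.
* Survival-curve uncertainty is excluded from the PSA by default (see
  above); parameter-level multivariate sampling of the fitted survival
  models is a natural extension but is not implemented.
* The PSM itself assumes the published curves adequately represent the
  target population; no calibration beyond curve fit is attempted.
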