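---
title: "Methods: the waitcea cost-utility model"
author: "waitcea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the waitcea cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waitcea)
```

# The decision problem

`waitcea` values a programme that moves elective-surgery patients from a
delayed (or missed, or fatal) pathway to an earlier one. The model is
deliberately incremental: it never attempts absolute lifetime QALYs or
total programme costs, only the *difference* between the early-surgery
arm and its counterfactual. That choice is what makes the model viable
in data-limited settings — each subgroup needs only a handful of
utilities, four event times, and six per-patient cost amounts.

# Model structure and assumptions

Each cohort (one surgical intervention) contains up to three subgroups,
one per counterfactual pathway:

* **reduced waiting time (RWT)** — surgery happens in both arms, earlier
  in one. Three segments contribute incremental QALYs: the waiting-time
  gap (weighted by `u_post_early - u_wait`; pre-operative stress is
  folded into `u_wait`), the residual post-operative difference
  (`u_post_early - u_post_delayed`) until the counterfactual death, and
  the survival gap (full `u_post_early`).
* **avoided missed surgery (AMS)** — the counterfactual patient lives
  unoperated at `u_missed`. Structurally this is the RWT model with the
  post-surgery segment empty, a collapse the test-suite verifies on
  randomized sweeps.
* **mortality averted (MA)** — the counterfactual patient dies at the
  scheduled early-surgery date (an approximation that avoids needing a
  separate time-of-death input). Only the survival-gap segment remains.

Assumptions worth making explicit:

* **Utilities are flat within segments.** No within-segment trajectory,
  ageing decrement or half-cycle correction is modelled; QALYs are exact
  areas under piecewise-constant curves.
* **The survival-gap segment uses `u_post_early`.** A distinct
  end-of-life utility would be defensible; the post-operative utility
  was chosen because the gap years are lived by the early-surgery
  patient in the post-operative state. A different choice can be
  emulated by splitting a cohort into subgroups.
* **One timeline per subgroup.** Age stratification within a subgroup is
  a deliberate simplification; finer strata can be expressed as
  additional cohorts.
* **Negative incremental QALYs propagate.** Adaptations may encode
  harms; downstream outcomes carry dominance flags rather than refusing
  such inputs.

# Discounting

Both QALYs and costs are discounted at an annual rate (default 0.035 per
year, configurable per run). Exposure is discounted in continuous time,
$\int_{t_0}^{t_1} (1+r)^{-t}\,dt$, evaluated in closed form. The
alternative — discrete annual cycles — was rejected because segment
boundaries are arbitrary non-integer years and a single canonical
semantics keeps results reproducible; the closed form is audited against
adaptive quadrature in the tests (agreement to 1e-8 relative). Costs are
episodic lump sums discounted from explicit incurrence times, not
continuous flows: surgical costs are paid around the surgery, and the
incurrence times are first-class inputs, so either a
"discount-from-launch" or a "discount-from-surgery-date" convention is
expressible in the configuration.

# Costs and perspectives

Each of the three cost components (direct medical, patient productivity,
caregiver productivity) contributes
`discounted(early amount) - discounted(counterfactual amount)`, so
savings are negative. Productivity losses enter as pre-monetised
human-capital amounts per patient rather than wage-by-duration
calculations — keeping them as inputs preserves adaptability across
labour markets. Scenario handling of the counterfactual arm: AMS
defaults its counterfactual direct surgical cost to 0 at load time (no
surgery happens) but the field is overridable, e.g. for ongoing
palliative care; MA zeroes every counterfactual component (the
counterfactual patient is dead). The societal perspective sums all three
components; the payer perspective is the direct component alone.

# Outcomes and conventions

ICERs are ratios of *population sums*, never averages of per-cohort
ratios. Degenerate denominators are encoded as markers (`dominant`,
`dominated`, `undefined`) rather than exceptions. The benefit-cost ratio
keeps the plain signed ratio plus a `cost_saving` flag when the
denominator is negative, so both the ratio and the dominance fact stay
representable. Cost-effectiveness against the willingness-to-pay
threshold uses `ICER <= WTP` (boundary equality counts) on the societal
perspective, or dominance. Net monetary benefit
(`ΔQALY × WTP - Δcost`) is computed as an auxiliary column because it
remains stable when the QALY increment is near zero; it is not a
headline outcome. ICERs are held unrounded internally and rounded to
whole currency units only for display.

# Catastrophic health expenditure

The budget-share method classifies an out-of-pocket payment as
catastrophic when it *strictly exceeds* a threshold share (10% or 25%;
25% is the base case) of the household's total expenditure. The strict
boundary follows the ordinary reading of "exceeding" and is fixed so
results are bit-reproducible: for a price of 5,000 at the 25% share, a
household spending exactly 20,000 a year is at, not over, the line, so
in the three-household example {10,000; 20,000; 40,000} exactly one
household (1/3) faces CHE. Expenditure distributions may be empirical
(exact counting below the cutoff `oop/threshold`) or lognormal (CDF at
the cutoff); the two agree within 0.01 at 10^5 households in the tests.
The normative and partial-normative CHE variants (which deduct
subsistence spending) are recognised extension points and deliberately
not implemented: the budget-share method is the SDG-monitoring standard
and the variants have no single canonical definition.

# Sensitivity analyses

**One-way (tornado).** Every addressable parameter is varied to
`mean × (1 ± δ)` (default δ = 0.10) with the rest at base case, the full
pipeline is re-evaluated, and entries are ranked by the width of the
composite societal ICER interval. Perturbations that would break a
structural invariant are flagged infeasible, never clamped — silent
clamping would misreport the perturbation actually evaluated.

**Probabilistic.** Distributions follow the standard assignment rule —
beta for utilities, normal for time variables, gamma for costs —
parameterised from mean and standard error by the method of moments.
When no spread is supplied the default standard error is 10% of the
mean, mirroring the one-way band; a zero mean or zero spread degrades
gracefully to a point mass. Sampling is independent across parameters
(no correlation structure is specified or modelled), 5000 draws by
default, fully determined by an explicit seed.

**Why time uncertainty is sampled on durations.** Sampling absolute
event times independently makes order violations *structural*: if the
counterfactual and early deaths coincide at base case (a cohort with no
mortality effect), independent normal draws invert their order on half
of all draws, and no rejection-sampling scheme survives that. The
package therefore parameterises time uncertainty on `t_early` plus three
non-negative durations — `wait_duration`, `post_delayed_duration`,
`survival_gap` — from which the absolute times are rebuilt in order.
Zero durations (no post-operative difference, no survival gap) then stay
exactly zero under sampling, which is the structurally faithful reading
of those inputs. Absolute timeline fields remain addressable for
explicit use; draws that still violate an ordering (possible with
explicit absolute sampling or extreme spreads) are rejected and redrawn
with a logged count, and the analysis aborts with a diagnostic naming
the worst parameter if more than half of all sampled draws are
infeasible. PSA summaries are reported as draw-level
(ΔQALY, Δcost) pairs, their means, the ratio-of-means ICER and the
cost-effective fraction — never as a mean of per-draw ICERs, which is
unstable near ΔQALY = 0.

# Synthetic fixtures and calibration

The `egypt_like` fixture encodes five illustrative cohorts (open-heart
surgery, cardiac catheterization, cochlear implantation, retinal
surgery, joint replacement) whose *qualitative* pattern matches the
published national experience: cochlear implantation societally dominant
(large productivity savings from early childhood implantation), retinal
surgery above the threshold (small survival and productivity impact),
cardiac cohorts comfortably below it. Its numeric values are invented
illustrations chosen once for clinical plausibility — they are not
recovered national data, which live in unpublished appendices. The
`randomized` profile draws valid parameters uniformly within documented
ranges (utilities 0.2–0.95, waits 0.1–3 years, survival horizons 5–40
years, costs 10^4–10^6 currency units), rounded to four decimals so
configurations round-trip bit-exactly through YAML.

The calibrated fixture rescales all patient counts by a common factor
(QALYs are linear in counts) to hit a target QALY total, then solves a
one-dimensional adjustment of a single direct-cost knob to hit a target
societal cost total; the result is re-verified through the full pipeline
to 0.01% relative. This minimal two-knob calibration was chosen over
inverse-solving all parameters precisely to avoid implying that the
underlying per-surgery inputs have been recovered. With the published
aggregates (48,385 QALYs; 2,264,156,090 societal cost) the composite
societal ICER evaluates to 46,795 per QALY. The payer-side aggregate is
*not* calibrated — only its structure is exercised — because the
published payer figure cannot be reconstructed from headline aggregates
alone.

What passing tests on these fixtures do **not** show: that the model's
inputs for any real programme are right. The fixtures exercise the
arithmetic, invariants and conventions; real data features such as
correlated parameters, age-varying utilities, non-lognormal expenditure
tails and within-cohort heterogeneity are exactly what the fixtures do
not contain.

# Numerical choices

* Discounted exposure and lump-sum discounting are closed-form; the
  independent oracles (adaptive quadrature; fine-grid midpoint Riemann
  integration at Δt = 1e-3 to 1e-4 years) live in the test suite, with
  tolerances 1e-8 and 1e-5 relative respectively.
* Segment totals accumulate left-associatively so the deterministic
  pipeline and the vectorised PSA evaluator agree bit-for-bit; a
  degenerate (all-spreads-zero) PSA reproduces the base case exactly.
* Beta moment-matching requires `spread² < mean(1-mean)` and a mean
  strictly inside (0,1); infeasible moments are a named validation
  error, not a silent truncation.
* Ties: `t_death_counterfactual` is pinned to `t_early` in the MA
  scenario, and the unused `t_delayed` tracks `t_death_counterfactual`
  in AMS; setting either mover updates its tied field.
* Degenerate inputs (zero patients, zero rate, empty intervals, zero
  QALY increments) all take well-defined values (zero totals, plain
  durations, undefined-ICER markers) rather than erroring.

# Problem sizes in the shipped tests

The suite verifies the oracle equivalences on 1000 randomized parameter
draws per scenario, the structural collapses on 300-draw sweeps, PSA
behaviour at 5000 draws, CHE estimator agreement at 10^5 households, and
fixture validity over 100 randomized configurations — sizes chosen to
make Monte-Carlo tolerances (3 standard errors) meaningfully tight while
keeping a full test run in the tens of seconds.

# Known limitations

* No friction-cost productivity method, no recurring within-horizon cost
  streams, no parametric survival curves, no correlated PSA sampling, no
  expected-value-of-perfect-information analysis.
* The CHE module measures exposure only: no impoverishment analysis and
  no capacity-to-pay subsistence deduction.
* Counts are treated as fixed population weights (not sampled) unless a
  distribution is explicitly assigned to them.
* Only two-arm (before/after) comparisons are supported; multi-programme
  incremental analysis is out of scope.
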