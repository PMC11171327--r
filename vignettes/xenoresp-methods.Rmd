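---
title: "Methods: xenograft response evaluation with xenoresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: xenograft response evaluation with xenoresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoresp)
```

# The measurement model

A xenograft efficacy study enrolls a mouse once its implanted tumor reaches
a measurable size (at least 100 mm³), treats from day 0, and measures tumor
volume weekly with calipers until the tumor reaches 400% of its day-0
volume, at which point that animal's study ends. Everything downstream —
event-free survival (EFS), response category, activity calls — derives from
these short, truncated volume series.

Two conventions run through the package:

* **Day 0 is treatment start.** Pre-enrollment growth is neither measured
  nor modeled.
* **Volume 0 means unmeasurable.** A recorded 0 is not a numerical zero but
  "no tumor could be measured". The threshold separating measurable from
  unmeasurable is the `measurable_min` argument of `classify_animal()`,
  default 0 (only an exact 0 counts as disappeared). The study protocol
  never defines a detection limit, so the package does not invent one; a
  user with a known caliper floor can set it.

# Time to event

The event is a quadrupling: `V(t) >= 4 V0`. Tumor growth between adjacent
weekly readings is treated as exponential (log-linear), so when readings
`V_{i-1} < 4V0 <= V_i` bracket the threshold, `event_time()` solves the
exponential through the two points:

$$t_{event} = t_{i-1} + (t_i - t_{i-1})
  \frac{\ln(4V_0/V_{i-1})}{\ln(V_i/V_{i-1})}.$$

Choices worth stating:

* **First crossing wins.** The search stops at the first reading at or above
  the threshold; later regressions cannot rescind the event. This is the
  usual time-to-event semantics, and the simulator's truncation rule means
  post-event readings should not exist anyway.
* **Exact hits.** If a reading equals the threshold exactly, its day is the
  event time; no interpolation.
* **Regrowth from zero.** A tumor recorded as 0 that later crosses the
  threshold would put a zero in the logarithm. The preceding anchor is then
  replaced by a floor volume (`floor_volume`, default 1 mm³). The choice is
  conservative — it moves the interpolated event slightly earlier than any
  positive true volume would — and only affects trajectories that regrew
  from complete regression, where the exact event day is least meaningful.
* **Censoring.** Animals that never quadruple are censored at their last
  observed day. No extrapolation beyond the data: the growth-rate
  extrapolation used at study termination applies to the bracketed-crossing
  case, which the interpolation formula already covers.

A useful invariant (tested): on noise-free exponential growth at rate *k*
the interpolation is exact, returning ln(4)/k to machine precision whenever
a bracketing pair exists, for any measurement grid. Scaling all volumes by a
positive constant leaves the event time unchanged, since the threshold
scales with baseline.

# Response classification

Per animal, with `r = V_t / V0`, evaluated with precedence
MCR > CR > PR > SD > PD:

| Category | Rule |
|---|---|
| MCR | ≥3 consecutive unmeasurable readings, all after treatment ends |
| CR  | ≥2 unmeasurable readings (consecutive or intermittent), MCR not met |
| PR  | min r ≤ 0.5, CR/MCR not met |
| SD  | min r > 0.5 and final r ≤ 1.25 |
| PD  | min r > 0.5 and final r > 1.25 |

Three genuinely open points were resolved as follows:

* **The CR plurality clause.** The rule text ("up to two times consecutively
  or intermittently any number of times") is read as requiring at least two
  unmeasurable readings in total. A single isolated unmeasurable reading is
  not a CR; under precedence it falls to PR, which is coherent: a
  disappeared tumor is a ≥50% regression at that reading. This also closes
  the gap that a literal reading of the PR clause ("measurable throughout")
  would leave, where a single-zero trajectory satisfies no category at all.
* **MCR run placement.** The ≥3-reading unmeasurable run must lie strictly
  after the treatment-end day (`treatment_end_day`, default day 7: a single
  dose on day 1 plus five daily doses from day 3). Runs that start during
  treatment count toward CR, not MCR — "maintained" refers to response
  persisting off treatment.
* **End of study.** The SD/PD growth test uses the animal's own last
  reading, which for early-terminated (quadrupled) animals is the
  termination reading. Those animals are PD by construction unless they
  regressed ≥50% earlier, which is the intended semantics.

Group calls take the median of per-animal ordinals (PD=0 … MCR=4), rounding
half-integers *down*, toward the worse category. Median is the convention in
preclinical testing consortia reporting one call per model/arm; pessimistic
rounding avoids claiming a response class that half the animals did not
reach. Objective response means PR or better, and the count of objective
responders across models is the headline activity number.

# Event-free survival statistics

`km_fit()` is the product-limit estimator written out directly: at each
distinct event time, multiply by (1 − d/n). Censored records reduce the risk
set only; censorings tied with an event are taken to occur just after it
(the standard convention, so the censored animal is still at risk at that
time). Median EFS is the smallest time with S(t) ≤ 0.5 — the left endpoint
when S sits exactly at 0.5 over a flat step — and "not reached" (`NA`) when
S never gets there, as happens for a treated arm whose animals are all
censored at the horizon.

`logrank()` is the two-group score test: summed observed-minus-expected
events in one group over distinct event times, with the hypergeometric
variance, referred to chi-square on 1 df (two-sided). Ties are handled by
the simultaneous-event convention. Computed p-values are floored at 1e-16
and flagged, rather than printed as 0.

The test suite checks `km_fit()` exhaustively against a brute-force product
over risk sets for every event/censor pattern up to n = 8, and checks
`logrank()` against an independent implementation on random inputs. One
calibration caveat belongs here because the tests surface it: with 10
animals per arm and every animal an event, the asymptotic chi-square
reference is slightly anti-conservative — the true null rejection rate at
nominal α = 0.05 is about 0.066, and an independent implementation of the
same statistic reproduces that rate exactly. At typical xenograft arm sizes,
log-rank p-values near the significance boundary deserve skepticism; the
headline comparisons in studies of this design are orders of magnitude below
it, where the issue is immaterial.

# Dose-response fitting and potentiation

`fit_4pl()` fits `y = bottom + (top − bottom)/(1 + (c/IC50)^h)` by bounded
least squares (L-BFGS-B) over (top, bottom, log IC50, log h). Numerical
choices:

* **Initialization.** top/bottom start at the max/min of dose-averaged
  signals; IC50 starts at the log-linear interpolation of the dose pair
  bracketing the half-maximal signal; the Hill slope is multi-started over
  {0.5, 1, 2}, keeping the best residual sum of squares, which guards
  against the h–IC50 trade-off on sparse dose grids.
* **Constraints.** bottom ≥ 0, h ∈ (0.1, 10], IC50 within 10⁴× of the dose
  range. A fit ending on a bound, or flat input data, returns
  `converged = FALSE` (with `ic50 = NA` for flat data) instead of raising.
* **Zero doses.** Wells at concentration 0 predict the top asymptote (the
  power term vanishes) and participate in the residuals; they anchor `top`
  without entering any logarithm.
* At least 4 distinct positive concentrations are required.

Potentiation is deliberately simple: the ratio of fitted IC50s,
single-agent over combination (`potentiation_fold()`), or combination over
combination-plus-modulator (`potentiation_with_modulator()`, e.g. adding an
MGMT inhibitor to an already-sensitized combination). No synergy index is
computed — fold-shift of the IC50 at a fixed sensitizer concentration is the
quantity the assay design supports. The fold inherits scale equivariance
from the fit: rescaling concentrations rescales IC50s, rescaling signals on
both plates cancels.

# Biomarker-response correlation

For correlating a biomarker (say, normalized MGMT band intensity) with
in vivo response, categories are re-coded 1 = MCR … 5 = PD — so a *positive*
correlation means higher expression, worse response — and Pearson's r is
computed treating the rank as numeric, with the two-sided p from
t = r√(n−2)/√(1−r²) on n−2 df and a Fisher-z 95% CI. Treating a 5-level
ordinal as numeric is a modeling choice inherited from practice; Spearman's
rho is reported alongside as the rank-safe companion, and the two disagree
only when the expression-rank relation is markedly non-linear. For
published coefficients, `pearson_p_from_r()` recomputes the implied p: at
r = 0.88, n = 6 it gives 0.0207 two-sided (0.0104 one-sided) — handy when a
printed p-value does not state its convention. The permutation null at
n = 6 has only 720 orderings, so t-based and permutation p agree only up to
that granularity; the tests allow for it.

# RNA-seq utilities

Xenograft RNA is a graft/host mixture, so quantification starts by
assigning each read pair aligned to both the human and mouse genomes to
human-only / mouse-only / common / unaligned. With both genomes aligned,
the comparison is lexicographic on mate-summed metrics: alignment score
(higher), then mismatches (fewer), then matched length (longer); ties on
all three are `common`. The score tolerance defaults to 0 — only exact ties
are `common` — and is configurable, since the grouping criteria come with
no published thresholds. Quantification retains human-only ∪ common,
discarding host contamination.

FPKM is the unit construction `counts · 10⁹ / (length_bp · total_reads)`.
The differential-expression *filter* — up if log2FC > 1, mean FPKM > 1 and
BH-adjusted p < 0.05; down symmetrically; all inequalities strict — is
implemented over any per-gene statistics table. The differential test
itself (negative-binomial modeling à la DESeq) is out of scope on purpose:
the filter criteria are the portable contribution, and they compose with
any upstream test. BH adjustment delegates to `stats::p.adjust` and is
verified against the brute-force step-up definition in the tests.

# The synthetic-data generator

`simulate_trajectory()` draws from a piecewise-exponential model: regression
at `k_regress ≤ 0` for `effect_days`, then regrowth at `k_regrow`; controls
(`effect_days = 0`) grow at `k_control` throughout. Measured volumes are the
model volume times lognormal noise (log-sd = `cv_noise`, median 1 —
multiplicative, because caliper error scales with tumor size), truncated at
the first reading ≥ 4× baseline, with model volumes below `detect_floor`
(default 1 mm³) recorded as exactly 0. Sub-seeds for cohort animals derive
from the master seed by a fixed stride-97 counter, so cohorts are
reproducible and any single animal can be regenerated in isolation.

Defaults mirror the study design the package targets: enrollment at
≥100 mm³ (the constructor rejects smaller `v0`), weekly measurement, a
~13-week horizon, treatment ending on day 7. The noise default
`cv_noise = 0.15` is a free parameter chosen as a realistic caliper CV; no
measurement-error magnitude is stated in the motivating study.

`archetype_params()` provides one parameter set per response category whose
noise-free trajectory is classified exactly as intended: PD is pure growth;
SD a static tumor; PR regresses to ~25% then regrows; CR is tuned so the
volume sits below the detection floor on exactly two consecutive weekly
readings (days 14 and 21) before regrowing; MCR regresses below floor from
day 21 on. These are recovery fixtures, not biology: the CR/MCR kinetics
were chosen for a clean classification signal, with margins wide enough
that cv = 0.15 noise almost never flips a reading across the detection
floor (measured group-call agreement over noisy cohorts is ≈99–100%).

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: inter-animal growth-rate heterogeneity
(all animals in an arm share kinetics; only measurement noise varies),
dropout for toxicity or ulceration, non-exponential (e.g. Gompertzian)
growth, drug-effect onset delay, and any pharmacokinetics of the slow-release
conjugate. Classifier robustness at cv = 0.15 says the rule set tolerates
caliper noise, not that it resolves biologically borderline SD/PD animals.

# Problem sizes and determinism

The shipped tests and the acceptance script run at the sizes the analyses
are designed for: exhaustive product-limit checks to n = 8 per pattern,
2000-replicate null calibration at 10 animals per arm, 500 simulated
cohorts (10 animals each) for noisy classifier recovery, 500 noisy plates
for IC50 bias, 200 two-plate designs for fold recovery, 10⁴ permutations
for the correlation oracle. Every stochastic step takes an explicit seed;
`run_pipeline()` threads one seed through all stages and reruns are
byte-identical.

# Known limitations

* The classification gap-closure (isolated zero → PR) and the MCR
  run-placement rule are interpretations of prose rules; both are
  configurable only via `measurable_min`, not via alternative rule sets.
* Median EFS has no confidence interval; the package reports the point
  estimate and "not reached".
* `fit_4pl()` reports residual sum of squares but no parameter
  covariance; fold-potentiation consequently carries no standard error.
  Replicate-plate designs are the supported route to uncertainty.
* The log-rank test is asymptotic; see the calibration note above. An exact
  permutation variant is not provided.
* The RNA-seq module consumes alignment *summaries*; it does not parse BAM
  or run aligners.
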