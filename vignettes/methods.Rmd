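---
title: "Model and methods: pre-diabetes screening microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: pre-diabetes screening microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Most pre-diabetes in China is found opportunistically: adults who attend an
annual health examination (about 42%) receive a fasting plasma glucose (FPG)
test, and the rest are not screened at all. FPG is blind to isolated
impaired glucose tolerance (i-IGT) — elevated post-load glucose with normal
fasting glucose — which is the most common pre-diabetes substate. The
Chinese Diabetes Risk Score (CDRS) is a free, non-invasive questionnaire
with much higher pre-diabetes sensitivity but much lower specificity.
`prediabsim` asks: does replacing FPG with CDRS (strategy S1), or adding
self-administered CDRS for the unscreened majority (strategy S2), prevent
enough type 2 diabetes (T2DM) to justify the extra confirmatory testing and
intervention cost?

## Model structure and assumptions

The model is an individual-level (microsimulation) Markov model with annual
cycles and six states: NGT, i-IFG, i-IGT, IFG+IGT, T2DM and death. Key
structural assumptions:

* NGT never progresses directly to T2DM; pre-diabetes may revert to NGT;
  T2DM is absorbing among living states.
* Progression from pre-diabetes to T2DM depends on substate, age band and
  diagnosis status. Diagnosis means twice-yearly lifestyle intervention,
  which roughly halves the annual progression probability for i-IGT and
  IFG+IGT. For i-IFG the diagnosed probabilities in the source data are
  *higher* than the undiagnosed ones (they come from a different cohort);
  the model takes the table at face value, so screening is not uniformly
  beneficial for i-IFG patients.
* A positive first-line test triggers an OGTT, modelled as a perfect gold
  standard that reveals the true state. True pre-diabetes becomes a
  diagnosis; a false-positive NGT returns to the screening pool and may be
  re-screened the next year (no cooldown). Diagnosed people are never
  re-screened; a diagnosed pre-diabetic who reverts to NGT loses the
  diagnosis (intervention stops, screening eligibility returns).
* Within a cycle the order is screen → intervene (cost) → transition →
  die → age. The choice is deliberate: a diagnosis made in year *k* already
  affects the year-*k* transition, the most favourable reading of
  "intervention upon diagnosis". One measurable corner-case consequence:
  with death certain in every cycle (`qx = 1`), the cumulative T2DM
  prevalence equals the initial T2DM fraction *plus one cycle* of
  pre-DM→T2DM inflow, not the initial fraction alone.
* Compliance multiplies only self-administered CDRS among non-exam-goers.
  Exam-based testing always happens, which is the only reading under which
  a compliance collapse leaves exam-based strategies' costs high while
  self-screening costs vanish.
* The exam-goer flag is a lifetime trait, drawn once per person: the
  population is partitioned into with/without-examination groups, not
  re-randomized annually.
* Simulation ends at death or the 80th birthday (the average life
  expectancy used as horizon); survivors exit alive with no terminal costs.
  No half-cycle correction is applied.

## Parameters

Every input lives in a flat registry (`default_params()`), one scalar per
table row, each with a base value, an uncertainty range and a distribution
tag. Highlights, with units:

* Age-banded prevalences of undiagnosed T2DM and the three pre-diabetes
  substates (probabilities; bands `<40`, `40–60`, `>60`).
* Test operating characteristics (probabilities): FPG sensitivity 73.4%
  (T2DM), 46.1% (i-IFG), 69.7% (IFG+IGT); CDRS sensitivity 87.6% (T2DM) and
  73.4% (one common value for all pre-diabetes substates); CDRS
  false-positive rate for NGT 44.7%.
* Annual transition probabilities (per year): NGT→{i-IFG 2.04%, i-IGT
  6.46%, IFG+IGT 2.76%}; substate→T2DM by diagnosis and age band
  (`<40`, `40–50`, `50–60`, `>60`); reversion to NGT 6.9/8.8/5.3%.
  Cumulative multi-year probabilities are converted to annual ones at load
  time via `annual_probability()` (`P = 1 − (1 − P_t)^{1/t}`).
* Unit costs (2021 USD, converted at ¥6.45/$ before entry — the engine never
  sees yuan): FPG $5.49, OGTT $13.36, lifestyle intervention $26.66 per
  session × 2 sessions/yr; CDRS $0.
* Discount rate 5%/yr (costs only; an optional flag also discounts the
  effectiveness outcome, default off, since the source analysis mentions
  discounting only for costs). Willingness-to-pay $12,551 per case
  prevented. Compliance 1.0 in the base case.

Two data-quality decisions were needed. The printed range for the
undiagnosed i-IFG→T2DM probability in the 50–60 band (1.35–2.25%) excludes
its own base value (2.98%); the shipped file keeps the printed low and
extends the high to the base so the `low ≤ base ≤ high` invariant holds.
The CDRS-for-T2DM range printed as "65.7–1.00%" is read as 65.7–100%.
Missing ranges default to 75–125% of base. Age bands are half-open
`[lo, hi)` starting at 18, so a boundary age (40, 50, 60) belongs to the
upper band and a printed "`>60`" band starts at 60 — this keeps every adult
age covered; the source table leaves the boundary ages ambiguous.

Two FPG gaps are filled with configurable defaults: FPG sensitivity for
i-IGT is 0 (fasting glucose cannot detect isolated post-load hyperglycemia)
and the FPG false-positive rate for NGT is 0.10 (consistent with an
approximate 90% specificity). Both carry ranges and enter the sensitivity
analyses.

## Synthetic demography

The published analysis draws its age structure and mortality from national
yearbooks that ship no data files, so the package generates stand-ins:

* **Ages**: a truncated normal on [18, 80), SD 16 years, floored to whole
  years. Truncation and flooring shift a naive mean, so the latent location
  is solved by root-finding at model construction to make the *expected
  sampled integer age* equal 45.70 exactly; the sampled female fraction is
  Bernoulli(0.4892). SD and support are stated model choices (only the mean
  and sex ratio are published); 16 years on [18, 80) is a realistic adult
  spread for China and is exposed as a knob.
* **Mortality**: Gompertz–Makeham, `qx(a, sex) = min(1, c + b_sex e^{θa})`
  with θ = 0.09/yr, Makeham floor c = 5×10⁻⁴/yr, and sex scales solved once
  so life expectancy at birth is 74 y (male) and 80 y (female), bracketing
  the 80-year horizon (frozen: b_male = 5.834×10⁻⁵, b_female = 3.291×10⁻⁵).
  The table closes with `qx(100) = 1`. A real yearbook life table can be
  substituted via `load_life_table()` with no other changes. Mortality is
  period (attained-age) qx; no calendar trend.

What the synthetic world does *not* emulate: the exact Chinese age pyramid
(only its mean), sex-specific age distributions, regional heterogeneity,
and the yearbook's age-by-age mortality profile. A green test therefore
establishes internal correctness (the simulation computes its stated
expectation; orderings and decisions are right) — not numeric reproduction
of published absolute costs and prevalences, which require the external
demographic inputs.

## Cost accounting

The published per-capita control cost ($6.04 over a lifetime of annual FPG
testing) cannot be reproduced under any straightforward accounting of the
listed unit costs, and the source is silent on two points. Both are exposed
as flags (`sim_options()`):

* `treat_exam_fpg_as_sunk` — charge exam-embedded FPG at $0 (the exam
  happens regardless under the status quo). Default `FALSE`: full
  attribution.
* `intervention_years_cap` — charge intervention for at most k years after
  diagnosis. Default `Inf`: charged for every diagnosed pre-diabetic year.

Under the shipped defaults absolute costs are roughly an order of magnitude
above the published scale, but the cost *ordering* (S1 > S2 > control),
the prevalence ordering (S1 < S2 < control) and every cost-effectiveness
verdict at the $12,551 threshold are unaffected, which is what the test
suite asserts.

## Numerical and statistical choices

* **Common random numbers**: all strategies sharing a seed use the identical
  cohort and the identical uniform draw for each (individual, cycle,
  decision channel), so strategy contrasts and one-way/compliance contrasts
  are paired. Implemented as per-(cycle, channel) seeded uniform vectors
  indexed by individual.
* **Confidence intervals**: the cohort is split into 50 equal batches; CIs
  are normal approximations over batch means. ICER CIs are percentile
  intervals of per-batch ICERs over the paired batches (a pragmatic
  alternative to Fieller's method; the source does not state its method).
* **Deterministic oracle**: `expected_occupancy()` runs the exact
  expectation of the same model by forward recursion over (baseline age,
  sex, exam-goer) strata on an 11-compartment space (diagnosis-split living
  states plus dead-with/without-T2DM). It shares parameter lookups with the
  engine but no simulation code path; the acceptance suite requires the
  10⁵-person Monte Carlo run to agree within 4σ binomial bounds, state by
  state, for all three strategies.
* **PSA distributions**: probabilities that come from studies (prevalences,
  sensitivities, transition probabilities) are beta, moment-matched with
  SD = range/3.92 (range read as a 95% interval), which makes every sampled
  mean unbiased for its base value; costs are lognormal, moment-matched on
  the natural scale; the exam proportion, discount rate and the invented
  FPG false-positive default are uniform on their ranges. A uniform on an
  asymmetric range recovers the midpoint, not the base — this is why
  study-derived probabilities with asymmetric ranges (e.g. CDRS sensitivity
  for T2DM, 0.657–1.0 around 0.876) are tagged beta rather than uniform.
  Parameters are sampled independently; joint draws violating a structural
  invariant (outgoing probabilities exceeding 1) are rejected, redrawn and
  counted. Degenerate ranges are tagged `fixed` and not sampled.
* **Perturbation semantics**: `perturb()` changes one scalar, leaves the
  input object untouched, re-validates everything, and widens the stored
  range when the new value falls outside it (needed for scenarios such as
  tripling the OGTT cost).
* **WTP rule**: inclusive (`ICER ≤ WTP`); immaterial at these magnitudes.
  A cheaper-and-more-effective comparator is flagged dominant and counted
  cost-effective; costlier-and-less-effective is dominated; zero prevented
  cases flags the ratio undefined rather than dividing.
* **Reproducibility**: no output depends on wall clock or locale; the
  pipeline writes a manifest (seed, n, parameter-file MD5, version) and
  rerunning a config reproduces artifacts byte-identically. All seeded
  draws restore the caller's RNG state.

## Limitations

* No diabetes-complication states, no QALYs, and no treatment costs after a
  T2DM diagnosis — effectiveness is solely T2DM cases prevented by 80.
* CDRS is modelled only through its operating characteristics; the
  questionnaire itself, its score distribution and threshold mechanics are
  out of scope, as is re-deriving transition probabilities from their
  source cohorts.
* The synthetic demography reproduces two published moments (mean age, sex
  ratio) and a calibrated life expectancy, not the real population
  structure; absolute prevalences shift by a few percentage points under a
  real life table.
* Per-iteration PSA cohorts (default 10⁴, scaled in tests) add Monte Carlo
  noise on top of parameter uncertainty; with ICERs sitting an order of
  magnitude below the threshold, the acceptability conclusions are robust
  to this, but PSA ICER quantiles should not be over-read.
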