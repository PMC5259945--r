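---
title: "Model methods: the linked diabetes-depression microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: the linked diabetes-depression microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the model is

`diadem` is a patient-level discrete-event simulation (DES) of the
primary-care pathway experienced by adults with type-2 diabetes in England,
in which two disease processes are linked bi-directionally:

* a **depression sub-model** — onset of minor (sub-threshold) and major
  depression, minor-to-major progression, spontaneous recovery, relapse,
  screening-based identification and treatment; and
* a **diabetes sub-model** — annual hazards of eight diabetes-related
  complications (classified microvascular: IHD, blindness, renal failure;
  macrovascular: heart failure, MI, stroke, diabetic ulcer, amputation) and
  mortality, from a pluggable risk engine.

The linkage runs both ways. Depression raises complication hazards through
class-specific hazard ratios (microvascular 1.31 minor / 1.36 major;
macrovascular 1.00 minor / 1.25 major), weighted by the fraction of the
preceding year spent depressed — half a year of exposure confers half the
elevation — and excluding time on treatment for patients who ultimately
respond. Conversely, the presence of any diabetes-related complication
multiplies every depression onset and relapse hazard by 1.5 (the same
multiplier whether one or several complications are present).

Four policies are compared on costs, QALYs and clinical event counts:
current practice (`CP`), collaborative care (`P1`, relative risks 1.79 on
treatment response and 1.33 on drop-out reduction plus an add-on cost),
universal opportunistic screening (`P2`, every primary-care appointment of a
patient without identified depression includes a screen), and both combined
(`P3`).

## Event mechanics and numerical choices

**Exponential waiting times.** Every "time to X" input is an annual
probability, a mean, or a fraction-by-horizon; no distribution is named for
any of them, so all waiting times are exponential with the matching rate
(probability `p` per year becomes rate `-log(1-p)`; the 42%-by-2-years
progression input becomes rate `-log(0.58)/2` per year). The memoryless
property is load-bearing: whenever a hazard changes mid-wait (a first
complication appears, severity progresses), the remaining time is simply
re-drawn at the new rate, which is distributionally exact.

**Competing risks.** From the depression-free state with no history, minor
and major onset run as two independent exponential processes at 5.4%/year
each; with a history, a single relapse process (mean 1.359 years) applies
and the relapse severity is re-drawn with equal probability — the source
material is silent on whether relapse inherits the prior severity, and the
equal re-draw is our documented assumption. Minor episodes face competing
progression and recovery; ties (measure zero) resolve to progression.

**Contacts by thinned-Poisson segments.** GP appointments arrive as a
Poisson process (12.5/year without depression, 8/year with; treatment
appointments are excluded by construction). Only a screen that can identify
depression changes the patient's state, so the simulator samples the *first
identifying contact* directly as an exponential time at rate
`visits x p(screen) x Whooley sensitivity x interview sensitivity`, and
bills all other contacts of each constant-regime segment retrospectively
from the complementary thinning (unscreened, screened-negative, or — for
non-depressed patients — screened-false-positive with the interview ruling
them out at a cost). This is exact, and keeps the event loop at a few dozen
events per patient-lifetime.

**Annual cycles.** Complication and mortality draws happen on each
patient's diabetes anniversary for the coming year, using the depression
exposure accumulated over the *preceding* year, which is precisely the
exposure-weighting rule of the linkage. Event times within the year are
uniform. The annual review is offered at the same anniversary (attendance
90.4% times a state relative risk of 0.9 minor / 0.65 major; the review
includes a screen with probability 85.9% under current practice and 1 under
the screening policies — we treat the review as a primary-care appointment
for the purposes of the universal-screening policy, a documented
assumption).

**Screening cascade.** The two-item Whooley screen has sensitivity 0.95
(applied equally to minor and major depression; the evidence is not
stratified) and specificity 0.66; positives receive a structured interview,
perfect by default, which confirms true cases (they become *identified* and
are referred to treatment immediately) and rules out false positives at
interview cost only. With a perfect interview no patient can ever be
falsely identified — the test suite asserts this as a hard invariant. The
configuration allows an imperfect interview sensitivity (missed
confirmations); an imperfect interview *specificity* is honoured by the
standalone screening operation but patient timelines never create false
identified states — treating non-cases is out of the model's scope.

**Treatment.** One course per episode: drop-out is drawn first, then
response among completers. Responders remit at course end when that is
earlier than their sampled spontaneous recovery (treatment "shortens time
to remission"); while on course they have their major-depression utility
decrement halved and their depressed time excluded from complication-risk
exposure. Non-responders and drop-outs continue natural history unchanged.
Modalities and course composition are not published: the defaults (response
0.5, drop-out 0.3, duration 0.25 years; minor episodes get six
low-intensity sessions at £88, major episodes antidepressants at £0.073/day
with a 25% chance of a twelve-session high-intensity course; collaborative
care adds £180 per course) are deliberate placeholders, prominently
config-exposed and the first candidates for the sensitivity harness.
Drop-outs accrue half the planned course (configurable). The "relative risk
1.33" for drop-out is directionally ambiguous in its source; we divide the
drop-out probability by 1.33 so the effect is a decrease, with the
alternative reading (retention multiplied by 1.33) available as a switch.

**The risk engine is a surrogate.** The published regression equations this
class of model normally uses for complication and death hazards are not
reproduced here. The default engine uses constant per-complication annual
hazards chosen to give lifetime complication frequencies of a plausible
order for a 2,000,000-person diabetes cohort (e.g. MI 0.0105/yr, renal
failure 0.0019/yr), and a Gompertz-type mortality `exp(-10 + 0.092*age)`
with additive log-hazard loadings per complication present. Risk factors
(HbA1c, SBP, BMI, smoking) are carried in the cohort and held constant over
time, and a coefficient-file loader (`load_risk_engine()`) lets users plug
in an external equation set. Consequences: absolute cohort totals (costs in
£bn, complication counts) are indicative only; parameter-recovery,
worked-example and directional results are the quantities the package
stands behind. MI, stroke and ulcer may recur; IHD, heart failure,
blindness, renal failure and amputation occur at most once. Depression has
no direct mortality effect (mortality is routed through complications
only), and severe hypoglycaemia is an optional rate process, off by
default. A paper-internal inconsistency exists for the complication class
map (the structural description and the outcome table group four
complications differently); we follow the structural description, and the
class map is a configuration field.

**Economics.** Utility is additive: baseline 0.807 plus decrements
(-0.3 major depression, 0 minor; complication decrements as printed,
including the counterintuitive signs +0.008 for MI prior history and
+0.033 for blindness, which we preserve from the source table), clamped to
[-0.594, 1]; a multiplicative composition is a switch. Costs accrue either
as lumps at event times (appointments £37, reviews £397, screens £2 —
charged for review screens as well, consistent with the reported screening
aggregate — interviews £80, complication event-year costs) or as continuous
rates (ongoing management £252/yr, complication subsequent-year costs
starting one year after first occurrence, treatment resources spread over
the course). Discounting is continuous at 3.5%/yr: lumps by `1.035^-t`,
rates by the exact integral; annual-step discounting is a switch. The
structured-interview unit cost is not a published value; £80 is a
documented placeholder. All complication costs carry a 2013-GBP
currency-year tag. Societal outputs (informal-care days, days off work) use
per-state day rates that are pure placeholders. Every patient carries an
exact ledger: category totals always sum to the total, and the entry-level
ledger (`detail = TRUE`) reconciles with the internal accumulators to
floating-point accuracy — the suite tests both.

**Common random numbers.** Each (patient, process) pair owns an RNG stream
(processes: onset, episode transitions, contacts/screens, reviews,
treatment, diabetes draws, miscellaneous), with stream seeds derived from
the master seed. Each annual diabetes cycle consumes a fixed number of
uniforms whether or not events occur, so complication and death draws stay
aligned across policies. Two exact consequences, both asserted in tests:
with all linkage hazard ratios set to 1, complication counts are identical
across the four policies; and policies that do not touch any process a
patient uses (e.g. collaborative care for a never-depressed patient)
produce bit-identical timelines.

**Horizon.** Lifetime, with a hard cap at age 110 (the surrogate mortality
makes survival beyond this negligible; the cap bounds runtime for
degenerate configurations).

## The synthetic cohort

No patient-level baseline data ship with the package. `generate_cohort()`
draws a seeded synthetic cohort: age ~ N(65, 10) truncated to [35, 90],
diabetes duration ~ N(8, 6) truncated to [0, 40], 56% male, HbA1c/SBP/BMI
independent truncated normals, 16% smokers. Baseline depression prevalence
defaults to 10% major and 10% minor (the minor value is set equal to major
by assumption, as in the evidence base; the true baseline prevalence behind
the published analysis is not printed anywhere we can reach, so this is a
config value), a 10% resolved-history probability among the never
depressed, and baseline episodes start unidentified. The generator emulates
the *structure* the simulation needs, not the joint distribution of any
real audit population: risk factors are independent (no correlation
structure), there is no age-severity gradient, and prevalences are
age-constant. Tests that pass on this cohort therefore validate model
mechanics, parameter recovery and directional policy effects — not
calibration to any real population.

## Problem sizes and tolerances

Parameter-recovery checks run at 100,000 draws with four Monte-Carlo
standard errors as the acceptance band; hazard-ratio recovery uses two
50,000-patient cohorts over four annual cycles; the emergent
identification-fraction checks run the full linked model on 10,000-patient
cohorts (a deliberate reduction from the published 600,000 — the
identification fraction is intensive, so cohort size affects only
Monte-Carlo noise, about half a percentage point at this size). The
multi-policy comparison scales totals linearly to a 2,000,000-person
reporting cohort; scaling is exact and tested.

Under current practice the model identifies roughly half of all depressive
episodes, close to the reported share. Under universal screening it
reaches the low 80s in percent, a few points short of the reported ~87%:
identification of an episode competes with its spontaneous recovery, and
with minor episodes lasting on average 0.354 years while screening
opportunities are capped at 8 contacts/year x 0.95 sensitivity plus annual
reviews, per-episode identification for minors cannot exceed ~75% under
the printed parameter set. The unpublished internal treatment and episode
parameters of the original analysis evidently produced a higher value; we
report our emergent number rather than adjust printed inputs to chase it.

## Sensitivity harness

`sensitivity_sweep()` re-runs the full comparison once per scenario, under
the base seed and cohort so differences isolate the parameter change. The
default scenario file (`inst/extdata/scenarios.yaml`) varies the relapse
time, both directions of the bi-directional association (including the
complication-on-depression hazard ratio to 1.0 and 2.0 and the
depression-on-complication ratios to 1), the major-depression disutility,
the screen cost (£0 / £4) and the collaborative-care cost. Scenario files
are user-editable, so the number of analyses is user-defined.

## Known limitations

* The risk engine is a surrogate; absolute totals are not calibrated.
* Treatment course composition, interview cost, collaborative-care cost,
  baseline prevalence and societal day rates are placeholders.
* No probabilistic sensitivity analysis (deliberately out of scope), no
  stepped-care sequencing, no instrument-specific screening detail, no
  suicide-specific mortality, no HbA1c-mediated causal pathway between
  depression and complications.
* Relapse severity re-draw, review-as-appointment under universal
  screening, and history-based screening from first onset are documented
  assumptions where the evidence base is silent.
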