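---
title: "Methods: a whole-disease microsimulation of the schizophrenia care pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-disease microsimulation of the schizophrenia care pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`schizwdm` is a patient-level discrete-event simulation (DES) of the UK
secondary-care pathway for psychosis, evaluated over a lifetime horizon
(default age cap 100 years) with costs from the NHS and Personal Social
Services perspective in 2016–17 GBP and outcomes in QALYs, both discounted
at 3.5% a year. One shared model serves five decision problems (CBT at
clinical high risk, acute episode management, first-line antipsychotic,
family intervention, antipsychotic choice in treatment resistance); every
arm of every topic runs the *entire* pathway, not a truncated sub-model, so
upstream choices propagate into downstream costs and outcomes.

Patients enter at referral with status not-at-risk (33.21%), clinical high
risk (CHR-P, 34.90%) or first-episode psychosis (31.89%), age
Normal(23.52, 5.1) truncated at 14, 60.4% men.

* **Assessment.** Everyone incurs an assessment cost at entry; psychosis
  entrants incur the acute-assessment cost (£507).
* **CHR pathway.** CBT (16 sessions at £97) is offered — in the
  `pau_plus_cbt` arm — with probability provision (0.4101) times take-up
  (0.51). Transition to psychosis and remission compete as exponential
  clocks from annual probabilities; CBT scales the transition probability by
  RR 0.41, either for life (`prevent` mode) or during a configurable window
  (`delay` mode, default 3 years), after which the baseline hazard resumes.
  Remitters leave the service (out-of-scope utility, no further cost).
* **Psychosis pathway.** An antipsychotic is taken up with probability
  0.9738. Annual all-cause discontinuation per drug comes from its odds
  ratio against placebo applied to the placebo probability 0.82. Each
  discontinuation opens an untreated gap (default 1 year) with an elevated
  relapse hazard, then the next line in a fixed fallback sequence starts.
  After two failed adequate trials the patient is treatment-resistant:
  clozapine initiation is delayed by the observed delay (3.98 years, spent
  on an interim antipsychotic), non-clozapine choices discontinue per their
  odds ratios against clozapine's inefficacy probability 0.02, and a patient
  who discontinues clozapine settles on absorbing non-clozapine maintenance.
  Relapses arrive from a piecewise-constant hazard (baseline annual
  probability times state multipliers, times RR 0.63 while family
  intervention applies), each costing an acute assessment plus either a
  hospital admission (bed-days x bed-day cost) or a CRHT episode (contacts x
  contact cost) according to the acute-management arm; during an episode
  (default 0.25 years) utility drops to the relapse value.
* **Adverse events.** Per drug-line, four adverse events arrive as
  exponential clocks from annual incidences: weight gain and diabetes are
  chronic from onset (lifetime disutility and annual cost), acute
  extrapyramidal symptoms are episodic (disutility for the episode plus a
  per-episode cost), neutropenia is a per-episode cost.
* **Death.** Background mortality is a synthetic Gompertz–Makeham hazard
  (Makeham constant 4e-4, Gompertz level 2.2e-5, slope 0.1 per year of age;
  male hazard ratio 1.4), multiplied by a standardized mortality ratio
  (2.5) from psychosis onset. Death times are found by inverting the
  piecewise cumulative hazard against one exponential draw, so adding the
  SMR after a transition shortens survival without resampling.

Probabilities become rates via `r = -log(1 - p)`; treatment effects
multiply on the probability scale first (capped at 1) and are then
converted. Discounting is continuous, `rho = log(1.035)`, which agrees
with annual-cycle discounting at integer years and is the natural
convention when events occur at arbitrary real times.

## Common random numbers

Every patient owns a fixed 176-long block of uniform draws keyed by purpose
(CBT offer/take-up, transition, remission, death, antipsychotic take-up,
family-intervention offer/take-up, eight discontinuation clocks, a 4 x 8
adverse-event grid, 64 relapse gaps, 64 episode-management assignments),
seeded from `(run seed, patient id)`. The block is consumed positionally,
never sequentially, so two scenarios with the same seed use the *same*
numbers for the *same* purposes regardless of which events actually occur.
Consequences that the test suite verifies exactly: a mixed CRHT/hospital
arm reproduces the hospital-only arm's QALYs bit for bit (management
changes costs only); `crht_fraction = 0` is bit-identical to hospital-only;
a null CBT effect (RR 1) changes costs by exactly the course cost times the
uptake fraction and QALYs not at all; and effect monotonicity (prevent vs
delay vs none; discontinuation odds ratios vs treatment-resistance entries)
holds pointwise, not just in expectation.

## Parameter registry

`inst/extdata/parameters.csv` holds one row per parameter: `name, family,
param1, param2, baseline, units, provenance, citation`. Families: beta
(alpha, beta), gamma (shape, scale), normal (baseline mean, SE), lognormal
(baseline *median*, SD of log — the standard convention for published
relative risks and odds ratios), Dirichlet components (n, N; components
sharing N are drawn as one joint Dirichlet so shares sum to 1), Weibull
(shape, scale) and fixed. Deterministic analyses use the baseline column
exactly; PSA draws one joint sample per iteration, redrawing values that
fall outside the support implied by the units (probabilities and utilities
in [0, 1], costs non-negative) and counting the redraws.

Three numerical choices deserve note:

* A few gamma rows have a printed baseline that disagrees with shape x
  scale by more than rounding (the clozapine delay, and several
  adverse-event costs — for the long-run weight-gain cost the distribution
  mean is about 80 times the baseline). Deterministic runs always use the
  printed baseline; PSA draws rescale the gamma's scale so its mean equals
  the baseline, preserving the shape and hence the coefficient of
  variation. Sampling from the printed distribution unmodified would let a
  transcription artefact dominate the PSA.
* The Weibull for bed-days per relapse (shape 0.65, scale 0.61) has mean
  0.85 under any standard convention, against a printed baseline of 138.9;
  PSA draws are rescaled to mean 138.9 likewise.
* The clozapine inefficacy beta(4.98, 310.02) has mean 0.0158 against a
  printed 0.02; the baseline 0.02 is used deterministically and the beta
  for PSA.

Entries with `provenance = placeholder` are quantities the published
summary does not report; `placeholder_entries()` enumerates them and every
`run_topic()` log lists the ones in use.

## Placeholder baselines and what they mean

Baseline event risks (CHR transition 0.20/yr, CHR remission 0.15/yr,
relapse on maintenance 0.05/yr), the off-treatment relapse hazard ratio
(5), the non-clozapine-in-TRS relapse hazard ratio (2), the untreated gap
(1 year), episode durations, adverse-event incidences, the out-of-scope
utility (0.87), the CHR care cost, background mortality and the SMR are
placeholders. They were set once, on two grounds: clinical plausibility
(orders of magnitude from the relapse-prevention and clozapine literatures)
and consistency with the *directions* of the published model's findings —
the standard way a whole-disease model pins unobservable baseline risks is
to calibrate them against known outputs. Two structural choices matter
most: placebo confers no relapse protection (the off-treatment multiplier
applies while on placebo), and non-clozapine antipsychotics after treatment
resistance carry a relapse multiplier, expressing clozapine's unique
efficacy in TRS — without it, clozapine's higher acquisition and monitoring
costs could never be offset by fewer relapses and no parameterisation would
make clozapine dominant, contradicting the published finding and clinical
consensus.

Consequently the model reproduces *structure and direction*, not absolute
levels: per-arm absolute costs and QALYs depend on the placeholders and are
deliberately not asserted anywhere. What the test suite does assert (all
computed at test time, nothing hard-coded from a simulation we did not
run): the ICER arithmetic and the dominance/extended-dominance labels over
the seven published first-line arm results; exact cohort composition;
the exact-zero incremental QALY of the acute-management comparison; the
closed-form discounted annuity from a degenerate simulation; and the
directional rankings (CBT arm dominating, AP + family intervention
dominating, clozapine the most cost-effective TRS arm, and the
low-discontinuation drugs amisulpride/risperidone/olanzapine the cheapest
first-line options, each outranking aripiprazole and placebo on net
monetary benefit). The haloperidol-vs-olanzapine margin is a few tens of
pounds per person at desk scale — inside placeholder uncertainty — so no
ordering between them is asserted.

## Cost-effectiveness layer

`efficiency_frontier()` removes strictly dominated arms, then iteratively
removes arms while ICERs along the cost-sorted frontier fail to increase
strictly (extended dominance). The test suite checks it against an
independent brute-force oracle (pairwise dominance by definition; extended
dominance by exact mixture-segment checks over all pairs) on 10,000 random
instances of up to six arms. `ceac_from_draws()` computes, per
willingness-to-pay value, the probability of each arm having the highest
net monetary benefit; exact ties split evenly (the source gives no tie
rule; ties have probability zero under continuous draws anyway).
`run_psa()` holds the patient-level seed fixed across draws so the CEAC
reflects parameter (second-order) uncertainty only, with cohort size per
draw configurable — 10,000 by default at desk scale, 200,000 to mimic a
full deterministic analysis.

## Problem sizes and numerics

Deterministic desk-scale analyses in the examples and tests use cohorts of
2,000–10,000 patients; the stratified generator makes the headline
composition exact at any size (largest-remainder rounding), and 200,000
patients reproduce the published composition exactly (120,800 men, 69,800
at CHR-P) in seconds. The engine caps composed event probabilities at 0.99
before rate conversion (a rate of infinity has no DES meaning), caps
relapses at 64 and treatment lines at 8 per patient (beyond any realistic
trajectory), and truncates ages at 14 with the pre-truncation mean shifted
so the post-truncation mean is exactly 23.52 (solved by `uniroot` at
generation time). Mortality inversion uses `uniroot` on the piecewise
cumulative hazard with tolerance 1e-10 and returns infinity when the total
hazard over 150 years is below the drawn exponential (relevant only for
degenerate null-mortality tests). Utility segments are half-open,
non-overlapping by construction, and floored at zero after subtracting
adverse-event decrements.

## Limitations

The model does not cover long-acting injectables as scenario arms,
societal costs, covariates beyond age and sex, relapse-count-dependent
hazards (a per-relapse multiplier hook exists but defaults to 1), or
correlation between PSA parameters (independence assumed; the source is
silent). Whether session costs should be charged per attended session under
partial adherence is unknown; the full course is charged at course start.
The internal ordering of the four non-clozapine TRS arms follows
time-to-clozapine-switch in this model, which need not match the published
ordering of those four arms; only clozapine's top rank is claimed. Because
the placeholder baselines set the scale of costs and QALYs, absolute
outputs should not be quoted as national estimates; the model is a faithful
structural re-implementation whose quantitative fidelity is limited to the
published inputs it embeds.
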