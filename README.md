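# schizwdm

Patient-level whole-disease model of the UK schizophrenia care pathway, with
a cost-effectiveness analysis layer.

Most economic models in schizophrenia evaluate one decision in isolation — a
drug comparison here, a psychosocial intervention there — with inconsistent
assumptions between models. A *whole-disease model* (WDM) instead simulates
the entire care pathway in one consistent framework, so that interventions
at every decision point are evaluated against the same downstream costs and
consequences. `schizwdm` implements such a model as a discrete-event
microsimulation: people referred to secondary mental-health services (some
not at risk of psychosis, some at clinical high risk, some presenting with
first-episode psychosis) are simulated individually through assessment, the
clinical-high-risk state, psychosis, antipsychotic treatment lines,
discontinuation, relapse, treatment resistance, clozapine, adverse events
and death, in continuous time over a lifetime horizon.

The package evaluates five decision problems from the one shared model:

1. **CHR-P** — practice as usual with vs without 16 sessions of CBT for
   people at clinical high risk of psychosis;
2. **acute psychosis** — hospital admission alone vs a mix of admission and
   crisis resolution and home treatment (CRHT);
3. **first-episode psychosis (FEP)** — seven first-line oral antipsychotic
   options (including placebo);
4. **family intervention** — antipsychotic medication alone, family
   intervention alone, or both;
5. **treatment-resistant schizophrenia (TRS)** — five antipsychotic options
   including clozapine.

## The model in brief

Events are scheduled in continuous time from annual probabilities converted
to exponential rates, `r = -log(1 - p)`. Treatment effects enter as relative
risks on the probability scale (e.g. RR 0.41 on the CHR-to-psychosis
transition for CBT, RR 0.63 on relapse for family intervention) or as odds
ratios applied to a reference probability,

    p = OR * o0 / (1 + OR * o0),  o0 = p0 / (1 - p0),

as for per-drug annual all-cause discontinuation against placebo
(p0 = 0.82). Outcomes are quality-adjusted life-years (QALYs) from
health-state utilities (0.71 at clinical high risk, 0.80 in remission, 0.67
in relapse, minus adverse-event decrements) and costs in 2016–17 GBP from
the NHS and Personal Social Services perspective; both are discounted at
3.5% a year in the continuous convention `rho = log(1.035)`.

The cost-effectiveness layer computes incremental cost-effectiveness ratios
(ICER = Δcost/ΔQALY), identifies the efficiency frontier with strict and
extended dominance, computes net monetary benefit (NMB = λ·QALY − cost) and
cost-effectiveness acceptability curves, and runs probabilistic sensitivity
analysis by re-simulating under joint parameter draws from the registry's
distributions (beta, gamma, lognormal, Dirichlet, Weibull) with a fixed
patient-level seed, so that PSA variation reflects parameter uncertainty
only.

All arms of a topic are simulated under *common random numbers*: every
patient owns a fixed block of uniform draws keyed by purpose, so arms differ
only where the interventions differ. This makes structural identities exact —
the mixed CRHT/hospital arm reproduces the hospital-only arm's clinical
course event for event and differs only in episode-management costs.

Quantities the published parameter summary does not report (baseline
transition/relapse risks, adverse-event incidences, background mortality)
are shipped as explicitly flagged `placeholder` registry entries; see the
methods vignette (`vignettes/whole-disease-model.Rmd`) for how they were
chosen and what that implies.

## Worked example

```r
library(schizwdm)

registry <- load_registry(default_registry())
params   <- baseline_parameters(registry)
cohort   <- generate_cohort(2000, params, mode = "stratified", seed = 1)

hosp <- simulate_cohort(cohort, scenario_config(acute_management = "hospital_only"),
                        params, seed = 1, arm_name = "hospital_only")
mix  <- simulate_cohort(cohort, scenario_config(acute_management = "mixed_crht"),
                        params, seed = 1, arm_name = "mixed_crht")
hosp
#> <wdm_arm_result> hospital_only: n = 2000, mean cost = 208579 GBP, mean QALY = 18.5909
mix
#> <wdm_arm_result> mixed_crht: n = 2000, mean cost = 187219 GBP, mean QALY = 18.5909

efficiency_frontier(list(hosp, mix))
#>             arm     cost     qaly      status      label inc_cost inc_qaly icer
#> 1 hospital_only 208579.1 18.59089   dominated  dominated       NA       NA   NA
#> 2    mixed_crht 187218.8 18.59089 on_frontier dominating       NA       NA   NA
```

The two arms accrue *identical* QALYs — under common random numbers the
clinical course is the same and only the cost of managing each acute episode
changes — so the mixed arm dominates: same health, lower cost. The absolute
cost level depends on the flagged placeholder baselines and should not be
read as a calibrated national estimate.

`run_topic()` runs a whole decision topic and writes a result bundle
(arm results, CEA table, optional CEAC, JSON manifest, log):

```r
run_topic("chr", "out/chr", n_patients = 10000, seed = 1)
```

A thin command-line wrapper is provided at `inst/cli/wdm.R`:

```sh
Rscript inst/cli/wdm.R run-deterministic --topic trs-ap --n-patients 10000 --seed 1 --out-dir out/trs
```

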