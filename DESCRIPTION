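Package: schizwdm
Title: Whole-Disease Microsimulation of the Schizophrenia Care Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level discrete-event simulation of the UK secondary-care
    pathway for psychosis and schizophrenia, from referral and assessment
    through the clinical-high-risk state, first-episode psychosis, relapse,
    and treatment-resistant schizophrenia, with a cost-effectiveness layer.
    A single whole-disease model evaluates interventions at five decision
    points (CBT for people at clinical high risk, crisis resolution and home
    treatment for acute psychosis, choice of first-line antipsychotic,
    family intervention, and antipsychotics for treatment resistance) under
    common random numbers. Includes a parameter registry with probabilistic
    sensitivity-analysis sampling, discounted QALY and cost accumulation,
    incremental analysis with dominance and extended dominance, and
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
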