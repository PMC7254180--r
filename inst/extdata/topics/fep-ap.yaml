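topic: fep-ap
n_patients: 10000
seed: 1
wtp: [20000, 30000]
arms:
  amisulpride:
    fep_first_line: amisulpride
  aripiprazole:
    fep_first_line: aripiprazole
  haloperidol:
    fep_first_line: haloperidol
  olanzapine:
    fep_first_line: olanzapine
  placebo:
    fep_first_line: placebo
  quetiapine:
    fep_first_line: quetiapine
  risperidone:
    fep_first_line: risperidone
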