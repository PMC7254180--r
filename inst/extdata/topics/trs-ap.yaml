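topic: trs-ap
n_patients: 10000
seed: 1
wtp: [20000, 30000]
arms:
  clozapine:
    trs_first_line: clozapine
  haloperidol:
    trs_first_line: haloperidol
  olanzapine:
    trs_first_line: olanzapine
  quetiapine:
    trs_first_line: quetiapine
  risperidone:
    trs_first_line: risperidone
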