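topic: acute
n_patients: 10000
seed: 1
wtp: [20000, 30000]
arms:
  hospital_only:
    acute_management: hospital_only
  mixed_crht:
    acute_management: mixed_crht
    crht_fraction: 0.5
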