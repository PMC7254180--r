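topic: chr
n_patients: 10000
seed: 1
wtp: [20000, 30000]
arms:
  pau:
    chr_intervention: pau
  pau_plus_cbt:
    chr_intervention: pau_plus_cbt
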