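topic: fep-fi
n_patients: 10000
seed: 1
wtp: [20000, 30000]
arms:
  ap_only:
    family_intervention: ap_only
  fi_only:
    family_intervention: fi_only
  ap_plus_fi:
    family_intervention: ap_plus_fi
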