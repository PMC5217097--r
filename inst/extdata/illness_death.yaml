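# illness-death trial scenario: non-fatal event N, fatal event F,
# constant yearly hazards; intervention arm identical to control (null)
tau: 5
censor_rate: 0.05
n_per_arm: 500
arms:
  control:
    edges:
      - {from: 'initial', to: 'N', component: 'N', hazard: 0.05}
      - {from: 'initial', to: 'F', component: 'F', hazard: 0.02}
      - {from: 'N', to: 'N.F', component: 'F', hazard: 0.2}
  intervention:
    edges:
      - {from: 'initial', to: 'N', component: 'N', hazard: 0.05}
      - {from: 'initial', to: 'F', component: 'F', hazard: 0.02}
      - {from: 'N', to: 'N.F', component: 'F', hazard: 0.2}
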