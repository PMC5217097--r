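# two transient states N (less severe) and M plus a fatal state F;
# intervention reduces every hazard by 25%
tau: 5
censor_rate: 0.05
n_per_arm: 500
arms:
  control:
    edges:
      - {from: 'initial', to: 'N', component: 'N', hazard: 0.08}
      - {from: 'initial', to: 'M', component: 'M', hazard: 0.1}
      - {from: 'initial', to: 'F', component: 'F', hazard: 0.04}
      - {from: 'N', to: 'N.F', component: 'F', hazard: 0.2}
      - {from: 'M', to: 'M.F', component: 'F', hazard: 0.3}
  intervention:
    edges:
      - {from: 'initial', to: 'N', component: 'N', hazard: 0.06}
      - {from: 'initial', to: 'M', component: 'M', hazard: 0.075}
      - {from: 'initial', to: 'F', component: 'F', hazard: 0.03}
      - {from: 'N', to: 'N.F', component: 'F', hazard: 0.15}
      - {from: 'M', to: 'M.F', component: 'F', hazard: 0.225}
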