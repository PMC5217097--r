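# vascular-prevention trial: myocardial infarction (MI), stroke (ST),
# vascular death (DE); post-event rates double, no ST->MI transitions
tau: 3
censor_rate: 0.05
n_per_arm: 700
arms:
  control:
    edges:
      - {from: 'initial', to: 'MI', component: 'MI', hazard: 0.04}
      - {from: 'initial', to: 'ST', component: 'ST', hazard: 0.06}
      - {from: 'initial', to: 'DE', component: 'DE', hazard: 0.015}
      - {from: 'MI', to: 'MI.ST', component: 'ST', hazard: 0.12}
      - {from: 'MI', to: 'MI.DE', component: 'DE', hazard: 0.03}
      - {from: 'ST', to: 'ST.DE', component: 'DE', hazard: 0.03}
      - {from: 'MI.ST', to: 'MI.ST.DE', component: 'DE', hazard: 0.03}
  intervention:
    edges:
      - {from: 'initial', to: 'MI', component: 'MI', hazard: 0.03}
      - {from: 'initial', to: 'ST', component: 'ST', hazard: 0.04}
      - {from: 'initial', to: 'DE', component: 'DE', hazard: 0.01}
      - {from: 'MI', to: 'MI.ST', component: 'ST', hazard: 0.08}
      - {from: 'MI', to: 'MI.DE', component: 'DE', hazard: 0.02}
      - {from: 'ST', to: 'ST.DE', component: 'DE', hazard: 0.02}
      - {from: 'MI.ST', to: 'MI.ST.DE', component: 'DE', hazard: 0.02}
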