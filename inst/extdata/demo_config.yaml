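# Demo run configuration: synthetic weather for the default arid site, the
# shipped calibrated crop profile, the T5 treatment (80% ETc in the rapid
# and mid stages), scaled module budgets.
seed: 3
scale: 0.1
scenario:
  days: 180
  start_doy: 115
treatment:
  plan: T5
bilevel:
  pop: 24
  generations: 60
  mode: simulator
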