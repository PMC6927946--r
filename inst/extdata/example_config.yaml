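# Example run configuration: a three-animal cohort, default seven-phase
# curriculum (omitted = packaged defaults), default sequencer constraints.
cohort:
  - animal_id: m1
    group: wt
  - animal_id: m2
    group: wt
  - animal_id: m3
    group: wt
odor_pair: [cineol, eugenol]
start_phase: 1
duration_h: 24
seed: 42
agents:
  tau: 120
  p_rfid_fail: 0.05
  p_presample_fail: 0.05
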