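# Brain irradiation (position P5) by a monoenergetic 0.6616 MeV point
# source at the head, for comparison against the collimated 6 MV beam.
scenario:
  type: treatment
  target: P5
  field_cm: 10
beam:
  mode: monoenergetic-point
  energy_mev: 0.6616
run:
  n_histories: 40000
  n_batches: 20
  seed: 1
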