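# Left-lung irradiation (position P4), generic 6 MV beam, 10 x 10 cm2
# field at the isocenter, 100 cm source-to-isocenter distance.
scenario:
  type: treatment
  target: P4
  field_cm: 10
run:
  n_histories: 40000
  n_batches: 20
  seed: 1
  workers: 1
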