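# Water-phantom depth-dose benchmark: SSD 100 cm, 10 x 10 cm2 field,
# 30 cm scored depth in 0.5 cm central-axis bins.
scenario:
  type: pdd
  depth_cm: 30
  bin_cm: 0.5
  field_cm: 10
run:
  n_histories: 200000
  n_batches: 10
  seed: 1
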