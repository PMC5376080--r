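# File formats

All CSV files: comma separator, dot decimal, one header row, UTF-8.

## Scenario configuration (YAML)

```yaml
scenario:
  type: treatment | pdd     # full room+phantom run, or water depth-dose
  target: P1..P5            # irradiation position (treatment)
  field_cm: 10              # square field side at the isocenter plane
  depth_cm: 30              # scored depth (pdd)
  bin_cm: 0.5               # depth bin (pdd)
beam:                       # optional; default: generic 6 MV cone beam
  mode: spectrum-beam | monoenergetic-point
  energy_mev: 0.6616        # line spectrum
  spectrum_file: spec.csv   # 2 columns: energy_mev, probability
  half_angle_deg: 2.86      # cone half-angle override
run:
  n_histories: 40000        # required, > 0
  n_batches: 20
  seed: 1
  workers: 1                # results independent of this value
  cutoff_mev: 0.01
  analog: false
  target_rel_error: 0.004   # optional early stop
```

## Cross-section library (`xs_photoatomic_v1.csv`)

element, energy_mev, pe_cm2g, incoh_cm2g, pair_cm2g — elemental mass
attenuation partials (photoelectric, incoherent, pair) on an ascending
log grid, 0.01-10 MeV. Regenerable with `xs_write_library()`.

## Dose table (`doses.csv`)

cell, organ, dose_mev_g_per_photon, dose_agy_per_photon, rel_error —
absorbed dose per source photon per tally region; rel_error is one
standard error of the batch mean over the mean.

## Conversion table (`convert` output)

position, organ, F, rel_error, target, seed — F = dose(organ)/dose(target
organ); F(target) = 1; rel_error combines both tally errors in
quadrature; seed is run provenance.

## Dispersed-dose report (`chart-report` output)

organ, F, dispersed_gy (3 s.f.), per_fraction_gy, percent_of_target —
dispersed dose = F x prescribed total dose of the fractionation schedule.

## PDD table (`pdd` output)

depth_cm (bin centers, 0-30 cm), pdd (percent of maximum), rel_error.

## Run manifest (`manifest.json`)

label, code_version, seed, n_histories, scenario_checksum (stable for
identical configs), started/finished timestamps, outputs.

## Run log (`run.log`)

Seed, history and lost-particle counts, and per-organ dose with final
relative errors.
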