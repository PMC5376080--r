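# photondose

Monte Carlo photon transport for in- and out-of-field radiotherapy
dosimetry, in R with a compiled tracking kernel.

External photon radiotherapy inevitably delivers *dispersed*
(out-of-field) dose to healthy organs, through scatter inside the
patient, the accelerator head and the treatment room. Estimating those
doses matters for secondary-cancer risk, yet they cannot be measured
inside a patient. photondose simulates the whole situation — a 6 MV
linear-accelerator head, a stylized adult male phantom on a couch, and
a shielded concrete bunker with maze and control room — and summarizes
each organ's exposure as a conversion coefficient

    F = D_d / D_t

the dose in a non-targeted tissue divided by the dose in the targeted
tissue of the same irradiation, per source photon. F(target) = 1 by
construction and F is independent of fluence normalization, so a table
of F values converts any prescription into per-organ dispersed doses:
with a prescribed total dose D, each organ receives F x D.

The core is an analog / implicit-capture photon transport engine over
quadric-surface constructive solid geometry:

* photoelectric absorption, free-electron Klein–Nishina Compton
  scattering, and pair production (0.01–10 MeV), with all electron
  energy deposited at the interaction site (collision kerma);
* collision and track-length-heating dose estimators with batch-means
  relative errors (convergence flag at 0.4%);
* per-history RNG streams, so results are bit-identical for any worker
  count — the parallel contract is tested, not assumed;
* analytic elemental cross-section tables shipped as CSV and
  regenerable in code (`xs_write_library()`);
* scenario builders for the treatment room (13.7 x 9 x 4 m, concrete
  2.35 g/cm^3, air 0.00129 g/cm^3), the phantom with irradiation
  points P1–P5 (testes, colon, liver, left lung, brain), the head
  (collimator, window, foil, spacers, X-jaws; 100 cm
  source-to-isocenter), a water-tank depth-dose benchmark (SSD 100 cm,
  10 x 10 cm^2 field, 30 cm in 0.5 cm bins), and analytic oracle
  worlds used by the test suite.

Absolute organ doses from a desk-scale kerma code with analytic cross
sections are *qualitative*; the validation strategy is therefore
property-based (exponential attenuation, Klein–Nishina quadrature
moments, exact energy balance, inverse-square fluence, estimator
agreement, F-ordering). See the methods vignette
(`vignettes/photondose-methods.Rmd`) for the model, its assumptions and
its limitations.

## Worked example

Irradiate the left lung (position P4) with the generic 6 MV beam,
derive conversion coefficients, and apply a hyperfractionated 54 Gy /
36-fraction course (3 fractions/day over 12 days):

```r
library(photondose)

scn <- build_treatment_scenario("P4", field_cm = 10)
res <- run(scn, run_config(n_histories = 4e4, seed = 1))
f   <- compute_conversion_coefficients(as_dose_result(res, "P4"),
                                       "left_lung")
sched <- fractionation_schedule(54, 36, per_day = 3, days = 12)
apply_conversion(f, sched, "P4")
```

The run prints per-organ doses per source photon (aGy/photon) with
relative errors, e.g. at 4e4 histories:

```
        organ dose_agy rel_error
    left_lung 35000.00   0.02670
        heart   716.00   0.11100
    esophagus   405.00   0.20900
        spine   264.00   0.05400
   right_lung   101.00   0.14200
        ...
```

The target organ dominates; nearby thoracic organs (heart, esophagus,
spine) follow, and distal organs (brain, testes) are orders of
magnitude lower. The conversion step turns these into F values
(heart 2.05e-2, spine 7.56e-3, ... with errors combined in quadrature)
and the schedule application into dispersed doses in Gy
(heart 1.11 Gy of the 54 Gy course, 0.0307 Gy per fraction).

Printed F values from a published table can be applied directly,
without a simulation — this is the package's deterministic worked
example:

```r
tab <- conversion_table("P4", c(heart = 0.9463, right_lung = 0.6556,
                                spine = 0.3519), target = "left_lung")
apply_conversion(tab, fractionation_schedule(54, 36, 3, 12), "P4")
#>        organ      F dispersed_gy per_fraction_gy percent_of_target
#> 1  left_lung 1.0000      54.0000         1.50000            100.00
#> 2      heart 0.9463      51.1002         1.41945             94.63
#> 3 right_lung 0.6556      35.4024         0.98340             65.56
#> 4      spine 0.3519      19.0026         0.52785             35.19
```

## Command line

A thin wrapper at `inst/cli/photondose-cli.R` exposes the workflow:
`run` (config -> dose CSV + manifest), `convert` (dose CSV -> F table),
`chart-report` (F table + schedule -> dispersed-dose report), `pdd`
(water-tank depth-dose CSV), `list-benchmarks` / `run-benchmark`
(analytic oracles with pass/fail), and `dump-geometry` (ASCII cross
sections of the assembled room). Example configs live in
`inst/extdata/`; file formats are documented in `inst/FORMATS.md`.

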