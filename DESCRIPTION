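Package: photondose
Title: Monte Carlo Photon Transport for In- and Out-of-Field Radiotherapy Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained Monte Carlo photon transport simulator for
    radiotherapy dosimetry in a shielded treatment room. Builds a stylized
    adult male phantom, a 6 MV linear-accelerator head and a concrete
    bunker (maze and control room) from quadric-surface constructive solid
    geometry, transports photons with Klein-Nishina Compton scattering,
    photoelectric absorption and pair production, and tallies absorbed
    dose per source photon in each organ. Post-processing computes
    percent-depth-dose curves, dose conversion coefficients F = Dd/Dt for
    non-targeted tissues, point-source comparison tables, and dispersed
    doses under fractionation schedules. Includes analytic benchmark
    oracles (slab attenuation, Klein-Nishina moments, inverse-square
    fluence) and a deterministic per-history random-number contract so
    results are independent of worker count.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
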