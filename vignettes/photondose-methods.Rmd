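---
title: "Methods: photon transport, dosimetry model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon transport, dosimetry model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

photondose simulates a common external-radiotherapy situation: a 6 MV
linear accelerator in a shielded concrete bunker irradiates one organ of
a supine adult male phantom, and we ask how much dose every *other*
organ receives. The summary quantity is the conversion coefficient

F = D_d / D_t,

the dispersed dose in a non-targeted tissue divided by the absorbed
dose in the targeted tissue of the same irradiation. F is a per-photon
dose ratio, so it is independent of fluence normalization; F of the
target itself is 1 by construction. Once a table of F values exists for
an irradiation position, the dispersed dose of any prescription follows
by multiplication: a 54 Gy prescription with F(heart) = 0.9463 implies
51.1 Gy to the heart, with per-fraction values given by dividing by the
number of fractions of the schedule.

This vignette records the physics model, the numerical choices, and the
design decisions that were genuinely open, in enough detail that a
maintainer can judge what a passing test does and does not demonstrate.

## Transport model

Photons are transported by analog or implicit-capture Monte Carlo
through constructive solid geometry built from quadric surfaces
(planes, spheres, ellipsoids, cylinders, cones). Three interactions are
modeled between 0.01 and 10 MeV:

* **Photoelectric absorption** — the photon's full energy is deposited
  at the interaction site (fluorescence is neglected).
* **Compton scattering** — free-electron Klein–Nishina sampling of the
  scattering cosine by rejection under the envelope f(mu) <= 2, with the
  scattered energy from E' = E / (1 + (E/0.511)(1 - cos theta)) and the
  electron recoil E - E' deposited locally.
* **Pair production** above 1.022 MeV — E - 1.022 MeV is deposited
  locally and two back-to-back 0.511 MeV annihilation photons continue
  transport with isotropic orientation.

**Secondary electrons are not transported.** All energy transferred to
electrons is deposited at the interaction point (the collision-kerma
approximation, valid under charged-particle equilibrium). This is the
dominant accuracy difference from a coupled photon–electron code: there
is no dose build-up region, so the simulated water depth-dose curve
peaks at the surface instead of at ~1.5 cm, and organ doses near
interfaces are kerma, not dose. Coherent (Rayleigh) scattering is
omitted; it redirects but barely degrades photons and deposits
essentially no energy. Photons falling below the 0.01 MeV cutoff
deposit their remaining energy on the spot (sub-cutoff photons have
millimeter-scale ranges in tissue).

## Cross-section data

No redistributable evaluated photo-atomic library is embedded. The
shipped element tables (`inst/extdata/xs_photoatomic_v1.csv`, 17
elements H–Pb on a 60-point log grid, regenerable with
`xs_write_library()`) are computed from analytic models:

* incoherent: the exact Klein–Nishina total cross section per electron
  times Z/A (binding neglected). Because attenuation in tissue between
  0.05 and 10 MeV is Compton-dominated, this reproduces standard water
  values closely (0.0706 vs 0.0707 cm^2/g at 1 MeV);
* photoelectric: a Born-approximation Z^5 form with an E^-7/2
  low-energy branch and a 1/E relativistic branch, normalized so water
  attenuation at 10 keV has the standard magnitude. Accuracy is a few
  percent in tissue, tens of percent for high-Z elements (the true Z
  exponent is nearer 4.5 and edge structure is absent);
* pair: Born-asymptote (28/9)ln(2k) - 218/27 in Z(Z+1) scaling with a
  cubic threshold match below k = 8. Pair is under 10% of tissue
  attenuation below 6 MeV, so this tolerance is acceptable here.

Consequently the package's absolute organ doses are not
evaluated-data-grade; conversion coefficients, which are dose ratios
within one run, are much less sensitive to the library scale. All
validation targets are therefore analytic properties (exponential
attenuation, Klein–Nishina moments, energy conservation, inverse-square
fluence, estimator consistency) rather than absolute dose values.

Interpolation is log-log between grid points, and the material total is
formed by summing interpolated partials, so partials add to the total
at every energy. The Klein–Nishina closed form is replaced by its
Thomson series below k = E/m c^2 = 0.005, where the closed form cancels
catastrophically in double precision.

## Estimators and statistics

The primary dose estimator is collision-based: the energy transferred
to electrons at each interaction, accumulated per cell and divided by
the analytic cell mass. A track-length heating estimator is also
scored: each chord contributes weight x length x kappa(E), where
kappa(E) = mu_pe E + mu_inc E (1 - mean scattered fraction) +
mu_pair (E - 1.022) is the expected locally deposited energy per unit
path, with the mean Compton scattered fraction from adaptive quadrature
of the Klein–Nishina distribution. The two estimators measure the same
expectation and their agreement (tested on the per-batch paired
difference, because they share histories) is a standing internal
consistency check.

Runs are divided into batches (default 20); the relative error is one
standard error of the batch means over the mean, flagged converged at
or below 0.4%. In analog mode the per-history balance emitted =
deposited + escaped holds to 1e-9 relative and is asserted. In
implicit-capture mode the photoelectric fraction of the weight is
absorbed at each collision and Russian roulette (threshold 0.01,
survival weight 0.1) terminates low-weight histories unbiasedly.

Every history draws from its own RNG stream (splitmix64 keyed by seed
and history index), so tallies are bit-identical however histories are
chunked across batches or forked workers — the parallel execution
contract is testable rather than assumed.

## Geometry and tracking numerics

Cells are boolean expression trees over signed quadric references,
compiled to postfix token streams for the C++ kernel. Point sense is
the sign of the quadric; boundary distance is the smallest positive
root over the cell's surfaces (stable quadratic formula, minimum root
acceptance 1e-9 cm). After each crossing the particle advances a 1e-6
cm nudge before relocating; ties between coincident surfaces resolve by
surface order. Chord additivity along a ray therefore holds to the
nudge budget (number of crossings x 1e-6 cm) rather than to machine
precision — the nudge is deliberately excluded from the recorded
chords. A full-audit point locator (used by tests and the geometry
dump) checks *all* cells and raises an error naming any two cells that
claim the same point; assembled scenarios are audited by uniform random
sampling.

## The scenario family

The scenario builders are first-class, tested code; they are the
package's synthetic-data generator and define the study conditions.

**Room.** Main room 13.7 x 9 x 4 m inner, ordinary concrete
(2.35 g/cm^3) walls 1 m thick, air fill at 0.00129 g/cm^3, isocenter at
room center 130 cm above the floor. A 2 m wide, 2.2 m high maze
corridor runs beyond the -x wall, open to the room at one end; a
9.9 x 2 x 4 m control room adjoins via a doorway with a lead door slab.
The bunker topology (which wall, where the door sits) is shown only
pictorially in typical floor plans, so the layout here is a documented
choice; out-of-field organ doses are dominated by in-phantom scatter,
not by the room return, so this choice is weakly coupled to F.

**Phantom.** A stylized adult male in the MIRD tradition, built from
quadrics with analytic volumes: elliptic-cylinder trunk (semi-axes
20 x 10 cm, 70 cm long) and legs, ellipsoidal head, 0.2 cm skin shell,
and 12 labeled tissue regions (brain, skull+leg-bone skeleton,
cylindrical spine and esophagus, ellipsoidal lungs/heart/liver, a
transverse-cylinder colon, two testis spheres, residual soft tissue).
Densities: soft 1.04, lung 0.296, bone 1.4, skin 1.05 g/cm^3, with
standard multi-element tissue recipes. Simplifications chosen for
disjointness and closed-form volumes: lungs are full ellipsoids rather
than sectioned half-ellipsoids, the skeleton omits ribs and arms, and
the colon is a straight transverse tube. The irradiation points P1–P5
(testes, colon, liver, left lung, brain) default to the organ shape
centers, since only pictorial positions exist to copy. The beam enters
anteriorly for every target; this is configurable in principle via the
source definition.

**Beamline.** The head components sit on the beam axis below the
source point at z = 100 cm: tungsten primary collimator with a conical
aperture, aluminium window (standing in for beryllium, which the
element set omits), copper scattering foil, alumina ceramic and
aluminium alloy spacers, and tungsten upper X-jaws whose gap projects
the requested field size at the isocenter. The commercial head's
dimensions are proprietary, so these are parameterized defaults. The
default source is a generic filtered 6 MV histogram spectrum (Kramers
thin-target shape hardened through 0.4 cm W + 2 cm Al computed with the
package's own attenuation tables), emitted in a cone exactly filling
the jaw aperture; a monoenergetic 0.6616 MeV isotropic point source
reproduces the comparison-source mode. Any two-column table can replace
the spectrum.

**Concrete Si note.** The element set lacks silicon, so concrete's Si
mass fraction is carried by aluminium (adjacent Z, similar cross
sections per gram at these energies).

**Benchmark worlds.** Slab-attenuation scenarios (water slab of
optical thickness tau, pencil beam), a two-shell vacuum world for the
inverse-square fluence check, a water sphere for the estimator
cross-check, a water tank with sixty 0.5 cm central-axis bins for the
depth-dose curve (SSD 100 cm, 10 x 10 cm^2 field), and a three-organ
mini phantom (target sphere, surrounding near shell, off-axis
downstream far sphere in a tissue cylinder) whose conversion
coefficients must order as F(target) = 1 > F(near) > F(far).

What passing tests show: the transport chain agrees with closed-form
attenuation, Klein–Nishina quadrature, exact energy conservation, and
geometric fluence laws, and the full scenario machinery produces
self-consistent, deterministic, correctly ordered organ doses. What
they do not show: agreement with measured or evaluated-data organ
doses — the collision-kerma approximation, the analytic cross sections
and the parameterized head geometry each move absolute values, so
published absolute doses serve only as qualitative references here.

## Problem sizes and runtime

The shipped tests use 1e5 histories per slab case, 1e6 Klein–Nishina
draws per energy, 2e5 histories for the depth-dose curve, 1e4 for the
mini phantom, and 2e4 for the estimator cross-check; the whole suite
runs in about a minute on one core. A treatment-room run at 4e4
histories takes ~10 s and reaches a few percent relative error on the
target organ; the bundled configs are sized accordingly, and
`target_rel_error` supports running to the 0.4% convergence flag when
more precision is wanted.

## Known limitations

* Collision kerma only: no electron transport, hence no build-up and
  kerma-vs-dose differences near interfaces and in small structures.
* Analytic photoelectric/pair fits: high-Z attenuation (jaws,
  collimator, lead door) is approximate; absolute transmitted
  intensities through thick W are order-of-magnitude only.
* Free-electron Compton: no binding/Doppler effects below ~0.05 MeV.
* The phantom is stylized; organ masses are self-consistent with its
  quadric shapes, not with reference anatomical masses.
* No gantry rotation, multileaf collimation, wedges or multi-field
  plans; one beam, five anterior target positions.

## Worked example

```{r example}
library(photondose)

# transport run at the left lung, then conversion coefficients
scn <- build_treatment_scenario("P4", field_cm = 10)
res <- run(scn, run_config(n_histories = 4e4, seed = 1))
f   <- compute_conversion_coefficients(as_dose_result(res, "P4"),
                                       "left_lung")

# dispersed doses for a hyperfractionated 54 Gy / 36 fraction course
sched <- fractionation_schedule(54, 36, per_day = 3, days = 12)
apply_conversion(f, sched, "P4")
```
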