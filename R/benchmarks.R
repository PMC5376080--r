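# Analytic benchmark worlds and oracle cases: every transport claim is
# testable against a closed form or an independent quadrature, with no
# external data. The oracle expectations are computed by routines that
# share no code path with the transport kernel.

#' Slab scenario for the exponential-attenuation oracle
#'
#' A water slab of the requested optical thickness (at the given energy)
#' in an otherwise empty world, with a normal pencil beam; the uncollided
#' transmission should be e^(-tau).
#'
#' @param tau Optical thickness (mean free paths).
#' @param energy_mev Beam energy (default 1 MeV).
#' @return A \code{scenario}.
#' @export
build_slab_scenario <- function(tau, energy_mev = 1) {
  if (tau < 0) stop("tau must be >= 0")
  mu <- mu_total(material_library()$water, energy_mev)
  thick <- max(tau / mu, 1e-6)
  slab <- box_region("slab", c(-500, -500, -thick), c(500, 500, 0))
  env <- box_region("env", c(-600, -600, -50 - thick), c(600, 600, 50))
  cells <- list(
    world = csg_cell("world", rg_not(env$region), "vacuum", world = TRUE),
    void = csg_cell("void", rg_and(env$region, rg_not(slab$region)),
                    "vacuum"),
    slab = csg_cell("slab", slab$region, "water",
                    volume = 1000 * 1000 * thick))
  model <- geometry_model(c(env$surfaces, slab$surfaces), cells,
                          list(lo = c(-610, -610, -60 - thick),
                               hi = c(610, 610, 60)))
  src <- beam_source("spectrum-beam", position = c(0, 0, 10),
                     axis = c(0, 0, -1), half_angle_deg = 0,
                     spectrum = spectrum_line(energy_mev))
  structure(list(model = model, source = src, target = "slab",
                 label = sprintf("slab-tau-%g", tau), tau = tau,
                 target_organ = NA_character_),
            class = "scenario")
}

#' Slab-attenuation oracle cases
#'
#' @param taus Optical thicknesses (> 0... 0 allowed, transmission 1).
#' @return List of \code{oracle_case}: name, scenario, expectation
#'   e^(-tau), tolerance policy "3sigma".
#' @export
make_slab_oracle <- function(taus = c(0.5, 1, 5)) {
  lapply(taus, function(tau) {
    structure(list(name = sprintf("slab-tau-%g", tau),
                   scenario = build_slab_scenario(tau),
                   expectation = exp(-tau),
                   formula = "uncollided transmission exp(-tau)",
                   tolerance = "3sigma"),
              class = "oracle_case")
  })
}

#' Klein-Nishina moment oracle cases
#'
#' Expectations (mean scattered-energy fraction, mean scattering cosine,
#' minimum scattered energy) computed by adaptive quadrature of the
#' Klein-Nishina differential cross section, independent of the rejection
#' sampler they test. The quadrature's own total cross section is checked
#' against the closed form to 1e-8 relative at construction.
#'
#' @param energies Photon energies (MeV).
#' @return List of \code{oracle_case}.
#' @export
make_kn_moment_oracle <- function(energies = c(0.2, 0.5, 0.6616, 2, 6)) {
  lapply(energies, function(e) {
    mom <- kn_moments(e)
    closed <- kn_total_cross_section(e)
    if (abs(mom$sigma_cm2 - closed) / closed > 1e-8)
      stop("quadrature self-check failed at ", e, " MeV")
    structure(list(name = sprintf("kn-moments-%g", e), energy_mev = e,
                   expectation = list(
                     mean_scatter_frac = mom$mean_scatter_frac,
                     mean_cosine = mom$mean_cosine,
                     min_scatter_mev = mom$min_scatter_mev),
                   formula = "Klein-Nishina quadrature moments",
                   tolerance = "3sigma"),
              class = "oracle_case")
  })
}

#' Three-organ mini phantom scenario
#'
#' A cut-down concentric layout for fast checks: a target sphere at the
#' isocenter, a surrounding near shell, and a farther sphere downstream,
#' all soft tissue inside a tissue cylinder, irradiated by a collimated
#' 1 MeV beam. Expected ordering: F(target) = 1 > F(near) > F(far).
#'
#' @return A \code{scenario} with tally organs target/near/far.
#' @export
make_mini_phantom_scenario <- function() {
  S <- list()
  add <- function(s) S[[s$id]] <<- s
  add(surf_cylinder("mp.cyl", "z", c(0, 0), 12))
  add(surf_plane("mp.zlo", "z", -15))
  add(surf_plane("mp.zhi", "z", 10))
  add(surf_sphere("mp.target", c(0, 0, 0), 2))
  add(surf_sphere("mp.near.out", c(0, 0, 0), 4.5))
  add(surf_sphere("mp.far", c(8, 0, -10), 2))
  add(surf_sphere("mp.env", c(0, 0, 0), 300))
  cyl_rg <- rg_and(inside("mp.cyl"), outside("mp.zlo"), inside("mp.zhi"))
  sph <- function(r) 4 / 3 * pi * r^3
  cells <- list(
    world = csg_cell("world", rg_not(inside("mp.env")), "vacuum",
                     world = TRUE),
    air = csg_cell("air", rg_and(inside("mp.env"), rg_not(cyl_rg)), "air"),
    target = csg_cell("target", inside("mp.target"), "soft_tissue",
                      tally = TRUE, organ = "target", volume = sph(2)),
    near = csg_cell("near",
                    rg_and(inside("mp.near.out"),
                           rg_not(inside("mp.target"))),
                    "soft_tissue", tally = TRUE, organ = "near",
                    volume = sph(4.5) - sph(2)),
    far = csg_cell("far", inside("mp.far"), "soft_tissue", tally = TRUE,
                   organ = "far", volume = sph(2)),   # off-axis, downstream
    tissue = csg_cell("tissue",
                      rg_and(cyl_rg, rg_not(inside("mp.near.out")),
                             rg_not(inside("mp.far"))),
                      "soft_tissue"))
  model <- geometry_model(S, cells, list(lo = c(-301, -301, -301),
                                         hi = c(301, 301, 301)))
  src <- beam_source("spectrum-beam", position = c(0, 0, 50),
                     axis = c(0, 0, -1),
                     half_angle_deg = atan(2 / 50) * 180 / pi,
                     spectrum = spectrum_line(1))
  structure(list(model = model, source = src, target = "target",
                 label = "mini-phantom", target_organ = "target"),
            class = "scenario")
}

#' Vacuum inverse-square fluence scenario
#'
#' Isotropic point source at the origin with two thin spherical-shell
#' track-length tallies at 50 and 100 cm; the shell fluences must follow
#' 1/r^2 (in vacuum every history contributes the shell thickness
#' exactly, so the check is on the geometric normalization).
#'
#' @return A \code{scenario} with tally organs shell50/shell100.
#' @export
make_inverse_square_scenario <- function() {
  S <- list()
  for (r in c(49.5, 50.5, 99.5, 100.5))
    S[[paste0("is.r", r)]] <- surf_sphere(paste0("is.r", r), c(0, 0, 0), r)
  sphv <- function(r) 4 / 3 * pi * r^3
  cells <- list(
    world = csg_cell("world", rg_not(inside("is.r100.5")), "vacuum",
                     world = TRUE),
    core = csg_cell("core", inside("is.r49.5"), "vacuum"),
    shell50 = csg_cell("shell50",
                       rg_and(inside("is.r50.5"), rg_not(inside("is.r49.5"))),
                       "vacuum", tally = TRUE, organ = "shell50",
                       volume = sphv(50.5) - sphv(49.5)),
    mid = csg_cell("mid",
                   rg_and(inside("is.r99.5"), rg_not(inside("is.r50.5"))),
                   "vacuum"),
    shell100 = csg_cell("shell100",
                        rg_and(inside("is.r100.5"),
                               rg_not(inside("is.r99.5"))),
                        "vacuum", tally = TRUE, organ = "shell100",
                        volume = sphv(100.5) - sphv(99.5)))
  model <- geometry_model(S, cells, list(lo = rep(-101, 3),
                                         hi = rep(101, 3)))
  src <- beam_source("monoenergetic-point", position = c(0, 0, 0),
                     spectrum = spectrum_line(1))
  structure(list(model = model, source = src, target = "shells",
                 label = "inverse-square", target_organ = NA_character_),
            class = "scenario")
}

#' Homogeneous-water estimator cross-check scenario
#'
#' A water sphere in air under a 1 MeV pencil beam, tallied with both the
#' collision and the track-length (heating-response) estimators; the two
#' estimate the same absorbed dose and must agree within statistics.
#'
#' @return A \code{scenario} with one tally region "water".
#' @export
make_estimator_check_scenario <- function() {
  S <- list(surf_sphere("ec.sphere", c(0, 0, 0), 20),
            surf_sphere("ec.env", c(0, 0, 0), 100))
  names(S) <- c("ec.sphere", "ec.env")
  cells <- list(
    world = csg_cell("world", rg_not(inside("ec.env")), "vacuum",
                     world = TRUE),
    air = csg_cell("air", rg_and(inside("ec.env"),
                                 rg_not(inside("ec.sphere"))), "air"),
    water = csg_cell("water", inside("ec.sphere"), "water", tally = TRUE,
                     organ = "water", volume = 4 / 3 * pi * 20^3))
  model <- geometry_model(S, cells, list(lo = rep(-101, 3),
                                         hi = rep(101, 3)))
  src <- beam_source("spectrum-beam", position = c(0, 0, 50),
                     axis = c(0, 0, -1), half_angle_deg = 0,
                     spectrum = spectrum_line(1))
  structure(list(model = model, source = src, target = "water",
                 label = "estimator-check", target_organ = NA_character_),
            class = "scenario")
}

#' List the built-in benchmark cases
#' @return Character vector of benchmark names.
#' @export
list_benchmarks <- function() {
  c(vapply(make_slab_oracle(), `[[`, "", "name"),
    vapply(make_kn_moment_oracle(), `[[`, "", "name"),
    "inverse-square", "mini-phantom-F", "estimator-agreement")
}

#' Run one benchmark case
#'
#' Executes the named case and compares the observation with its oracle
#' expectation; statistical cases pass within 3 sigma.
#'
#' @param name A name from \code{list_benchmarks()}.
#' @param n_histories Histories (statistical cases).
#' @param seed RNG seed.
#' @return list(name, observed, expected, sigma, pass).
#' @export
run_benchmark <- function(name, n_histories = 1e4, seed = 1) {
  slabs <- make_slab_oracle()
  kns <- make_kn_moment_oracle()
  slab_names <- vapply(slabs, `[[`, "", "name")
  kn_names <- vapply(kns, `[[`, "", "name")
  if (name %in% slab_names) {
    case <- slabs[[match(name, slab_names)]]
    res <- run(case$scenario,
               run_config(n_histories, n_batches = 10, seed = seed,
                          analog = TRUE))
    obs <- res$totals$uncollided / res$totals$n_histories
    sig <- sqrt(case$expectation * (1 - case$expectation) / n_histories)
    return(list(name = name, observed = obs, expected = case$expectation,
                sigma = sig, pass = abs(obs - case$expectation) <= 3 * sig))
  }
  if (name %in% kn_names) {
    case <- kns[[match(name, kn_names)]]
    s <- sample_compton(case$energy_mev, n = n_histories, seed = seed)
    obs <- mean(s$scattered_mev) / case$energy_mev
    sig <- stats::sd(s$scattered_mev / case$energy_mev) / sqrt(n_histories)
    exp_ <- case$expectation$mean_scatter_frac
    return(list(name = name, observed = obs, expected = exp_, sigma = sig,
                pass = abs(obs - exp_) <= 3 * sig &&
                  min(s$scattered_mev) >=
                    case$expectation$min_scatter_mev - 1e-12))
  }
  if (name == "inverse-square") {
    res <- run(make_inverse_square_scenario(),
               run_config(n_histories, n_batches = 10, seed = seed,
                          analog = TRUE))
    fl <- res$cell_track_per_photon / res$cell_volume
    obs <- fl[["shell50"]] / fl[["shell100"]]
    return(list(name = name, observed = obs, expected = 4,
                sigma = 0.02 / 3,   # geometric shell-thickness tolerance
                pass = abs(obs - 4) <= 0.02))
  }
  if (name == "mini-phantom-F") {
    res <- run(make_mini_phantom_scenario(),
               run_config(n_histories, n_batches = 10, seed = seed))
    f <- compute_conversion_coefficients(as_dose_result(res, "mini"),
                                         "target")
    fo <- stats::setNames(f$F, f$organ)
    return(list(name = name,
                observed = fo[c("target", "near", "far")],
                expected = "F(target)=1, F monotone in distance",
                sigma = NA,
                pass = fo[["target"]] == 1 && fo[["near"]] > fo[["far"]]))
  }
  if (name == "estimator-agreement") {
    res <- run(make_estimator_check_scenario(),
               run_config(n_histories, n_batches = 10, seed = seed,
                          analog = TRUE))
    # the two estimators share histories, so test the per-batch difference
    dd <- res$batch_means[, "water"] - res$batch_means_tl[, "water"]
    sig <- stats::sd(dd) / sqrt(length(dd))
    d <- res$doses[1, ]
    return(list(name = name, observed = d$dose_mev_g,
                expected = d$dose_tl_mev_g, sigma = sig / d$mass_g,
                pass = abs(mean(dd)) <= 3 * sig))
  }
  stop("unknown benchmark: ", name)
}
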