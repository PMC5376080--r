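# Interaction sampling and photon-state plumbing. The same Klein-Nishina
# rejection sampler used inside the transport kernel is exposed here; the
# quadrature moments in kn_moments() are an independent numerical route
# used for heating responses and as the oracle in tests.

#' Construct a photon state
#'
#' @param position Length-3 position (cm).
#' @param direction Unit vector (|u| = 1 within 1e-9).
#' @param energy Energy in MeV (> 0).
#' @param weight Statistical weight (>= 0).
#' @return A \code{photon_state}.
#' @export
photon_state <- function(position, direction, energy, weight = 1) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be a unit vector")
  if (energy <= 0) stop("energy must be positive")
  if (weight < 0) stop("weight must be non-negative")
  structure(list(position = as.numeric(position),
                 direction = as.numeric(direction),
                 energy = energy, weight = weight, alive = TRUE),
            class = "photon_state")
}

#' Sample exponential free paths
#'
#' @param mat A \code{material} with mu > 0 at \code{energy_mev}.
#' @param energy_mev Photon energy (MeV).
#' @param n Number of draws.
#' @return Path lengths in cm, exponentially distributed with mean 1/mu.
#' @export
sample_free_path <- function(mat, energy_mev, n = 1) {
  mu <- mu_total(mat, energy_mev)
  if (mu <= 0) stop("mu must be positive to sample a free path")
  stats::rexp(n, rate = mu)
}

#' Sample the interaction type at a collision
#'
#' Draws photoelectric / compton / pair proportional to the partial
#' macroscopic cross sections. Pair has zero probability below 1.022 MeV
#' by construction of the library threshold.
#'
#' @param mat A \code{material}.
#' @param energy_mev Photon energy (MeV).
#' @param n Number of draws.
#' @return Character vector of interaction tags.
#' @export
sample_interaction <- function(mat, energy_mev, n = 1) {
  p <- c(photoelectric = mu_total(mat, energy_mev, "photoelectric"),
         compton = mu_total(mat, energy_mev, "incoherent"),
         pair = mu_total(mat, energy_mev, "pair"))
  if (sum(p) <= 0) stop("all partial cross-sections are zero")
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Sample Klein-Nishina Compton scattering
#'
#' Free-electron Klein-Nishina sampling of the scattering cosine; the
#' scattered energy follows the Compton relation
#' E' = E / (1 + (E/0.511)(1 - cos theta)) and the electron energy E - E'
#' is the locally deposited share.
#'
#' @param energy_mev Incident photon energy (MeV).
#' @param n Number of draws.
#' @param seed Stream seed for the deterministic sampler.
#' @return data.frame(scattered_mev, cosine, deposited_mev).
#' @export
sample_compton <- function(energy_mev, n = 1, seed = 1) {
  if (energy_mev <= 0) stop("energy must be positive")
  m <- cpp_kn_sample(energy_mev, as.integer(n), as.numeric(seed))
  data.frame(scattered_mev = m[, 1], cosine = m[, 2],
             deposited_mev = energy_mev - m[, 1])
}

#' Sample a pair-production event
#'
#' Local-electron-deposition model: E - 1.022 MeV is deposited at the
#' interaction site and two back-to-back 0.511 MeV annihilation photons
#' are emitted isotropically.
#'
#' @param energy_mev Incident energy (MeV), >= 1.022.
#' @param n Number of draws.
#' @return data.frame(deposited_mev, ux, uy, uz) — the second photon's
#'   direction is the negation of (ux, uy, uz).
#' @export
sample_pair <- function(energy_mev, n = 1) {
  if (energy_mev < PAIR_THRESHOLD_MEV)
    stop("pair production requires E >= 1.022 MeV")
  mu <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - mu^2)
  data.frame(deposited_mev = rep(energy_mev - PAIR_THRESHOLD_MEV, n),
             ux = s * cos(phi), uy = s * sin(phi), uz = mu)
}

#' Klein-Nishina angular moments by adaptive quadrature
#'
#' Numerically integrates the Klein-Nishina differential cross section to
#' obtain the mean scattered-energy fraction, the mean scattering cosine,
#' and the total cross section; independent of the rejection sampler.
#'
#' @param energy_mev Photon energy (MeV).
#' @return list(mean_scatter_frac, mean_cosine, sigma_cm2,
#'   min_scatter_mev).
#' @export
kn_moments <- function(energy_mev) {
  k <- energy_mev / ELECTRON_REST_MEV
  dens <- function(mu) {           # dsigma/dmu up to 2 pi r_e^2 / 2
    r <- 1 / (1 + k * (1 - mu))
    r^3 + r - r^2 * (1 - mu^2)
  }
  z <- stats::integrate(dens, -1, 1, rel.tol = 1e-10)$value
  mf <- stats::integrate(function(mu) dens(mu) / (1 + k * (1 - mu)),
                         -1, 1, rel.tol = 1e-10)$value / z
  mc <- stats::integrate(function(mu) mu * dens(mu), -1, 1,
                         rel.tol = 1e-10)$value / z
  list(mean_scatter_frac = mf,
       mean_cosine = mc,
       sigma_cm2 = pi * CLASSICAL_ELECTRON_RADIUS_CM^2 * z,
       min_scatter_mev = energy_mev / (1 + 2 * k))
}

# Heating response kappa(E) = mu_pe E + mu_inc E (1 - mean scattered
# fraction) + mu_pair (E - 1.022), the expected locally deposited energy
# per unit track length; used by the track-length estimator.
material_heating <- function(mat, energy_mev, mean_dep_frac) {
  mu_total(mat, energy_mev, "photoelectric") * energy_mev +
    mu_total(mat, energy_mev, "incoherent") * energy_mev * mean_dep_frac +
    mu_total(mat, energy_mev, "pair") *
      pmax(0, energy_mev - PAIR_THRESHOLD_MEV)
}
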