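# Materials: elemental compositions, densities, and macroscopic
# attenuation coefficients assembled from the elemental library by the
# standard mass-fraction mixture rule.

#' Define a material
#'
#' @param name Material label.
#' @param density Bulk density in g/cm^3 (0 allowed only for vacuum).
#' @param composition Named numeric vector of elemental mass fractions;
#'   must sum to 1 within 1e-6 and use elements present in the library.
#' @return A \code{material} object. \code{$atom_density} is the total atom
#'   density in atoms/(barn cm).
#' @export
material <- function(name, density, composition = numeric()) {
  if (length(composition) == 0) {
    if (density != 0) stop("empty composition is only valid for vacuum")
  } else {
    if (density <= 0) stop("density must be > 0")
    if (abs(sum(composition) - 1) > 1e-6)
      stop("mass fractions must sum to 1 (got ", sum(composition), ")")
    unknown <- setdiff(names(composition), XS_ELEMENTS$symbol)
    if (length(unknown))
      stop("elements not in cross-section library: ",
           paste(unknown, collapse = ", "))
  }
  atom_density <- 0
  if (length(composition)) {
    A <- XS_ELEMENTS$A[match(names(composition), XS_ELEMENTS$symbol)]
    atom_density <- density * AVOGADRO * sum(composition / A) * 1e-24
  }
  structure(list(name = name, density = density,
                 composition = composition, atom_density = atom_density),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  rho = %g g/cm^3\n", x$name, x$density))
  if (length(x$composition))
    cat("  ", paste(sprintf("%s %.4f", names(x$composition), x$composition),
                    collapse = "  "), "\n")
  invisible(x)
}

#' Built-in material library
#'
#' Elemental compositions follow standard tissue/shielding recipes,
#' restricted to the elements carried by the photo-atomic library (silicon
#' in concrete is folded into aluminium; the accelerator vacuum window is
#' aluminium rather than beryllium).
#'
#' @return Named list of \code{material} objects.
#' @export
material_library <- function() {
  norm <- function(x) x / sum(x)
  list(
    vacuum = material("vacuum", 0),
    air = material("air", 0.00129,
                   norm(c(C = 0.000124, N = 0.755, O = 0.2318, Ar = 0.0128))),
    water = material("water", 1.0, norm(c(H = 0.111894, O = 0.888106))),
    soft_tissue = material("soft_tissue", 1.04,
      norm(c(H = 0.1047, C = 0.2302, N = 0.0234, O = 0.6321, Na = 0.0013,
             P = 0.0024, S = 0.0022, Cl = 0.0014, K = 0.0021))),
    lung_tissue = material("lung_tissue", 0.296,
      norm(c(H = 0.1021, C = 0.1001, N = 0.028, O = 0.7596, Na = 0.0019,
             P = 0.0008, S = 0.0023, Cl = 0.0027, K = 0.0020))),
    bone = material("bone", 1.4,
      norm(c(H = 0.0704, C = 0.2279, N = 0.0387, O = 0.4856, Na = 0.0032,
             Mg = 0.0011, P = 0.0694, S = 0.0017, Cl = 0.0014, K = 0.0015,
             Ca = 0.0991))),
    skin = material("skin", 1.05,
      norm(c(H = 0.1006, C = 0.2288, N = 0.0464, O = 0.6194, Na = 0.0007,
             P = 0.0008, S = 0.0019, Cl = 0.0014))),
    concrete = material("concrete", 2.35,
      # ordinary concrete; Si share carried by Al (adjacent Z)
      norm(c(H = 0.010, C = 0.001, O = 0.529, Na = 0.016, Mg = 0.002,
             Al = 0.372, K = 0.013, Ca = 0.044, Fe = 0.013))),
    tungsten = material("tungsten", 19.3, c(W = 1)),
    copper = material("copper", 8.96, c(Cu = 1)),
    aluminum = material("aluminum", 2.699, c(Al = 1)),
    alumina = material("alumina", 3.9, norm(c(Al = 0.5293, O = 0.4707))),
    carbon_fiber = material("carbon_fiber", 1.6, c(C = 1)),
    lead = material("lead", 11.35, c(Pb = 1))
  )
}

# Mass coefficient (cm^2/g) of one partial for a material at given energies.
material_mu_rho <- function(mat, energy_mev, column = "total_cm2g",
                            library = xs_library()) {
  if (length(mat$composition) == 0) return(rep(0, length(energy_mev)))
  out <- rep(0, length(energy_mev))
  for (el in names(mat$composition))
    out <- out + mat$composition[[el]] *
      xs_interp(library[[el]], energy_mev, column)
  out
}

#' Linear attenuation coefficient of a material
#'
#' Density times the mass-fraction-weighted sum of elemental mu/rho,
#' log-log interpolated on the library grid. Energies outside the grid are
#' an error (no silent extrapolation).
#'
#' @param mat A \code{material}.
#' @param energy_mev Photon energies in MeV.
#' @param partial One of "total", "photoelectric", "incoherent", "pair".
#' @return Linear attenuation coefficient(s) in cm^-1.
#' @export
mu_total <- function(mat, energy_mev, partial = "total") {
  if (partial == "total") {
    # interpolate the partials and sum, so partials add to the total at
    # every energy, not only on grid points
    return(mu_total(mat, energy_mev, "photoelectric") +
             mu_total(mat, energy_mev, "incoherent") +
             mu_total(mat, energy_mev, "pair"))
  }
  col <- switch(partial,
                photoelectric = "pe_cm2g",
                incoherent = "incoh_cm2g",
                pair = "pair_cm2g",
                stop("unknown partial: ", partial))
  mat$density * material_mu_rho(mat, energy_mev, col)
}
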