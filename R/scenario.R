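# Scenario builders: stylized adult male phantom, shielded treatment room
# with maze and control room, 6 MV accelerator head, couch, and beam
# sources, assembled into one geometry model with tally regions.
#
# Coordinates: right-handed, origin at the accelerator isocenter, z
# vertical (the beam travels -z toward the couch), units cm. The phantom
# is supine with its body axis along y (+y toward the head) and its
# anterior surface facing +z; aiming at a target organ translates the
# phantom so the chosen irradiation point sits at the isocenter, 100 cm
# below the source.

SOURCE_TO_ISOCENTER_CM <- 100

# Volume of the ellipsoid slice t1..t2 (fractions of the axial semi-axis
# b_ax) for lateral semi-axes a and c: pi a c b [t - t^3/3].
ellipsoid_zone_volume <- function(a, b_ax, c, t1, t2) {
  f <- function(t) t - t^3 / 3
  pi * a * c * b_ax * (f(t2) - f(t1))
}

# ---------------------------------------------------------------- phantom ---

#' Default stylized-phantom parameters
#'
#' Semi-axes, extents and organ centers (cm) of the package's documented
#' stylized adult male, in the phantom frame (origin mid-hip, body axis
#' +y toward the head, anterior +z). All organs are quadric shapes with
#' analytic volumes.
#' @return Named list of parameters.
#' @export
phantom_params <- function() {
  list(
    trunk_semi = c(20, 10), trunk_y = c(0, 70),
    legs_semi = c(18, 9), legs_y = c(-80, 0),
    head_center_y = 78, head_semi = c(7.5, 9.5, 9.5), head_cut_y = 70,
    skin_thickness = 0.2,
    brain_center = c(0, 78, 1), brain_semi = c(5.5, 7.5, 6),
    skull_semi = c(6.3, 8.3, 6.8),
    spine_center_xz = c(0, -6.5), spine_r = 1.5, spine_y = c(18, 70),
    eso_center_xz = c(0, -3), eso_r = 0.8, eso_y = c(38, 70),
    lung_center = c(9, 47, 1.5), lung_semi = c(4.2, 11, 5),
    heart_center = c(1, 43, 3), heart_semi = c(3.2, 4.5, 3.5),
    liver_center = c(-7, 29, 1), liver_semi = c(8, 6, 5),
    colon_center_yz = c(16, 2), colon_r = 2.5, colon_x = c(-9, 9),
    testis_r = 1.9, testis_centers = list(c(2, -3.5, 4), c(-2, -3.5, 4)),
    legbone_r = 2.5, legbone_x = 8, legbone_y = c(-78, -2),
    densities = c(soft = 1.04, lung = 0.296, bone = 1.4, skin = 1.05)
  )
}

#' Irradiation points P1..P5 in the phantom frame
#'
#' P1 testes, P2 colon, P3 liver, P4 left lung, P5 brain; defaults are the
#' organ centroids (centers of the quadric shapes).
#' @param params Phantom parameter list.
#' @return Named list of length-3 positions (cm).
#' @export
irradiation_points <- function(params = phantom_params()) {
  list(P1 = params$testis_centers[[1]],
       P2 = c(mean(params$colon_x), params$colon_center_yz),
       P3 = params$liver_center,
       P4 = params$lung_center,
       P5 = params$brain_center)
}

#' Build the stylized phantom geometry fragment
#'
#' Returns the surfaces, cells (12 labeled tissue regions), analytic
#' per-organ volumes/masses, and the body-envelope region used to carve
#' the surrounding air.
#'
#' @param params Parameter list from \code{phantom_params()}.
#' @param offset Length-3 translation of the phantom frame into world
#'   coordinates (set by \code{aim_beam}).
#' @return list(surfaces, cells, envelope_region, organs, points).
#' @export
build_phantom <- function(params = phantom_params(), offset = c(0, 0, 0)) {
  p <- params
  off <- offset
  t <- p$skin_thickness
  S <- list()
  add <- function(s) S[[s$id]] <<- s

  ec <- function(id, semi, grow = 0)   # body-section elliptic cylinder
    surf_cylinder(id, "y", c(off[1], off[3]), semi + grow)
  add(ec("ph.trunk", p$trunk_semi))
  add(ec("ph.trunk.o", p$trunk_semi, t))
  add(ec("ph.legs", p$legs_semi))
  add(ec("ph.legs.o", p$legs_semi, t))
  add(surf_ellipsoid("ph.head", off + c(0, p$head_center_y, 0), p$head_semi))
  add(surf_ellipsoid("ph.head.o", off + c(0, p$head_center_y, 0),
                     p$head_semi + t))
  yp <- function(id, at) surf_plane(id, "y", off[2] + at)
  add(yp("ph.y0", 0)); add(yp("ph.y70", p$trunk_y[2]))
  add(yp("ph.ylegs", p$legs_y[1]))
  add(yp("ph.y0o.lo", -t)); add(yp("ph.y70o.hi", p$trunk_y[2] + t))
  add(yp("ph.ylegso", p$legs_y[1] - t)); add(yp("ph.y0o.hi", t))
  add(surf_ellipsoid("ph.brain", off + p$brain_center, p$brain_semi))
  add(surf_ellipsoid("ph.skull", off + p$brain_center, p$skull_semi))
  add(surf_cylinder("ph.spine", "y", off[c(1, 3)] + p$spine_center_xz,
                    p$spine_r))
  add(yp("ph.spine.lo", p$spine_y[1]))
  add(surf_cylinder("ph.eso", "y", off[c(1, 3)] + p$eso_center_xz, p$eso_r))
  add(yp("ph.eso.lo", p$eso_y[1]))
  lc <- p$lung_center
  add(surf_ellipsoid("ph.lungL", off + lc, p$lung_semi))
  add(surf_ellipsoid("ph.lungR", off + c(-lc[1], lc[2], lc[3]), p$lung_semi))
  add(surf_ellipsoid("ph.heart", off + p$heart_center, p$heart_semi))
  add(surf_ellipsoid("ph.liver", off + p$liver_center, p$liver_semi))
  add(surf_cylinder("ph.colon", "x", off[c(2, 3)] + p$colon_center_yz,
                    p$colon_r))
  add(surf_plane("ph.colon.lo", "x", off[1] + p$colon_x[1]))
  add(surf_plane("ph.colon.hi", "x", off[1] + p$colon_x[2]))
  add(surf_sphere("ph.tesL", off + p$testis_centers[[1]], p$testis_r))
  add(surf_sphere("ph.tesR", off + p$testis_centers[[2]], p$testis_r))
  add(surf_cylinder("ph.boneL", "y", c(off[1] + p$legbone_x, off[3]),
                    p$legbone_r))
  add(surf_cylinder("ph.boneR", "y", c(off[1] - p$legbone_x, off[3]),
                    p$legbone_r))
  add(yp("ph.bone.lo", p$legbone_y[1])); add(yp("ph.bone.hi", p$legbone_y[2]))

  # section regions (exact partition of the body interior)
  trunk_rg <- rg_and(inside("ph.trunk"), outside("ph.y0"), inside("ph.y70"))
  legs_rg <- rg_and(inside("ph.legs"), outside("ph.ylegs"), inside("ph.y0"))
  head_rg <- rg_and(inside("ph.head"), outside("ph.y70"))
  body_inner <- rg_or(trunk_rg, legs_rg, head_rg)
  body_outer <- rg_or(
    rg_and(inside("ph.trunk.o"), outside("ph.y0o.lo"), inside("ph.y70o.hi")),
    rg_and(inside("ph.legs.o"), outside("ph.ylegso"), inside("ph.y0o.hi")),
    rg_and(inside("ph.head.o"), outside("ph.y70")))

  spine_rg <- rg_and(inside("ph.spine"), outside("ph.spine.lo"),
                     inside("ph.y70"))
  eso_rg <- rg_and(inside("ph.eso"), outside("ph.eso.lo"), inside("ph.y70"))
  colon_rg <- rg_and(inside("ph.colon"), outside("ph.colon.lo"),
                     inside("ph.colon.hi"))
  testes_rg <- rg_or(inside("ph.tesL"), inside("ph.tesR"))
  bones_rg <- rg_and(rg_or(inside("ph.boneL"), inside("ph.boneR")),
                     outside("ph.bone.lo"), inside("ph.bone.hi"))
  skull_rg <- rg_and(inside("ph.skull"), rg_not(inside("ph.brain")))
  skeleton_rg <- rg_or(bones_rg, skull_rg)

  organ_rgs <- list(
    brain = inside("ph.brain"),
    spine = spine_rg,
    esophagus = eso_rg,
    left_lung = inside("ph.lungL"),
    right_lung = inside("ph.lungR"),
    heart = inside("ph.heart"),
    liver = inside("ph.liver"),
    colon = colon_rg,
    testes = testes_rg,
    skeleton = skeleton_rg)

  # analytic volumes (cm^3)
  ell <- function(s) 4 / 3 * pi * prod(s)
  zone <- function(semi, y_from, center_y)
    ellipsoid_zone_volume(semi[1], semi[2], semi[3],
                          (y_from - center_y) / semi[2], 1)
  v_inner <- pi * prod(p$trunk_semi) * diff(p$trunk_y) +
    pi * prod(p$legs_semi) * diff(p$legs_y) +
    zone(p$head_semi, p$head_cut_y, p$head_center_y)
  v_outer <- pi * prod(p$trunk_semi + t) * (diff(p$trunk_y) + 2 * t) +
    pi * prod(p$legs_semi + t) * (diff(p$legs_y) + 2 * t) +
    zone(p$head_semi + t, p$head_cut_y, p$head_center_y) -
    pi * prod(p$legs_semi + t) * (2 * t) -                      # trunk_o/legs_o
    ellipsoid_zone_volume(p$head_semi[1] + t, p$head_semi[2] + t,
                          p$head_semi[3] + t,
                          (p$head_cut_y - p$head_center_y) /
                            (p$head_semi[2] + t),
                          (p$head_cut_y + t - p$head_center_y) /
                            (p$head_semi[2] + t))               # trunk_o/head_o
  vols <- c(
    brain = ell(p$brain_semi),
    spine = pi * p$spine_r^2 * diff(p$spine_y),
    esophagus = pi * p$eso_r^2 * diff(p$eso_y),
    left_lung = ell(p$lung_semi),
    right_lung = ell(p$lung_semi),
    heart = ell(p$heart_semi),
    liver = ell(p$liver_semi),
    colon = pi * p$colon_r^2 * diff(p$colon_x),
    testes = 2 * 4 / 3 * pi * p$testis_r^3,
    skeleton = 2 * pi * p$legbone_r^2 * diff(p$legbone_y) +
      ell(p$skull_semi) - ell(p$brain_semi))
  vols["skin"] <- v_outer - v_inner
  vols["residual"] <- v_inner - sum(vols[names(organ_rgs)])

  d <- p$densities
  mats <- c(brain = "soft_tissue", spine = "bone", esophagus = "soft_tissue",
            left_lung = "lung_tissue", right_lung = "lung_tissue",
            heart = "soft_tissue", liver = "soft_tissue",
            colon = "soft_tissue", testes = "soft_tissue",
            skeleton = "bone", skin = "skin", residual = "soft_tissue")
  dens <- c(brain = d[["soft"]], spine = d[["bone"]],
            esophagus = d[["soft"]], left_lung = d[["lung"]],
            right_lung = d[["lung"]], heart = d[["soft"]],
            liver = d[["soft"]], colon = d[["soft"]], testes = d[["soft"]],
            skeleton = d[["bone"]], skin = d[["skin"]],
            residual = d[["soft"]])

  cells <- list()
  for (org in names(organ_rgs))
    cells[[org]] <- csg_cell(paste0("phantom.", org), organ_rgs[[org]],
                             mats[[org]], tally = TRUE, organ = org,
                             volume = vols[[org]])
  cells$skin <- csg_cell("phantom.skin",
                         rg_and(body_outer, rg_not(body_inner)),
                         "skin", tally = TRUE, organ = "skin",
                         volume = vols[["skin"]])
  not_organs <- lapply(organ_rgs[setdiff(names(organ_rgs), "skeleton")],
                       rg_not)
  residual_rg <- do.call(rg_and, c(list(body_inner),
                                   list(rg_not(inside("ph.skull"))),
                                   not_organs[names(not_organs) != "brain"],
                                   list(rg_not(bones_rg))))
  cells$residual <- csg_cell("phantom.residual", residual_rg, "soft_tissue",
                             tally = TRUE, organ = "residual",
                             volume = vols[["residual"]])

  if (any(vols <= 0)) stop("non-positive organ volume in phantom build")

  pts <- lapply(irradiation_points(p), function(q) q + off)
  list(surfaces = S, cells = cells, envelope_region = body_outer,
       organs = data.frame(organ = names(vols),
                           material = mats[names(vols)],
                           density = dens[names(vols)],
                           volume_cm3 = as.numeric(vols[names(vols)]),
                           mass_g = as.numeric(vols[names(vols)]) *
                             dens[names(vols)],
                           row.names = NULL, stringsAsFactors = FALSE),
       points = pts, params = p, offset = off)
}

# ------------------------------------------------------------------- room ---

#' Default treatment-room parameters (cm)
#'
#' Inner main room 13.7 x 9 x 4 m, maze 2.2 m high x 2 m wide, control
#' room 9.9 x 2 x 4 m, ordinary-concrete walls (default 1 m thick), air
#' fill at 0.00129 g/cm^3. The isocenter sits at room center, 130 cm
#' above the floor.
#' @return Named list.
#' @export
room_params <- function() {
  list(main = list(x = c(-685, 685), y = c(-450, 450), z = c(-130, 270)),
       wall_thickness = 100,
       # 2 m wide corridor beyond the -x wall, open to the room at one end
       maze = list(x = c(-985, -785), y = c(-450, 450), z = c(-130, 90)),
       maze_opening = list(x = c(-785, -685), y = c(250, 450),
                           z = c(-130, 90)),
       control = list(x = c(-985, 5), y = c(-750, -550), z = c(-130, 270)),
       doorway = list(x = c(-935, -835), y = c(-550, -450), z = c(-130, 80)),
       door_y = c(-505, -500))
}

#' Build the shielded treatment-room geometry fragment
#'
#' @param params Parameter list from \code{room_params()}.
#' @return list(surfaces, cells_fixed, main_region, outer_box_region,
#'   bounding_box). The main-room air cell is assembled later so occupant
#'   envelopes (phantom, couch, accelerator head) can be carved out.
#' @export
build_room <- function(params = room_params()) {
  pr <- params
  w <- pr$wall_thickness
  S <- list()
  boxes <- list()
  mk <- function(name, b) {
    br <- box_region(paste0("room.", name),
                     c(b$x[1], b$y[1], b$z[1]), c(b$x[2], b$y[2], b$z[2]))
    S[names(br$surfaces)] <<- br$surfaces
    boxes[[name]] <<- br$region
  }
  mk("main", pr$main)
  mk("maze", pr$maze)
  mk("mzop", pr$maze_opening)
  mk("ctrl", pr$control)
  mk("dway", pr$doorway)
  mk("door", list(x = pr$doorway$x, y = pr$door_y, z = pr$doorway$z))
  outer <- list(
    x = c(min(pr$maze$x[1], pr$control$x[1]) - w, pr$main$x[2] + w),
    y = c(pr$control$y[1] - w, pr$main$y[2] + w),
    z = c(pr$main$z[1] - w, pr$main$z[2] + w))
  mk("outer", outer)

  maze_rg <- rg_or(boxes$maze, boxes$mzop)
  dway_air <- rg_and(boxes$dway, rg_not(boxes$door))
  cavities <- rg_or(boxes$main, maze_rg, boxes$ctrl, boxes$dway)
  cells <- list(
    world = csg_cell("world", rg_not(boxes$outer), "vacuum", world = TRUE),
    concrete = csg_cell("room.concrete",
                        rg_and(boxes$outer, rg_not(cavities)), "concrete"),
    maze_air = csg_cell("room.maze_air", maze_rg, "air"),
    control_air = csg_cell("room.control_air", boxes$ctrl, "air"),
    doorway_air = csg_cell("room.doorway_air", dway_air, "air"),
    door = csg_cell("room.door", boxes$door, "lead"))
  bb <- list(lo = c(outer$x[1], outer$y[1], outer$z[1]) - 10,
             hi = c(outer$x[2], outer$y[2], outer$z[2]) + 10)
  list(surfaces = S, cells_fixed = cells, main_region = boxes$main,
       outer_box = outer, bounding_box = bb, params = pr)
}

#' Inner volumes of the room model (m^3)
#' @param params Room parameters.
#' @return Named vector: main, control (analytic, from the cell extents).
#' @export
room_volumes_m3 <- function(params = room_params()) {
  v <- function(b) prod(diff(b$x), diff(b$y), diff(b$z)) / 1e6
  c(main = v(params$main), control = v(params$control))
}

# -------------------------------------------------------------- beam line ---

#' Default accelerator-head parameters (cm)
#'
#' Component stack below the photon source point at z = 100: tungsten
#' primary collimator with a conical aperture, aluminium vacuum window,
#' copper scattering foil, alumina and aluminium spacers, tungsten upper
#' X-jaws. Dimensions are parameterized defaults (the commercial head is
#' proprietary); the housing cylinder bounds the head air.
#' @return Named list.
#' @export
beamline_params <- function() {
  list(source_z = 100,
       housing = list(r = 20, z = c(69, 101)),
       collimator = list(r = 8, z = c(92, 98), aperture_tan = 0.2),
       window = list(r = 5, z = c(90.5, 91), material = "aluminum"),
       foil = list(r = 3, z = c(89.8, 89.9), material = "copper"),
       ceramic = list(r = 5, z = c(88, 88.5), material = "alumina"),
       alloy = list(r = 5, z = c(86, 86.5), material = "aluminum"),
       jaws = list(half_extent = 15, z = c(70, 78)))
}

#' Build the accelerator-head geometry fragment
#'
#' @param field_cm Side of the square field at the isocenter plane (cm);
#'   the upper X-jaws open to project this field from the source point.
#' @param params Head parameters.
#' @return list(surfaces, cells, housing_region).
#' @export
build_beamline <- function(field_cm = 10, params = beamline_params()) {
  bp <- params
  if (field_cm <= 0) stop("field size must be positive")
  S <- list()
  add <- function(s) S[[s$id]] <<- s
  zp <- function(id, at) surf_plane(id, "z", at)
  disc <- function(name, r, zr) {
    add(surf_cylinder(paste0("bl.", name, ".cyl"), "z", c(0, 0), r))
    add(zp(paste0("bl.", name, ".lo"), zr[1]))
    add(zp(paste0("bl.", name, ".hi"), zr[2]))
    rg_and(inside(paste0("bl.", name, ".cyl")),
           outside(paste0("bl.", name, ".lo")),
           inside(paste0("bl.", name, ".hi")))
  }
  housing <- disc("housing", bp$housing$r, bp$housing$z)
  coll_disc <- disc("coll", bp$collimator$r, bp$collimator$z)
  add(surf_cone("bl.cone", "z", c(0, 0, bp$source_z),
                bp$collimator$aperture_tan))
  coll_rg <- rg_and(coll_disc, outside("bl.cone"))
  window_rg <- disc("window", bp$window$r, bp$window$z)
  foil_rg <- disc("foil", bp$foil$r, bp$foil$z)
  ceramic_rg <- disc("ceramic", bp$ceramic$r, bp$ceramic$z)
  alloy_rg <- disc("alloy", bp$alloy$r, bp$alloy$z)

  jz <- bp$jaws$z
  gap <- field_cm / 2 *
    (bp$source_z - mean(jz)) / bp$source_z     # flat jaws, mid-plane match
  he <- bp$jaws$half_extent
  add(surf_plane("bl.jaw.gapL", "x", gap))
  add(surf_plane("bl.jaw.gapR", "x", -gap))
  add(surf_plane("bl.jaw.xhi", "x", he))
  add(surf_plane("bl.jaw.xlo", "x", -he))
  add(surf_plane("bl.jaw.yhi", "y", he))
  add(surf_plane("bl.jaw.ylo", "y", -he))
  add(zp("bl.jaw.zlo", jz[1])); add(zp("bl.jaw.zhi", jz[2]))
  jaw_band <- rg_and(outside("bl.jaw.ylo"), inside("bl.jaw.yhi"),
                     outside("bl.jaw.zlo"), inside("bl.jaw.zhi"))
  jawL <- rg_and(jaw_band, outside("bl.jaw.gapL"), inside("bl.jaw.xhi"))
  jawR <- rg_and(jaw_band, outside("bl.jaw.xlo"), inside("bl.jaw.gapR"))
  jaws_rg <- rg_or(jawL, jawR)

  parts <- list(collimator = list(coll_rg, "tungsten"),
                window = list(window_rg, bp$window$material),
                foil = list(foil_rg, bp$foil$material),
                ceramic = list(ceramic_rg, bp$ceramic$material),
                alloy = list(alloy_rg, bp$alloy$material),
                jaws = list(jaws_rg, "tungsten"))
  cells <- list()
  for (nm in names(parts))
    cells[[nm]] <- csg_cell(paste0("beamline.", nm), parts[[nm]][[1]],
                            parts[[nm]][[2]])
  head_air <- do.call(rg_and, c(list(housing),
                                lapply(parts, function(x) rg_not(x[[1]]))))
  cells$head_air <- csg_cell("beamline.head_air", head_air, "air")
  list(surfaces = S, cells = cells, housing_region = housing,
       params = bp, field_cm = field_cm)
}

# ---------------------------------------------------------------- sources ---

#' Single-line photon spectrum
#' @param energy_mev Line energy (MeV). @export
spectrum_line <- function(energy_mev) {
  stopifnot(energy_mev > 0, energy_mev <= XS_EMAX)
  structure(list(mode = "lines", energies = energy_mev, probs = 1),
            class = "beam_spectrum")
}

#' Tabulated photon spectrum
#'
#' Either discrete lines (\code{energies} + \code{probs}) or histogram
#' bins (\code{edges} of length n+1 + \code{probs} of length n; sampling
#' is uniform within a bin). Probabilities are normalized to unit sum.
#' @param energies,edges,probs Numeric vectors (MeV, unitless weights).
#' @export
spectrum_table <- function(energies = NULL, edges = NULL, probs) {
  if (any(probs < 0) || sum(probs) <= 0) stop("invalid spectrum weights")
  probs <- probs / sum(probs)
  if (!is.null(edges)) {
    stopifnot(length(edges) == length(probs) + 1, all(diff(edges) > 0),
              edges[1] >= 0, edges[length(edges)] <= XS_EMAX)
    structure(list(mode = "bins", edges = edges, probs = probs),
              class = "beam_spectrum")
  } else {
    stopifnot(length(energies) == length(probs), all(energies > 0),
              all(energies <= XS_EMAX))
    structure(list(mode = "lines", energies = energies, probs = probs),
              class = "beam_spectrum")
  }
}

#' Mean energy of a spectrum (analytic)
#' @param spec A \code{beam_spectrum}. @export
spectrum_mean <- function(spec) {
  if (spec$mode == "lines") sum(spec$energies * spec$probs)
  else sum((spec$edges[-1] + spec$edges[-length(spec$edges)]) / 2 * spec$probs)
}

#' Generic filtered 6 MV bremsstrahlung spectrum
#'
#' A thin-target (Kramers) shape hardened by transmission through 0.4 cm
#' of tungsten and 2 cm of aluminium, computed with the package's own
#' attenuation tables; a documented generic stand-in for a
#' machine-specific spectrum, user-replaceable via \code{spectrum_table}.
#'
#' @param e_max Accelerating potential end point (MeV).
#' @param n_bins Number of histogram bins (0.05 MeV to e_max).
#' @return A \code{beam_spectrum}.
#' @export
default_6mv_spectrum <- function(e_max = 6, n_bins = 24) {
  mats <- material_library()
  edges <- seq(0.05, e_max, length.out = n_bins + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- (e_max / mid - 1) *
    exp(-mu_total(mats$tungsten, mid) * 0.4 -
          mu_total(mats$aluminum, mid) * 2)
  spectrum_table(edges = edges, probs = w)
}

#' Define a photon source
#'
#' @param mode "spectrum-beam" (cone filling the jaw aperture) or
#'   "monoenergetic-point" (isotropic point, e.g. the 0.6616 MeV
#'   comparison source).
#' @param position Emission point (cm).
#' @param axis Beam axis unit vector (cone mode).
#' @param half_angle_deg Cone half-opening angle in degrees (cone mode);
#'   0 gives a pencil beam.
#' @param spectrum A \code{beam_spectrum}.
#' @return A \code{beam_source}.
#' @export
beam_source <- function(mode = c("spectrum-beam", "monoenergetic-point"),
                        position = c(0, 0, SOURCE_TO_ISOCENTER_CM),
                        axis = c(0, 0, -1), half_angle_deg = NULL,
                        spectrum = default_6mv_spectrum()) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "beam_spectrum"))
  axis <- axis / sqrt(sum(axis^2))
  structure(list(mode = mode, position = as.numeric(position), axis = axis,
                 half_angle_deg = half_angle_deg, spectrum = spectrum),
            class = "beam_source")
}

# --------------------------------------------------------------- assembly ---

#' Assemble the full treatment scenario
#'
#' Room + phantom + couch + accelerator head + source, aimed at one of
#' the irradiation points P1..P5 (the phantom is translated so the target
#' sits at the isocenter, 100 cm from the source along the beam axis).
#'
#' @param target One of "P1".."P5".
#' @param field_cm Square field side at isocenter (cm).
#' @param source Optional \code{beam_source}; the default is the generic
#'   6 MV spectrum cone filling the jaw aperture.
#' @param room,phantom,beamline Parameter lists.
#' @param label Run label.
#' @return A \code{scenario}.
#' @export
build_treatment_scenario <- function(target = "P4", field_cm = 10,
                                     source = NULL,
                                     room = room_params(),
                                     phantom = phantom_params(),
                                     beamline = beamline_params(),
                                     label = paste0("treatment-", target)) {
  pts <- irradiation_points(phantom)
  if (!target %in% names(pts)) stop("unknown target label: ", target)
  offset <- -pts[[target]]
  ph <- build_phantom(phantom, offset)
  rm_ <- build_room(room)
  bl <- build_beamline(field_cm, beamline)

  # couch: thin carbon-fiber slab under the phantom, moving with it
  post <- offset[3] - (phantom$trunk_semi[2] + phantom$skin_thickness)
  couch <- box_region("couch",
                      c(offset[1] - 30, offset[2] - 90, post - 0.7),
                      c(offset[1] + 30, offset[2] + 95, post - 0.1))
  couch_cell <- csg_cell("couch", couch$region, "carbon_fiber")

  air_rg <- rg_and(rm_$main_region,
                   rg_not(bl$housing_region),
                   rg_not(couch$region),
                   rg_not(ph$envelope_region))
  air_cell <- csg_cell("room.main_air", air_rg, "air")

  surfaces <- c(rm_$surfaces, bl$surfaces, couch$surfaces, ph$surfaces)
  cells <- c(rm_$cells_fixed, list(main_air = air_cell, couch = couch_cell),
             bl$cells, ph$cells)
  model <- geometry_model(surfaces, cells, rm_$bounding_box)

  if (is.null(source)) {
    half <- atan((field_cm / 2) / SOURCE_TO_ISOCENTER_CM) * 180 / pi
    source <- beam_source("spectrum-beam",
                          position = c(0, 0, bl$params$source_z),
                          axis = c(0, 0, -1), half_angle_deg = half)
  }
  scn <- structure(list(model = model, source = source, target = target,
                        field_cm = field_cm, phantom = ph, room = rm_,
                        beamline = bl, label = label,
                        target_organ = c(P1 = "testes", P2 = "colon",
                                         P3 = "liver", P4 = "left_lung",
                                         P5 = "brain")[[target]]),
                   class = "scenario")
  validate_scenario(scn)
  scn
}

#' Re-aim an assembled treatment scenario at another target
#'
#' Rebuilds the phantom/couch placement so the new irradiation point sits
#' at the isocenter; room and head geometry are unchanged (cell count
#' invariant).
#'
#' @param scenario A treatment \code{scenario}.
#' @param target One of "P1".."P5".
#' @return A new \code{scenario}.
#' @export
aim_beam <- function(scenario, target) {
  stopifnot(inherits(scenario, "scenario"))
  build_treatment_scenario(target = target, field_cm = scenario$field_cm,
                           source = scenario$source,
                           room = scenario$room$params,
                           phantom = scenario$phantom$params,
                           beamline = scenario$beamline$params,
                           label = paste0("treatment-", target))
}

validate_scenario <- function(scn) {
  # beam axis must pass through the target organ cell
  tgt_cell <- paste0("phantom.", scn$target_organ)
  tr <- ray_trace(scn$source$position, scn$source$axis, scn$model)
  if (!tgt_cell %in% tr$cell)
    stop("beam axis does not intersect the target organ ", scn$target_organ)
  first_tissue <- tr$cell[grep("^phantom\\.", tr$cell)][1]
  if (!identical(first_tissue, "phantom.skin"))
    stop("first tissue on the beam axis is not skin: ", first_tissue)
  invisible(scn)
}

#' Water-phantom percent-depth-dose benchmark scenario
#'
#' 6 MV beam, source-to-surface distance 100 cm, 10 x 10 cm^2 field, a
#' 50 x 50 x 40 cm water tank with its surface at the isocenter plane and
#' central-axis depth bins over the first 30 cm.
#'
#' @param depth_cm Scored depth (default 30).
#' @param bin_cm Depth bin thickness (default 0.5).
#' @param field_cm Field side (default 10).
#' @param source Optional \code{beam_source} override.
#' @return A \code{scenario} with cells \code{pdd.001}... as tally bins.
#' @export
build_water_phantom_benchmark <- function(depth_cm = 30, bin_cm = 0.5,
                                          field_cm = 10, source = NULL) {
  nb <- round(depth_cm / bin_cm)
  if (nb < 2) stop("need at least 2 depth bins")
  bl <- build_beamline(field_cm)
  S <- bl$surfaces
  airbox <- box_region("env", c(-120, -120, -80), c(120, 120, 140))
  tank <- box_region("tank", c(-25, -25, -40), c(25, 25, 0))
  col <- box_region("col", c(-2, -2, -depth_cm), c(2, 2, 0))
  S <- c(S, airbox$surfaces, tank$surfaces, col$surfaces)
  zcuts <- -seq(0, depth_cm, by = bin_cm)
  for (i in seq_len(nb - 1))
    S[[paste0("pdd.z", i)]] <- surf_plane(paste0("pdd.z", i), "z", zcuts[i + 1])
  bins <- list()
  for (i in seq_len(nb)) {
    above <- if (i == 1) inside("tank.zhi") else inside(paste0("pdd.z", i - 1))
    below <- if (i == nb) outside("col.zlo") else outside(paste0("pdd.z", i))
    rg <- rg_and(inside("col.xhi"), outside("col.xlo"),
                 inside("col.yhi"), outside("col.ylo"), above, below)
    bins[[sprintf("pdd.%03d", i)]] <-
      csg_cell(sprintf("pdd.%03d", i), rg, "water", tally = TRUE,
               organ = sprintf("depth_%05.1f", (i - 0.5) * bin_cm),
               volume = 16 * bin_cm)
  }
  rest <- csg_cell("tank.rest", rg_and(tank$region, rg_not(col$region)),
                   "water")
  air <- csg_cell("env.air",
                  rg_and(airbox$region, rg_not(bl$housing_region),
                         rg_not(tank$region)), "air")
  world <- csg_cell("world", rg_not(airbox$region), "vacuum", world = TRUE)
  model <- geometry_model(S, c(list(world = world, air = air, rest = rest),
                               bins, bl$cells),
                          list(lo = c(-121, -121, -81), hi = c(121, 121, 141)))
  if (is.null(source)) {
    half <- atan((field_cm / 2) / SOURCE_TO_ISOCENTER_CM) * 180 / pi
    source <- beam_source("spectrum-beam", position = c(0, 0, 100),
                          axis = c(0, 0, -1), half_angle_deg = half)
  }
  structure(list(model = model, source = source, target = "water",
                 field_cm = field_cm, label = "pdd-benchmark",
                 depth_cm = depth_cm, bin_cm = bin_cm,
                 target_organ = NA_character_),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %d cells, source mode %s\n", x$label,
              length(x$model$cells), x$source$mode))
  invisible(x)
}
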