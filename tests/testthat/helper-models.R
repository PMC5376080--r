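# Small geometry fixtures built in code.

# Unit sphere inside a box, with a world complement.
unit_sphere_model <- function(radius = 1) {
  sph <- surf_sphere("sph", c(0, 0, 0), radius)
  env <- box_region("env", c(-10, -10, -10), c(10, 10, 10))
  cells <- list(
    world = csg_cell("world", rg_not(env$region), "vacuum", world = TRUE),
    ball = csg_cell("ball", inside("sph"), "water",
                    volume = 4 / 3 * pi * radius^3),
    box = csg_cell("box", rg_and(env$region, rg_not(inside("sph"))),
                   "vacuum"))
  geometry_model(c(list(sph = sph), env$surfaces), cells,
                 list(lo = rep(-11, 3), hi = rep(11, 3)))
}

# Unit box split into two slabs at x = split.
two_cell_slab_model <- function(split = 0.3) {
  env <- box_region("env", c(0, 0, 0), c(1, 1, 1))
  cut <- surf_plane("cut", "x", split)
  cells <- list(
    world = csg_cell("world", rg_not(env$region), "vacuum", world = TRUE),
    left = csg_cell("left", rg_and(env$region, inside("cut")), "water",
                    volume = split),
    right = csg_cell("right", rg_and(env$region, outside("cut")), "water",
                     volume = 1 - split))
  geometry_model(c(env$surfaces, list(cut = cut)), cells,
                 list(lo = c(0, 0, 0), hi = c(1, 1, 1)))
}

# Independent brute-force distance to the six faces of an axis-aligned box.
brute_force_box_exit <- function(p, u, lo, hi) {
  ts <- c()
  for (i in 1:3) {
    if (u[i] != 0) ts <- c(ts, (lo[i] - p[i]) / u[i], (hi[i] - p[i]) / u[i])
  }
  min(ts[ts > 1e-9])
}

# A scenario that is pure vacuum (photon escapes untouched).
vacuum_world_scenario <- function(energy_mev = 1) {
  env <- box_region("env", c(-50, -50, -50), c(50, 50, 50))
  cells <- list(
    world = csg_cell("world", rg_not(env$region), "vacuum", world = TRUE),
    void = csg_cell("void", env$region, "vacuum", tally = TRUE,
                    organ = "void", volume = 100^3))
  model <- geometry_model(env$surfaces, cells,
                          list(lo = rep(-51, 3), hi = rep(51, 3)))
  src <- beam_source("spectrum-beam", position = c(0, 0, 0),
                     axis = c(0, 0, -1), half_angle_deg = 0,
                     spectrum = spectrum_line(energy_mev))
  structure(list(model = model, source = src, target = "void",
                 label = "vacuum", target_organ = NA_character_),
            class = "scenario")
}

# A large lead ball: essentially everything is absorbed locally.
absorber_scenario <- function(energy_mev = 0.05) {
  sph <- surf_sphere("ball", c(0, 0, 0), 30)
  cells <- list(
    world = csg_cell("world", rg_not(inside("ball")), "vacuum",
                     world = TRUE),
    ball = csg_cell("ball", inside("ball"), "lead", tally = TRUE,
                    organ = "ball", volume = 4 / 3 * pi * 30^3))
  model <- geometry_model(list(ball = sph), cells,
                          list(lo = rep(-31, 3), hi = rep(31, 3)))
  src <- beam_source("monoenergetic-point", position = c(0, 0, 0),
                     spectrum = spectrum_line(energy_mev))
  structure(list(model = model, source = src, target = "ball",
                 label = "absorber", target_organ = NA_character_),
            class = "scenario")
}

# Phantom fragment embedded in a minimal world, for organ-level audits.
phantom_model <- function(params = phantom_params(), offset = c(0, 0, 0)) {
  ph <- build_phantom(params, offset)
  env <- box_region("env", c(-60, -120, -60) + offset,
                    c(60, 120, 60) + offset)
  air <- csg_cell("air", rg_and(env$region, rg_not(ph$envelope_region)),
                  "air")
  world <- csg_cell("world", rg_not(env$region), "vacuum", world = TRUE)
  model <- geometry_model(c(env$surfaces, ph$surfaces),
                          c(list(world = world, air = air), ph$cells),
                          list(lo = c(-61, -121, -61) + offset,
                               hi = c(61, 121, 61) + offset))
  list(model = model, fragment = ph)
}
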