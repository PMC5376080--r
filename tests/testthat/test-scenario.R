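test_that("the room defaults match the modeled bunker", {
  vols <- room_volumes_m3()
  expect_equal(vols[["main"]], 13.7 * 9 * 4)      # 493.2 m^3
  expect_equal(vols[["control"]], 9.9 * 2 * 4)    # 79.2 m^3
  pr <- room_params()
  expect_equal(diff(pr$maze$z), 220)              # maze height 2.2 m
  expect_equal(diff(pr$maze$x), 200)              # maze width 2 m
  expect_equal(material_library()$air$density, 0.00129)
  expect_equal(material_library()$concrete$density, 2.35)
})

test_that("the phantom builds 12 labeled tissue regions with P1..P5 inside", {
  pm <- phantom_model()
  organs <- vapply(pm$fragment$cells, function(cl) cl$organ, "")
  expect_length(organs, 12)
  expect_setequal(unname(organs),
                  c("brain", "spine", "esophagus", "left_lung",
                    "right_lung", "heart", "liver", "colon", "testes",
                    "skeleton", "skin", "residual"))
  expect_true(all(pm$fragment$organs$mass_g > 0))
  pts <- irradiation_points()
  want <- c(P1 = "phantom.testes", P2 = "phantom.colon",
            P3 = "phantom.liver", P4 = "phantom.left_lung",
            P5 = "phantom.brain")
  for (p in names(pts))
    expect_equal(locate_point(pts[[p]], pm$model), want[[p]])
})

test_that("Monte Carlo volumes agree with the analytic organ volumes", {
  pm <- phantom_model()
  set.seed(11)
  n <- 2e5
  lo <- c(-25, -85, -15); hi <- c(25, 90, 15)   # box around the phantom core
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  cells <- locate_point(pts, pm$model)
  vbox <- prod(hi - lo)
  frag <- pm$fragment$organs
  for (org in c("liver", "left_lung", "heart", "brain", "colon")) {
    va <- frag$volume_cm3[frag$organ == org]
    p_hit <- va / vbox
    hits <- sum(cells == paste0("phantom.", org))
    expect_lt(abs(hits - n * p_hit), 3 * sqrt(n * p_hit * (1 - p_hit)),
              label = paste("MC volume of", org))
  }
})

test_that("left and right lungs are disjoint", {
  pm <- phantom_model()
  p <- phantom_params()
  set.seed(12)
  # sample uniformly inside the left-lung ellipsoid
  n <- 1e5
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3)
  pts <- sweep(sweep(u, 2, p$lung_semi, `*`), 2, p$lung_center, `+`)
  cells <- locate_point(pts, pm$model)
  expect_true(all(cells == "phantom.left_lung"))
})

test_that("ellipsoid organ volume matches the analytic formula by MC audit", {
  p <- phantom_params()
  va <- 4 / 3 * pi * prod(p$liver_semi)
  set.seed(13)
  n <- 2e5
  lo <- p$liver_center - p$liver_semi; hi <- p$liver_center + p$liver_semi
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  s <- surf_ellipsoid("e", p$liver_center, p$liver_semi)
  inside_frac <- mean(quadric_eval(s, pts) < 0)
  vmc <- inside_frac * prod(hi - lo)
  expect_lt(abs(vmc - va) / va,
            3 * sqrt((1 - pi / 6) / (pi / 6) / n) + 0.005)
})

test_that("aiming the beam places targets at the isocenter", {
  scn4 <- build_treatment_scenario("P4")
  tr <- ray_trace(scn4$source$position, scn4$source$axis, scn4$model)
  expect_true("phantom.left_lung" %in% tr$cell)
  first_tissue <- tr$cell[grep("^phantom\\.", tr$cell)][1]
  expect_identical(first_tissue, "phantom.skin")
  # source-to-target distance along the beam axis is 100 cm
  expect_equal(scn4$source$position, c(0, 0, 100))
  expect_equal(scn4$phantom$points$P4, c(0, 0, 0))

  scn1 <- aim_beam(scn4, "P1")
  pts <- irradiation_points()
  # rigid motion: relative source translation equals P4 - P1 exactly
  expect_equal(scn1$phantom$offset - scn4$phantom$offset, pts$P4 - pts$P1)
  # room geometry unchanged: cell and surface counts invariant
  expect_equal(length(scn1$model$cells), length(scn4$model$cells))
  expect_equal(length(scn1$model$surfaces), length(scn4$model$surfaces))

  scn5 <- aim_beam(scn4, "P5")
  tr5 <- ray_trace(scn5$source$position, scn5$source$axis, scn5$model)
  expect_true("phantom.brain" %in% tr5$cell)
  expect_error(build_treatment_scenario("P9"), "unknown target")
})

test_that("the water benchmark slices 30 cm into 60 centered bins", {
  scn <- build_water_phantom_benchmark()
  bins <- grep("^pdd\\.", names(scn$model$cells), value = TRUE)
  expect_length(bins, 60)
  tr <- ray_trace(c(0, 0, 100), c(0, 0, -1), scn$model)
  expect_true(all(bins %in% tr$cell))          # axis intersects every bin
  chords <- tr$length[tr$cell %in% bins]
  expect_equal(chords, rep(0.5, 60), tolerance = 1e-4)
  # bins are laterally centered on the beam axis
  expect_equal(locate_point(c(0, 0, -0.25), scn$model), "pdd.001")
  expect_equal(locate_point(c(0, 0, -29.75), scn$model), "pdd.060")
})

test_that("spectra validate and summarize", {
  sp <- spectrum_line(0.6616)
  expect_equal(spectrum_mean(sp), 0.6616)
  tb <- spectrum_table(energies = c(1, 3), probs = c(2, 2))
  expect_equal(spectrum_mean(tb), 2)
  expect_error(spectrum_table(energies = c(1, 3), probs = c(-1, 2)))
  expect_error(spectrum_line(50))
  s6 <- default_6mv_spectrum()
  expect_equal(sum(s6$probs), 1)
  expect_gt(spectrum_mean(s6), 0.3)
  expect_lt(spectrum_mean(s6), 3)
})
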