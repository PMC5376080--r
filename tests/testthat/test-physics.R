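mats <- material_library()

test_that("attenuation coefficients follow the mixture rule and references", {
  expect_identical(mu_total(mats$vacuum, 1.0), 0)
  # standard water value at 1 MeV (incoherent-dominated), 0.5 percent
  expect_equal(mu_total(mats$water, 1.0), 0.0707, tolerance = 0.005)
  # linearity: 50/50 two-element mixture equals the mean of the pure mu/rho
  ab <- material("mix", 2, c(Al = 0.5, Ca = 0.5))
  a <- material("a", 1, c(Al = 1)); b <- material("b", 1, c(Ca = 1))
  for (e in c(0.02, 0.1, 1, 5)) {
    expect_equal(mu_total(ab, e),
                 2 * (mu_total(a, e) + mu_total(b, e)) / 2,
                 tolerance = 1e-12)
  }
  expect_error(mu_total(mats$water, 1e-3), "outside")
  expect_error(mu_total(mats$water, 50), "outside")
})

test_that("partial cross sections sum to the total everywhere", {
  lib <- xs_library()
  for (el in c("H", "O", "Ca", "W", "Pb")) {
    tab <- lib[[el]]
    expect_equal(tab$total_cm2g,
                 tab$pe_cm2g + tab$incoh_cm2g + tab$pair_cm2g,
                 tolerance = 1e-9)
  }
  for (e in c(0.015, 0.3, 2.5, 9)) {
    expect_equal(mu_total(mats$bone, e),
                 mu_total(mats$bone, e, "photoelectric") +
                   mu_total(mats$bone, e, "incoherent") +
                   mu_total(mats$bone, e, "pair"),
                 tolerance = 1e-9)
  }
})

test_that("the shipped cross-section library is regenerable", {
  tmp <- tempfile(fileext = ".csv")
  xs_write_library(tmp)
  shipped <- system.file("extdata", "xs_photoatomic_v1.csv",
                         package = "photondose")
  expect_identical(readLines(tmp), readLines(shipped))
})

test_that("free paths are exponential with mean 1/mu", {
  mu <- mu_total(mats$water, 1.0)
  set.seed(1)
  x <- sample_free_path(mats$water, 1.0, n = 1e6)
  expect_lt(abs(mean(x) - 1 / mu), 3 / mu / sqrt(1e6))
  # opaque medium: tiny mean free path
  expect_lt(mean(sample_free_path(mats$tungsten, 0.05, n = 1e4)), 0.1)
})

test_that("interaction types are drawn proportional to the partials", {
  set.seed(2)
  draws <- sample_interaction(mats$bone, 0.05, n = 1e5)
  p_pe <- mu_total(mats$bone, 0.05, "photoelectric") /
    mu_total(mats$bone, 0.05)
  obs <- mean(draws == "photoelectric")
  expect_lt(abs(obs - p_pe), 3 * sqrt(p_pe * (1 - p_pe) / 1e5))
  # below the pair threshold nothing pairs
  expect_false(any(sample_interaction(mats$water, 0.8, n = 1e5) == "pair"))
  # frequency table vs partial ratios, chi-square goodness of fit
  draws <- sample_interaction(mats$water, 2.0, n = 1e6)
  p <- c(photoelectric = mu_total(mats$water, 2, "photoelectric"),
         compton = mu_total(mats$water, 2, "incoherent"),
         pair = mu_total(mats$water, 2, "pair"))
  tab <- table(factor(draws, levels = names(p)))
  expect_gt(stats::chisq.test(tab, p = p / sum(p))$p.value, 0.001)
})

test_that("Compton sampling respects the kinematic bounds", {
  s <- sample_compton(0.6616, n = 1e5, seed = 9)
  # backscatter limit at the 0.6616 MeV comparison line
  emin <- 0.6616 / (1 + 2 * 0.6616 / 0.511)
  expect_equal(emin, 0.1843, tolerance = 1e-3)
  expect_gte(min(s$scattered_mev), emin - 1e-12)
  expect_lte(max(s$scattered_mev), 0.6616 + 1e-12)
  expect_true(all(s$deposited_mev >= 0))
  expect_true(all(abs(s$scattered_mev + s$deposited_mev - 0.6616) < 1e-12))
  # scattered energy and cosine satisfy the Compton relation
  expect_equal(s$scattered_mev,
               0.6616 / (1 + (0.6616 / 0.511) * (1 - s$cosine)),
               tolerance = 1e-12)
})

test_that("Compton sampling reproduces the Thomson and quadrature moments", {
  # near-zero energy: fore/aft symmetric, mean cosine 0
  s <- sample_compton(1e-4, n = 1e6, seed = 5)
  expect_lt(abs(mean(s$cosine)), 3 * sd(s$cosine) / sqrt(1e6))
  # mean scattered fraction at 0.5 MeV vs the quadrature oracle
  s <- sample_compton(0.5, n = 1e6, seed = 6)
  frac <- s$scattered_mev / 0.5
  expect_lt(abs(mean(frac) - kn_moments(0.5)$mean_scatter_frac),
            3 * sd(frac) / sqrt(1e6))
})

test_that("Compton sampling is deterministic under a fixed seed", {
  a <- sample_compton(1, n = 1000, seed = 123)
  b <- sample_compton(1, n = 1000, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, sample_compton(1, n = 1000, seed = 124)))
})

test_that("pair production conserves energy at and above threshold", {
  expect_error(sample_pair(0.8), "1.022")
  set.seed(3)
  s <- sample_pair(1.022, n = 10)
  expect_true(all(s$deposited_mev == 0))
  s <- sample_pair(6, n = 1000)
  expect_true(all(abs(s$deposited_mev + 2 * 0.511 - 6) < 1e-12))
  # emitted directions are unit vectors (the twin photon is the negation)
  expect_equal(s$ux^2 + s$uy^2 + s$uz^2, rep(1, 1000), tolerance = 1e-12)
})

test_that("material invariants are enforced", {
  expect_error(material("m", 1, c(H = 0.4, O = 0.4)), "sum to 1")
  expect_error(material("m", 1, c(Xx = 1)), "not in cross-section library")
  expect_error(material("m", -1, c(H = 1)))
  w <- mats$water
  expect_gt(w$atom_density, 0.09)   # ~0.1 atoms/(barn cm)
  expect_lt(w$atom_density, 0.11)
})
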