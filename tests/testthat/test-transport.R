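test_that("a photon in vacuum escapes with its full energy", {
  h <- run_history(vacuum_world_scenario(2), history_index = 0, seed = 1)
  expect_equal(sum(h$deposited), 0)
  expect_equal(h$escaped, 2)
  expect_equal(h$emitted, 2)
})

test_that("an opaque absorber captures essentially all emitted energy", {
  res <- run(absorber_scenario(0.05),
             run_config(2000, n_batches = 4, seed = 2, analog = TRUE))
  expect_gt(res$totals$deposited / res$totals$emitted, 0.999)
})

test_that("analog transport balances energy to 1e-9 relative", {
  scn <- make_mini_phantom_scenario()
  res <- run(scn, run_config(5000, n_batches = 5, seed = 3, analog = TRUE))
  imbalance <- abs(res$totals$emitted - res$totals$deposited -
                     res$totals$escaped) / res$totals$emitted
  expect_lt(imbalance, 1e-9)
  # per-history balance as well
  for (h in c(0, 17, 4321)) {
    one <- run_history(scn, h, seed = 3)
    expect_lt(abs(one$emitted - sum(one$deposited) - one$escaped) /
                one$emitted, 1e-9)
  }
})

test_that("uncollided transmission through tau = 1 follows e^-1", {
  res <- run(build_slab_scenario(1),
             run_config(1e5, n_batches = 10, seed = 4, analog = TRUE))
  p <- exp(-1)
  obs <- res$totals$uncollided / res$totals$n_histories
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("tallies are bit-identical for any worker count", {
  scn <- make_mini_phantom_scenario()
  r1 <- run(scn, run_config(5000, n_batches = 10, seed = 5, workers = 1))
  r8 <- run(scn, run_config(5000, n_batches = 10, seed = 5, workers = 8))
  expect_identical(r1$doses$dose_mev_g, r8$doses$dose_mev_g)
  expect_identical(r1$batch_means, r8$batch_means)
})

test_that("relative error shrinks like one over sqrt(histories)", {
  scn <- make_mini_phantom_scenario()
  re <- function(r) r$doses$rel_error[r$doses$organ == "target"]
  res <- vapply(1:10, function(s) c(
    re(run(scn, run_config(1500, n_batches = 10, seed = s))),
    re(run(scn, run_config(3000, n_batches = 10, seed = 100 + s)))),
    c(0, 0))
  # averaged over 10 repeats, doubling histories scales RE by ~1/sqrt(2)
  ratio <- mean(res[2, ]) / mean(res[1, ])
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.2 / sqrt(2))
})

test_that("batch-means relative error matches a hand computation", {
  re <- estimate_relative_error(c(5, 5, 5))
  expect_equal(as.numeric(re), 0)
  # batch means {1,2,3}: sd = 1, SE = 1/sqrt(3) = 0.5774, RE = 0.2887
  re <- estimate_relative_error(c(1, 2, 3))
  expect_equal(as.numeric(re), 0.28867513, tolerance = 1e-7)
  expect_false(attr(re, "converged"))
  # at the 0.4 percent convergence threshold
  x <- c(1, 1.0001, 0.9999, 1)
  expect_true(attr(estimate_relative_error(x, target = 0.004), "converged"))
  expect_true(is.na(estimate_relative_error(c(-1, 1))))
  expect_error(estimate_relative_error(1), "at least 2")
})

test_that("run configuration invariants are enforced", {
  expect_error(run_config(10, n_batches = 1), "at least 2")
  expect_error(run_config(5, n_batches = 10), ">= n_batches")
  expect_error(run_config(100, cutoff_mev = 0.001), "below")
})

test_that("early stop honors the target relative error", {
  scn <- make_mini_phantom_scenario()
  res <- run(scn, run_config(4e4, n_batches = 20, seed = 6,
                             target_rel_error = 0.2))
  expect_lte(res$totals$n_batches, 20)
  re <- res$doses$rel_error[res$doses$dose_mev_g > 0]
  expect_lte(max(re), 0.2)
})

test_that("spectrum source energies average to the table mean", {
  scn <- vacuum_world_scenario()
  scn$source <- beam_source("spectrum-beam", position = c(0, 0, 0),
                            axis = c(0, 0, -1), half_angle_deg = 0,
                            spectrum = default_6mv_spectrum())
  res <- run(scn, run_config(5e4, n_batches = 10, seed = 7, analog = TRUE))
  mean_e <- res$totals$emitted / res$totals$n_histories
  expect_equal(mean_e, spectrum_mean(scn$source$spectrum), tolerance = 0.02)
})
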