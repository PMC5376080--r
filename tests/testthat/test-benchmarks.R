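test_that("slab oracle expectations are the closed-form transmissions", {
  cases <- make_slab_oracle(c(0.5, 1, 5))
  expect_equal(cases[[1]]$expectation, exp(-0.5))
  expect_equal(cases[[2]]$expectation, 0.367879, tolerance = 1e-5)
  expect_equal(cases[[3]]$expectation, 0.006738, tolerance = 1e-4)
  expect_equal(make_slab_oracle(0)[[1]]$expectation, 1)
  # re-running the expectation generator reproduces the stored value
  again <- make_slab_oracle(c(0.5, 1, 5))
  expect_identical(vapply(cases, `[[`, 0, "expectation"),
                   vapply(again, `[[`, 0, "expectation"))
})

test_that("KN oracle quadrature agrees with the closed-form total", {
  cases <- make_kn_moment_oracle(c(0.0005, 0.6616, 6))
  # construction itself enforces 1e-8 agreement; spot-check the limits
  expect_lt(abs(cases[[1]]$expectation$mean_cosine), 1e-3)  # Thomson
  expect_equal(cases[[2]]$expectation$min_scatter_mev,
               0.6616 / (1 + 2 * 0.6616 / 0.511))
  again <- make_kn_moment_oracle(c(0.0005, 0.6616, 6))
  expect_identical(cases[[2]]$expectation, again[[2]]$expectation)
})

test_that("the mini phantom orders F by distance and runs fast", {
  t0 <- Sys.time()
  res <- run(make_mini_phantom_scenario(),
             run_config(1e4, n_batches = 10, seed = 21))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 30)
  f <- compute_conversion_coefficients(as_dose_result(res, "mini"),
                                       "target")
  fo <- stats::setNames(f$F, f$organ)
  expect_identical(fo[["target"]], 1)
  expect_gt(fo[["near"]], fo[["far"]])
})

test_that("benchmark registry names resolve and report verdicts", {
  expect_true(all(c("slab-tau-1", "kn-moments-0.6616", "inverse-square",
                    "mini-phantom-F", "estimator-agreement")
                  %in% list_benchmarks()))
  b <- run_benchmark("slab-tau-1", n_histories = 5000, seed = 1)
  expect_true(b$pass)
  expect_equal(b$expected, exp(-1))
  b <- run_benchmark("kn-moments-0.5", n_histories = 1e5, seed = 1)
  expect_true(b$pass)
  expect_error(run_benchmark("no-such-case"), "unknown benchmark")
})
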