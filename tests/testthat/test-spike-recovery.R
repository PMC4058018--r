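test_that("noiseless linear data is recovered to machine precision", {
  x <- c(5, 10, 50, 100, 500)
  ex <- data.frame(spiked = x, recovered = 0.9 * x + 2)
  fit <- recovery_regression(ex)
  expect_equal(fit$slope, 0.9, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_true(all(is.finite(fit$slope_ci)))

  ident <- recovery_regression(data.frame(spiked = x, recovered = x))
  expect_equal(ident$slope, 1, tolerance = 1e-10)
  expect_equal(ident$intercept, 0, tolerance = 1e-8)
})

test_that("a duplicated level reduces to the two-point slope formula", {
  ex <- data.frame(spiked = c(10, 10, 50), recovered = c(8, 8, 40))
  fit <- recovery_regression(ex)
  expect_equal(fit$slope, (40 - 8) / (50 - 10), tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  expect_error(recovery_regression(data.frame(spiked = c(10, 10, 10),
                                              recovered = c(9, 8, 10))),
               "rank-deficient")
  expect_error(recovery_regression(data.frame(spiked = c(1, 2),
                                              recovered = c(1, 2))),
               "at least 3")
})

test_that("the LOD rule picks the smallest reliably detected level", {
  # full recovery, no noise, zero background: smallest non-zero level
  ex <- data.frame(spiked = rep(c(0, 1, 5, 10), each = 5),
                   recovered = rep(c(0, 1, 5, 10), each = 5))
  expect_equal(limit_of_detection(ex, background = c(0, 0, 0)), 1)
  # healthy background up to 3/mL masks the 1/mL level
  ex2 <- data.frame(spiked = rep(c(1, 5, 10, 100), each = 5),
                    recovered = rep(c(1, 5, 10, 100), each = 5))
  expect_equal(limit_of_detection(ex2, background = c(0, 1, 3)), 5)
  # nothing recovered anywhere: sentinel above the tested range
  ex3 <- data.frame(spiked = rep(c(1, 5, 10), each = 5), recovered = 0)
  expect_identical(limit_of_detection(ex3, background = 0), Inf)
})

test_that("LOD falls with recovery rate and rises with background", {
  lods_rec <- vapply(c(0.2, 0.5, 1.0), function(rr) {
    lods <- vapply(1:10, function(s) {
      ex <- simulate_spike_series(c(1, 2, 5, 10, 20, 50, 100), rr,
                                  background_per_ml = 1, replicates = 40,
                                  seed = s)
      limit_of_detection(ex, background = c(0, 1, 2, 3))
    }, 0)
    mean(lods)
  }, 0)
  expect_true(all(diff(lods_rec) <= 0))

  lods_bg <- vapply(c(0, 3, 8), function(bmax) {
    lods <- vapply(1:10, function(s) {
      ex <- simulate_spike_series(c(1, 2, 5, 10, 20, 50, 100), 0.9,
                                  background_per_ml = max(bmax / 2, 0.1),
                                  replicates = 40, seed = s)
      limit_of_detection(ex, background = c(0, bmax))
    }, 0)
    mean(lods)
  }, 0)
  expect_true(all(diff(lods_bg) >= 0))
})
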