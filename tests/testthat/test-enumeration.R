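test_that("Poisson CV reproduces the published per-slide values", {
  # every printed CV% in the patient table follows from its slide count
  tab <- melanoma_cohort()
  expect_equal(poisson_cv(tab$n_cmc_slide), tab$cv_percent)
  expect_equal(poisson_cv(101), 10)
  expect_equal(poisson_cv(2134), 2.2)
  expect_equal(poisson_cv(1), 100)
  expect_equal(poisson_cv(4, digits = NULL), 50)
  expect_error(poisson_cv(0), "undefined")
})

test_that("per-mL extrapolation follows the sampling-ratio arithmetic", {
  expect_equal(per_ml(10, 5e5, 5e4, 1), 100)
  expect_equal(per_ml(4, 2.625e6, 5e4, 10), 21)
  expect_equal(per_ml(0, 1e6, 5e4, 10), 0)
  # linear in the slide count; halving blood volume doubles the result
  expect_equal(per_ml(30, 2e6, 5e4, 10, round = FALSE),
               3 * per_ml(10, 2e6, 5e4, 10, round = FALSE))
  expect_equal(per_ml(7, 2e6, 5e4, 5, round = FALSE),
               2 * per_ml(7, 2e6, 5e4, 10, round = FALSE))
  expect_warning(per_ml(5, 3e4, 5e4, 10), "oversamples")
})

test_that("mass balance flags unaccounted cell losses", {
  mb <- mass_balance(1e8, 1.5e6, 9.8e7)
  expect_equal(mb$recovery, 0.995)
  expect_true(mb$pass)
  expect_true(mass_balance(1e8, 0, 1e8)$pass)
  bad <- mass_balance(1e8, 1e6, 5e7)
  expect_equal(bad$recovery, 0.51)
  expect_false(bad$pass)
  expect_error(mass_balance(0, 1, 1), "feed")
})

test_that("depletion rate is the removed leukocyte fraction", {
  expect_equal(depletion_rate(1e8, 1e6), 0.99)
  expect_equal(depletion_rate(1e8, 1e8), 0)
  expect_error(depletion_rate(1e6, 2e6), "exceeds")
})

test_that("manifests are schema-checked", {
  dir <- withr::local_tempdir()
  man <- data.frame(sample_id = "s1", fraction = "Eluate", total_cells = 1e6,
                    cells_per_slide = 5e4, blood_volume_ml = 10)
  path <- file.path(dir, "man.csv")
  write.csv(man, path, row.names = FALSE)
  expect_silent(read_manifest(path))
  man$fraction <- "Elute"  # typo
  write.csv(man, path, row.names = FALSE)
  expect_error(read_manifest(path), "invalid rows")
  write.csv(man[, -1], path, row.names = FALSE)
  expect_error(read_manifest(path), "missing columns")
})
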