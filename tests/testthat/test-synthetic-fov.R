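test_that("ground truth lists exactly the requested objects", {
  spec <- scene_spec(n_cmc = 5, seed = 2)
  sc <- make_fov(spec)
  expect_equal(nrow(sc$truth), 5)
  expect_true(all(sc$truth$class == "CMC"))
  expect_true(all(sc$truth$nucleus))
  expect_true(all(sc$truth$centroid_row >= 1 &
                    sc$truth$centroid_row <= spec$fov_shape[1]))

  mixed <- make_fov(scene_spec(n_cmc = 3, n_leuko = 4, n_dual = 2,
                               n_debris = 2, seed = 9))
  expect_equal(as.vector(table(factor(mixed$truth$class,
                                      c("CMC", "leukocyte", "dual", "debris")))),
               c(3L, 4L, 2L, 2L))
  expect_false(any(mixed$truth$nucleus[mixed$truth$class == "debris"]))
})

test_that("identical specs render bit-identical images", {
  spec <- scene_spec(n_cmc = 4, n_leuko = 6, n_debris = 3, seed = 42)
  a <- make_fov(spec); b <- make_fov(spec)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(make_fov(spec)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("rendered intensities are 8-bit clipped in every channel", {
  specs <- list(
    scene_spec(n_cmc = 8, n_leuko = 10, seed = 3),
    scene_spec(n_cmc = 5, background_mean = 250, background_sd = 30, seed = 4),
    scene_spec(n_debris = 10, background_mean = 0, background_sd = 0, seed = 5))
  for (spec in specs) {
    sc <- make_fov(spec)
    for (ch in sc$image$channels) {
      expect_true(is.integer(ch))
      expect_gte(min(ch), 0)
      expect_lte(max(ch), 255)
    }
  }
})

test_that("impossible placements raise an error naming the failing object", {
  spec <- scene_spec(fov_shape = c(64, 64), n_cmc = 60, seed = 1)
  expect_error(make_fov(spec), "place object .* CMC")
})

test_that("scene specs are validated", {
  expect_error(scene_spec(n_cmc = -1), "non-negative")
  expect_error(scene_spec(nucleus_radius_range = c(5, 2)), "increasing")
  expect_error(scene_spec(margin_sharpness = 0), "margin_sharpness")
  expect_error(scene_spec(background_mean = 300), "background")
})
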