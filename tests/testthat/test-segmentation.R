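test_that("shape metrics match closed forms on digital shapes", {
  disk <- shape_metrics(disk_mask(20))
  expect_gte(disk$circularity, 0.9)
  expect_lte(disk$aspect_ratio, 1.1)
  expect_equal(disk$area, sum(disk_mask(20)))

  # circularity of a square tends to pi/4 as the side grows
  sq <- shape_metrics(square_mask(120))
  expect_lt(abs(sq$circularity - pi / 4), 0.03)

  ell <- shape_metrics(ellipse_mask(40, 20))
  expect_lt(abs(ell$aspect_ratio - 2), 0.1)

  expect_error(shape_metrics(matrix(0, 5, 5)), "empty")
})

test_that("component labeling is 8-connected with raster-order labels", {
  bw <- matrix(0, 6, 6)
  bw[2, 2] <- 1; bw[3, 3] <- 1  # touch only diagonally
  lab <- cmcount:::label8(bw)
  expect_identical(max(lab), 1L)
  bw[5, 5] <- 1                 # separate object
  lab <- cmcount:::label8(bw)
  expect_identical(max(lab), 2L)
  expect_identical(lab[2, 2], 1L)
  expect_identical(lab[5, 5], 2L)
})

test_that("nuclear mask finds exactly the sharp-margin nuclei", {
  sc <- make_fov(scene_spec(n_cmc = 5, seed = 31))
  nm <- nuclear_mask(sc$image$channels$dapi)
  expect_equal(nrow(nm$objects), 5)

  # anuclear debris must not contribute nuclei
  sc2 <- make_fov(scene_spec(n_cmc = 5, n_debris = 10, seed = 31))
  nm2 <- nuclear_mask(sc2$image$channels$dapi)
  expect_equal(nrow(nm2$objects), 5)
})

test_that("fuzzy-margin nuclei are rejected by the margin filter", {
  sharp <- make_fov(scene_spec(n_cmc = 6, margin_sharpness = 4, seed = 32))
  fuzzy <- make_fov(scene_spec(n_cmc = 6, margin_sharpness = 0.25, seed = 32))
  expect_equal(nrow(nuclear_mask(sharp$image$channels$dapi)$objects), 6)
  expect_equal(nrow(nuclear_mask(fuzzy$image$channels$dapi)$objects), 0)
})

test_that("a blank noisy field yields an empty nucleus list without error", {
  blank <- make_fov(scene_spec(seed = 33))  # background only
  nm <- nuclear_mask(blank$image$channels$dapi)
  expect_equal(nrow(nm$objects), 0)
})
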