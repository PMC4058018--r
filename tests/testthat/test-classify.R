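cell_row <- function(green = 8, red = 8, g_nuc = 8, margin = 0.5,
                     nucleus = TRUE, border = FALSE, cv = 0.1) {
  data.frame(green_mean = green, red_mean = red, green_nuclear_mean = g_nuc,
             green_cv = cv, margin_score = margin, border = border,
             nucleus_present = nucleus)
}
thr <- structure(list(t_red = 30, t_green = 40, mode = "explicit"),
                 class = "threshold_pair")

test_that("the CMC decision rules classify canonical cells correctly", {
  cfg <- count_config()
  # green, not red, nucleated, cytoplasmic pattern -> CMC
  expect_equal(as.character(classify_cells(cell_row(green = 150, red = 5),
                                           thr, cfg)), "CMC")
  # green AND red -> dual ("yellow"), never a CMC
  expect_equal(as.character(classify_cells(cell_row(green = 150, red = 120),
                                           thr, cfg)), "dual")
  # red only -> leukocyte
  expect_equal(as.character(classify_cells(cell_row(green = 5, red = 120),
                                           thr, cfg)), "leukocyte")
  # green signal without an associated nucleus -> debris
  expect_equal(as.character(classify_cells(cell_row(green = 150,
                                                    nucleus = FALSE),
                                           thr, cfg)), "debris")
  # fuzzy margin fails the well-defined-margin rule
  expect_equal(as.character(classify_cells(cell_row(green = 150,
                                                    margin = 0.05),
                                           thr, cfg)), "null")
  # Melan-A green must be predominantly cytoplasmic
  expect_equal(as.character(classify_cells(cell_row(green = 150, g_nuc = 200),
                                           thr, cfg)), "null")
  s100 <- count_config(marker = "S100B")
  expect_equal(as.character(classify_cells(cell_row(green = 150, g_nuc = 200),
                                           thr, s100)), "CMC")
  # border-touching cells are excluded whatever their colors
  expect_equal(as.character(classify_cells(cell_row(green = 150,
                                                    border = TRUE),
                                           thr, cfg)), "border")
})

random_cell_table <- function(n) {
  data.frame(green_mean = runif(n, 0, 255), red_mean = runif(n, 0, 255),
             green_nuclear_mean = runif(n, 0, 100),
             green_cv = runif(n, 0, 1.5),
             margin_score = runif(n, 0, 0.8),
             border = runif(n) < 0.1,
             nucleus_present = runif(n) < 0.95)
}

test_that("green + red + yellow + null partition the accepted nucleated objects", {
  cfg <- count_config()
  set.seed(51)
  for (i in 1:20) {
    cells <- random_cell_table(200)
    cls <- classify_cells(cells, thr, cfg)
    accepted <- sum(cells$nucleus_present & !cells$border)
    tal <- table(cls)
    expect_identical(unname(tal[["CMC"]] + tal[["leukocyte"]] +
                              tal[["dual"]] + tal[["null"]]), accepted)
  }
})

test_that("raising a threshold never raises the corresponding tally", {
  cfg <- count_config()
  set.seed(52)
  cells <- random_cell_table(500)
  cmc_tally <- vapply(seq(0, 255, by = 5), function(tg) {
    th <- structure(list(t_red = 60, t_green = tg, mode = "explicit"),
                    class = "threshold_pair")
    sum(classify_cells(cells, th, cfg) == "CMC")
  }, 0L)
  expect_true(all(diff(cmc_tally) <= 0))

  leuko_tally <- vapply(seq(0, 255, by = 5), function(tr) {
    th <- structure(list(t_red = tr, t_green = 60, mode = "explicit"),
                    class = "threshold_pair")
    sum(classify_cells(cells, th, cfg) == "leukocyte")
  }, 0L)
  expect_true(all(diff(leuko_tally) <= 0))
})

test_that("threshold selection is biased against green for patients", {
  set.seed(53)
  cells <- data.frame(green_mean = c(rnorm(40, 20, 3), rnorm(40, 180, 10)),
                      red_mean = c(rnorm(40, 150, 10), rnorm(40, 10, 3)))
  pat <- select_thresholds(cells, mode = "patient")
  ctl <- select_thresholds(cells, mode = "control")
  base <- isodata_threshold(tabulate(as.integer(round(cells$green_mean)) + 1L,
                                     256L))
  expect_gt(pat$t_green, base)
  expect_lt(ctl$t_green, base)
  expect_gt(pat$t_green, 20); expect_lt(pat$t_green, 180)

  exp <- select_thresholds(cells, mode = "explicit", t_red = 30, t_green = 40)
  expect_identical(exp[c("t_red", "t_green")], list(t_red = 30, t_green = 40))
  expect_error(select_thresholds(cells[1:5, ], mode = "patient"), "explicit")
})

test_that("on a marker-negative slide the patient-mode green threshold clears every cell", {
  sc <- make_fov(scene_spec(n_leuko = 40, fov_shape = c(400, 400), seed = 54))
  nm <- nuclear_mask(sc$image$channels$dapi)
  cells <- measure_cells(sc$image, nm$objects, nm$labels)
  th <- select_thresholds(cells, mode = "patient")
  expect_true(all(cells$green_mean <= th$t_green))
})
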