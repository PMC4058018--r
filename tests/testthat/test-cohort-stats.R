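test_that("cohort summaries reproduce the published medians and ranges", {
  tab <- melanoma_cohort()
  s <- summarize_cohort(tab)
  expect_equal(s$median, 287)
  expect_equal(s$min, 21)
  expect_equal(s$max, 28483)
  expect_equal(s$n, 11)
  expect_equal(unname(s$by_sex[["male"]]), 5)
  expect_equal(unname(s$by_site[["cutaneous"]]), 8)
  expect_equal(unname(s$by_braf_status[["positive"]]), 7)
  expect_equal(unname(s$by_marker[["S100B"]]), 4)

  single <- summarize_cohort(data.frame(n_cmc_ml = 12))
  expect_equal(single$median, 12)
  expect_error(summarize_cohort(data.frame()), "empty")
})

test_that("exact Mann-Whitney matches direct enumeration of labelings", {
  expect_equal(mann_whitney_exact(c(1, 2), c(3, 4))$p, 1 / 3)
  expect_equal(mann_whitney_exact(c(5, 5), c(5, 5))$p, 1)
  # exhaustive check on random small samples with ties, combined n <= 8
  set.seed(81)
  for (i in 1:40) {
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    a <- sample(1:5, m, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    expect_equal(mann_whitney_exact(a, b)$p, mw_enumerate(a, b),
                 tolerance = 1e-12,
                 label = sprintf("a=(%s) b=(%s)", toString(a), toString(b)))
  }
})

test_that("patients separate completely from healthy controls", {
  mw <- mann_whitney_exact(melanoma_cohort()$n_cmc_ml,
                           healthy_controls()$n_cmc_ml)
  expect_equal(mw$method, "exact")
  expect_lt(mw$p, 0.001)
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(82)
  a <- rpois(30, 5); b <- rpois(30, 8)
  mw <- mann_whitney_exact(a, b)
  expect_match(mw$method, "normal")
  ref <- suppressWarnings(wilcox.test(a, b, correct = FALSE))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-6)
})

test_that("the Cox fit maximizes the Breslow partial likelihood", {
  times <- c(1, 2, 3, 4); events <- c(TRUE, TRUE, TRUE, TRUE)
  x <- c(1, 0, 1, 0)  # interleaved so the partial likelihood has a finite maximum
  fit <- cox_ph_single(times, events, x)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, breslow_loglik, 0, times = times, events = events, x = x)
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-3)
})

test_that("Cox degenerate inputs raise informative errors", {
  expect_error(cox_ph_single(1:4, rep(TRUE, 4), rep(2, 4)), "constant")
  expect_error(cox_ph_single(1:4, rep(FALSE, 4), 1:4), "no events")
})

test_that("survival on log CMC count reproduces the published hazard ratio", {
  tab <- melanoma_cohort()
  fit <- cox_ph_single(tab$survival_months, !tab$alive_at_analysis,
                       log(tab$n_cmc_ml))
  expect_equal(round(fit$hr, 2), 1.46)
  expect_equal(round(fit$hr_ci, 2), c(0.91, 2.36))
  expect_equal(round(fit$p, 2), 0.12)
})

test_that("log-rank matches the hand-computed observed-minus-expected table", {
  times <- c(2, 4, 5, 7, 9, 12, 3, 6, 8, 10)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE,
              TRUE, TRUE, TRUE, FALSE)
  grp <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$chisq, logrank_oracle(times, events, grp), tolerance = 1e-9)
  # invariant to time-unit rescaling
  lr_days <- logrank_test(times * 30.44, events, grp)
  expect_equal(lr$chisq, lr_days$chisq, tolerance = 1e-9)
  # identical groups carry no signal
  lr0 <- logrank_test(rep(times, 2), rep(events, 2),
                      rep(c("a", "b"), each = 10))
  expect_lt(lr0$chisq, 1e-10)
  expect_error(logrank_test(times, rep(FALSE, 10), grp), "no events")
})

test_that("Spearman correlation handles monotone data and ties", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  expect_equal(spearman_cor(1:8, (1:8)^3)$p, 0)
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 4, 6)
  rho_direct <- cor(rank(x), rank(y))
  expect_equal(spearman_cor(x, y)$rho, rho_direct)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("delta-delta-Ct fold enrichment behaves as powers of two", {
  expect_equal(mir_fold_change(25, 20, 24, 19), 1)   # equal delta-Ct
  expect_equal(mir_fold_change(25, 20, 23, 19), 2)   # one cycle earlier
  expect_equal(mir_fold_change(25, 20, 25 - 3.322, 20), 10, tolerance = 1e-3)
  expect_equal(mir_fold_change(25, 20, 25, 20), 1)   # Feed vs itself
  expect_error(mir_fold_change(25, NA, 24, 19), "present")
})
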