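test_that("density estimate is normalized, mode-accurate, and translation-equivariant", {
  set.seed(100)
  x <- rnorm(1000)
  grid <- estimate_density(x)
  expect_lt(abs(grid$x[which.max(grid$density)]), 0.2)
  integral <- sum(diff(grid$x) * (head(grid$density, -1) + tail(grid$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_gte(nrow(grid), 512)
  # grid spans [min - 3h, max + 3h]
  bw <- attr(grid, "bw")
  expect_equal(min(grid$x), min(x) - 3 * bw)
  expect_equal(max(grid$x), max(x) + 3 * bw)

  shifted <- estimate_density(x + 5)
  expect_equal(shifted$x, grid$x + 5, tolerance = 1e-8)
  expect_equal(shifted$density, grid$density, tolerance = 1e-8)

  expect_error(estimate_density(rep(1, 50)), "constant")
  expect_error(estimate_density(rnorm(5)), "at least 10")
})

test_that("cutoff finder recovers the valley of a planted bimodal mixture", {
  set.seed(42)
  x <- c(rnorm(255, 4, 0.5), rnorm(45, 9, 0.5))  # 0.85/0.15 mixture, n = 300
  cut <- find_cutoff(estimate_density(x))
  expect_false(is.na(cut$cutoff))
  expect_gt(cut$cutoff, 5.5)
  expect_lt(cut$cutoff, 7.5)
})

test_that("unimodal densities yield none_found rather than an error", {
  set.seed(7)
  cut <- find_cutoff(estimate_density(rnorm(500, 6, 1)))
  expect_identical(cut$rule_applied, "none_found")
  expect_true(is.na(cut$cutoff))
})

test_that("with several minima the five-percent rule picks the low-adjacent valley", {
  # three modes: deep valley after the dominant low mode (under 5% of max),
  # shallow valley between the two upper modes (well above 5%)
  x <- seq(0, 13, length.out = 1301)
  y <- dnorm(x, 4, 0.6) + 0.25 * dnorm(x, 8.3, 0.7) + 0.25 * dnorm(x, 10.1, 0.7)
  grid <- tibble::tibble(x = x, density = y / sum(y * diff(x)[1]))
  cut <- find_cutoff(grid)
  expect_identical(cut$rule_applied, "five_percent_rule")
  expect_equal(length(cut$minima), 2)
  expect_gt(cut$cutoff, 4)
  expect_lt(cut$cutoff, 8.5)
})

test_that("dichotomization assigns boundary values to the low group", {
  cohort <- tibble::tibble(sample_id = c("a", "b", "c"),
                           evi1_log2 = c(4, 6, 8), ms4a3_log2 = 0)
  lab <- dichotomize(cohort, cutoff = 6)
  expect_identical(lab$group, c("low", "low", "high"))
})

test_that("percent-high reporting matches published cohort count arithmetic", {
  expect_equal(pct_high(18, 229), 7.3)
  expect_equal(pct_high(12, 202), 5.6)
  expect_equal(pct_high(9, 102), 8.1)
  expect_equal(pct_high(21, 109), 16.2)
})

test_that("z_to_p reproduces printed two-sided normal p-values", {
  expect_equal(signif(z_to_p(2.56), 2), 1.0e-2)
  expect_equal(signif(z_to_p(2.84), 2), 4.5e-3)
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(-2.56), z_to_p(2.56))
})

test_that("resampling statistic obeys Z = -M/SD and the repression sign convention", {
  for (s in c(3, 11, 27)) {
    cohort <- simulate_cohort(cohort_design(seed = s))
    lab <- dplyr::mutate(cohort, group = .data$true_group)
    b <- bootstrap_association(lab, n_iter = 500, seed = s)
    expect_identical(b$Z, -b$M / b$SD)
    expect_equal(b$p_two_sided, 2 * (1 - pnorm(abs(b$Z))))
    expect_lt(b$M, 0)  # planted repression: response lower in the high group
    expect_gt(b$Z, 0)
    expect_equal(length(b$d), 500)
  }
})

test_that("bootstrap recovers the planted effect for the reference design", {
  cohort <- simulate_cohort(cohort_design(
    n_high = 20, n_low = 200, mu_low = 4, mu_high = 9,
    sigma_low = 0.5, sigma_high = 0.5, effect_delta = 1.0,
    ms4a3_sd = 0.5, seed = 11
  ))
  fit <- cohort_association(cohort, n_iter = 2000, seed = 11)
  expect_gt(fit$cutoff_result$cutoff, 4)
  expect_lt(fit$cutoff_result$cutoff, 9)
  expect_gte(fit$bootstrap$M, -1.3)
  expect_lte(fit$bootstrap$M, -0.7)
  expect_gt(fit$bootstrap$Z, 2)
  # M recovers -delta within 3 resampling SDs plus high-group sampling error
  expect_lt(abs(fit$bootstrap$M + 1.0), 3 * max(fit$bootstrap$SD, 0.5 / sqrt(20)))
})

test_that("degenerate and invalid bootstrap inputs are handled as specified", {
  flat <- tibble::tibble(sample_id = sprintf("s%d", 1:30),
                         ms4a3_log2 = 5,
                         group = rep(c("high", "low"), c(5, 25)))
  b <- bootstrap_association(flat, n_iter = 100, seed = 1)
  expect_true(b$degenerate)
  expect_identical(b$Z, 0)
  expect_identical(b$p_two_sided, 1)
  expect_true(all(b$d == 0))

  small_low <- tibble::tibble(ms4a3_log2 = rnorm(10),
                              group = rep(c("high", "low"), c(7, 3)))
  expect_error(bootstrap_association(small_low, seed = 1), "smaller")
  one_high <- tibble::tibble(ms4a3_log2 = rnorm(10),
                             group = rep(c("high", "low"), c(1, 9)))
  expect_error(bootstrap_association(one_high, seed = 1), "at least 2")
})

test_that("resampling is seed-reproducible and Monte-Carlo stable under doubling", {
  cohort <- simulate_cohort(cohort_design(seed = 19))
  lab <- dplyr::mutate(cohort, group = .data$true_group)
  b1 <- bootstrap_association(lab, n_iter = 1000, seed = 5)
  b1b <- bootstrap_association(lab, n_iter = 1000, seed = 5)
  expect_identical(b1$d, b1b$d)
  b2 <- bootstrap_association(lab, n_iter = 2000, seed = 5)
  expect_identical(b2$d[1:1000], b1$d)  # same stream, extended
  expect_lt(abs(b2$M - b1$M), 2 * b1$SD / sqrt(1000))
})

test_that("with-replacement resampling is available behind a flag", {
  cohort <- simulate_cohort(cohort_design(seed = 23))
  lab <- dplyr::mutate(cohort, group = .data$true_group)
  b <- bootstrap_association(lab, n_iter = 500, seed = 2, replace = TRUE)
  expect_lt(b$M, 0)
  # with replacement the low group may be smaller than the high group
  tiny <- tibble::tibble(ms4a3_log2 = rnorm(8),
                         group = rep(c("high", "low"), c(5, 3)))
  expect_no_error(bootstrap_association(tiny, n_iter = 50, seed = 1,
                                        replace = TRUE))
})

test_that("tidy/glance summaries mirror the cohort-table layout", {
  cohort <- simulate_cohort(cohort_design(seed = 11))
  fit <- cohort_association(cohort, n_iter = 500, seed = 11)
  td <- tidy(fit)
  expect_named(td, c("cutoff", "n_high", "n_low", "pct_high", "M", "SD", "Z",
                     "p_two_sided", "p_2sf"))
  expect_equal(td$pct_high, pct_high(td$n_high, td$n_low))
  gl <- glance(fit)
  expect_true(gl$rule_applied %in% c("single_minimum", "five_percent_rule"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$bootstrap), "ggplot")
})
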