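make_measurements <- function(E, rho, condition = "c1") {
  tibble::tibble(cell_id = paste0(condition, "_", seq_along(E)),
                 condition = condition, bait_expression = E,
                 prey_expression = 50, rho_mean = rho, qc_pass = TRUE)
}

test_that("expression estimate is background-subtracted mean, floored at 0", {
  img <- matrix(100, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  img[mask] <- 500
  est <- estimate_expression(img, mask)
  expect_equal(est$expression, 400)
  expect_equal(est$background, 100)
  expect_equal(estimate_expression(matrix(0, 8, 8),
                                   diag(8) == 1)$expression, 0)
  # floor: dimmer inside than outside
  dim_in <- matrix(100, 8, 8); dim_in[1:2, ] <- 10
  m2 <- matrix(FALSE, 8, 8); m2[1:2, ] <- TRUE
  expect_equal(estimate_expression(dim_in, m2)$expression, 0)
  expect_error(estimate_expression(img, matrix(TRUE, 20, 20)), "background")
  expect_error(estimate_expression(img, matrix(FALSE, 20, 20)), "empty")
})

test_that("estimated expression rank-orders with simulated ground truth", {
  hits <- vapply(1:20, function(seed) {
    lo <- simulate_cell(small_config(seed = seed, bait_expression = 20))
    hi <- simulate_cell(small_config(seed = seed, bait_expression = 200))
    e_lo <- estimate_expression(lo$bait, lo$mask)$expression
    e_hi <- estimate_expression(hi$bait, hi$mask)$expression
    e_hi > e_lo
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("exact collinear input is recovered exactly by the linear fit", {
  m <- make_measurements(c(0, 50, 100), 0.10 + 0.002 * c(0, 50, 100))
  fit <- suppressWarnings(fit_zero_expression(m)) # perfect-fit lm warning
  expect_equal(fit$intercept, 0.10, tolerance = 1e-12)
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
  expect_equal(fit$n_cells, 3L)
})

test_that("two points give the interpolating line with a warning", {
  m <- make_measurements(c(10, 110), c(0.2, 0.4))
  expect_warning(fit <- fit_zero_expression(m), "minimum")
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.18, tolerance = 1e-12)
  expect_true(is.na(fit$intercept_sd))
})

test_that("degenerate fits are rejected or skipped per strictness", {
  same_e <- make_measurements(rep(50, 5), runif(5))
  expect_error(fit_zero_expression(same_e), "rank-deficient")
  two_conds <- dplyr::bind_rows(same_e,
                                make_measurements(c(1, 2, 3) * 50,
                                                  c(0.1, 0.22, 0.3), "c2"))
  expect_warning(fit <- fit_zero_expression(two_conds, strict = FALSE),
                 "skipped")
  expect_equal(fit$condition, "c2")
})

test_that("intercept estimate matches the OLS sampling distribution", {
  # known line + Gaussian noise: recovered intercept within 3 SE in ~99%
  set.seed(40)
  inside <- vapply(1:500, function(i) {
    E <- runif(20, 0, 300)
    rho <- 0.30 + 0.001 * E + rnorm(20, 0, 0.05)
    fit <- fit_zero_expression(make_measurements(E, rho))
    abs(fit$intercept - 0.30) < 3 * fit$intercept_sd
  }, logical(1))
  expect_gte(mean(inside), 0.98)
})

test_that("intercept consistency: near-zero expression reduces to the group mean", {
  set.seed(41)
  E <- runif(12, 0, 1e-3)
  rho <- rnorm(12, 0.4, 0.002)
  fit <- fit_zero_expression(make_measurements(E, rho))
  expect_equal(fit$intercept, mean(rho), tolerance = 0.01)
})

test_that("tidy, glance and confint expose the per-condition fits", {
  m <- dplyr::bind_rows(
    make_measurements(c(10, 60, 120, 200), c(0.2, 0.25, 0.31, 0.4), "a"),
    make_measurements(c(10, 60, 120, 200), c(0.05, 0.06, 0.04, 0.07), "b"))
  fit <- fit_zero_expression(m)
  td <- tidy(fit)
  expect_equal(nrow(td), 4) # 2 conditions x 2 terms
  expect_setequal(unique(td$term), c("intercept", "expression"))
  gl <- glance(fit)
  expect_true(all(c("r.squared", "n_cells") %in% names(gl)))
  ci <- confint(fit, level = 0.95)
  expect_true(all(ci$conf.low < ci$intercept & ci$intercept < ci$conf.high))
})

test_that("star thresholds follow the two-tailed t-test convention", {
  expect_identical(stars_for_p(c(0.009, 0.0099, 0.01, 0.03, 0.049, 0.05, 0.5)),
                   c("**", "**", "*", "*", "*", "", ""))
})

test_that("cell-mode comparison matches a Welch t-test with closed-form t", {
  set.seed(42)
  a <- rnorm(20, 0.8, 0.05); b <- rnorm(20, 0.05, 0.05)
  m <- dplyr::bind_rows(make_measurements(seq_along(a), a, "a"),
                        make_measurements(seq_along(b), b, "b"))
  cmp <- compare_conditions(m, "a", "b", mode = "cells")
  expect_gt(abs(cmp$t_statistic), 40)
  expect_lt(cmp$p_value, 0.01)
  expect_identical(cmp$stars, "**")
  ref <- t.test(a, b)
  expect_equal(cmp$t_statistic, unname(ref$statistic))
  expect_equal(cmp$p_value, ref$p.value)
  # identical groups: p = 1 by convention
  same <- dplyr::bind_rows(make_measurements(1:5, rep(0.3, 5), "a"),
                           make_measurements(1:5, rep(0.3, 5), "b"))
  eq <- compare_conditions(same, "a", "b", mode = "cells")
  expect_equal(eq$p_value, 1)
  expect_identical(eq$stars, "")
})

test_that("intercept-mode comparison uses the fits' standard errors", {
  set.seed(43)
  E <- runif(20, 10, 300)
  m <- dplyr::bind_rows(
    make_measurements(E, 0.4 + 0.0005 * E + rnorm(20, 0, 0.03), "a"),
    make_measurements(E, 0.0 + 0.0005 * E + rnorm(20, 0, 0.03), "b"))
  fit <- fit_zero_expression(m)
  cmp <- compare_conditions(fit, "a", "b", mode = "intercepts")
  ra <- fit[fit$condition == "a", ]; rb <- fit[fit$condition == "b", ]
  t_manual <- (ra$intercept - rb$intercept) /
    sqrt(ra$intercept_sd^2 + rb$intercept_sd^2)
  expect_equal(cmp$t_statistic, t_manual)
  expect_lt(cmp$p_value, 0.01)
  expect_error(compare_conditions(fit, "a", "zzz", mode = "intercepts"),
               "not found")
})

test_that("condition report joins fits and control comparisons", {
  set.seed(44)
  E <- runif(15, 10, 300)
  m <- dplyr::bind_rows(
    make_measurements(E, 0.35 + 0.0004 * E + rnorm(15, 0, 0.03), "hit"),
    make_measurements(E, 0.00 + 0.0004 * E + rnorm(15, 0, 0.03), "ctrl"))
  rep1 <- condition_report(m)
  expect_false("p_value" %in% names(rep1))
  rep2 <- condition_report(m, control = "ctrl")
  expect_true(is.na(rep2$p_value[rep2$condition == "ctrl"]))
  expect_identical(rep2$stars[rep2$condition == "hit"], "**")
  expect_error(condition_report(m, control = "nope"), "available")
})
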