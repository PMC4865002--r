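test_that("expected cases multiply person-years by rates cell-wise", {
  ages <- 40:90
  s <- build_single_decrement(gompertz_schedule(ages), 90)
  grid <- compute_pyar(data.frame(age_lower = c(40, 50), age_upper = c(49, 59),
                                  population = c(100, 200)), s, 5, 20)

  # all-zero rates
  zero <- matrix(0, nrow(grid$pyar), ncol(grid$pyar))
  expect_equal(expected_cases(grid, zero)$FN_p, 0)

  # direct product: 1000 PY at 10 per 100,000 is 0.1 cases
  expect_equal(1000 * 10 / 1e5, 0.1)
  one <- matrix(c(1e-4, rep(0, length(grid$pyar) - 1)),
                nrow(grid$pyar), ncol(grid$pyar))
  expect_equal(expected_cases(grid, one)$FN_p, grid$pyar[1, 1] * 1e-4)

  # random small grid against an elementwise multiply-and-sum oracle
  set.seed(3)
  rates <- matrix(runif(length(grid$pyar), 0, 1e-4),
                  nrow(grid$pyar), ncol(grid$pyar))
  cm <- expected_cases(grid, rates)
  brute <- 0
  for (i in seq_len(nrow(rates))) {
    for (j in seq_len(ncol(rates))) brute <- brute + grid$pyar[i, j] * rates[i, j]
  }
  expect_equal(cm$FN_p, brute, tolerance = 1e-12)
  expect_equal(cm$FN_p, sum(cm$D))
  expect_equal(cm$by_band, rowSums(cm$D))

  expect_error(expected_cases(grid, matrix(0, 2, 2)), class = "fef_grid_error")
})

test_that("attained-age rates are looked up along the Lexis diagonal", {
  # one person aged 60, no attrition, annual intervals: the case expectation
  # in future year t is the rate at age 60 + t, not the baseline-band rate
  ages <- 50:70
  s <- build_single_decrement(zero_schedule(ages), 70)
  grid <- compute_pyar(data.frame(age_lower = 60, age_upper = 60, population = 1),
                       s, 1, 3)
  rates <- data.frame(age = ages, rate = (ages - 50) * 1e-5)
  cm <- expected_cases(grid, project_constant(rates, grid))
  expect_equal(as.numeric(cm$D), c(10e-5, 11e-5, 12e-5), tolerance = 1e-12)
})

test_that("lifetime risk is cases over cohort size with guarded edge cases", {
  expect_equal(lifetime_risk(0, 1000), 0)
  expect_equal(lifetime_risk(1000, 1000), 1)
  expect_error(lifetime_risk(10, 0), class = "fef_undefined_error")
})

test_that("the modified excess-risk formula matches the back-solved algebraic oracle", {
  set.seed(101)
  for (k in 1:200) {
    lr_p <- runif(1, 1e-5, 0.3)
    n_p <- runif(1, 1e3, 1e7)
    n_e <- runif(1) * n_p
    rr <- runif(1, 1, 25)
    got <- lifetime_excess_risk(lr_p, n_p, n_e, rr)
    # independent route: solve LR_p * N_p = LR_u * N_u + LR_u * RR * N_e
    # numerically for LR_u
    f <- function(u) u * (n_p - n_e) + u * rr * n_e - lr_p * n_p
    u <- uniroot(f, c(0, 1), tol = 1e-15)$root
    expect_equal(got$LR_u, u, tolerance = 1e-9)
    expect_equal(got$LR_x, u * (rr - 1), tolerance = 1e-9)
  }
})

test_that("excess-risk limits and refusals behave as the formula requires", {
  # RR = 1: no excess whatever the split
  expect_equal(lifetime_excess_risk(0.1, 1e6, 3e5, 1)$LR_x, 0)
  # no one exposed: LR_u collapses to LR_p and LR_x = LR_p (RR - 1)
  out <- lifetime_excess_risk(0.02, 1e6, 0, 4)
  expect_equal(out$LR_u, 0.02)
  expect_equal(out$LR_x, 0.02 * 3)
  # protective exposures are refused with the formula's assumption named
  expect_error(lifetime_excess_risk(0.02, 1e6, 1e5, 0.8),
               regexp = "greater than 1", class = "fef_rr_error")
  expect_error(lifetime_excess_risk(0.02, 1e6, 2e6, 2),
               class = "fef_validation_error")
})

test_that("multi-level exposure shares one unexposed group", {
  lr_p <- 0.01; n_p <- 1e6
  n_e <- c(1e5, 5e4); rr <- c(2, 6)
  got <- lifetime_excess_risk(lr_p, n_p, n_e, rr)
  u <- lr_p * n_p / ((n_p - sum(n_e)) + sum(n_e * rr))
  expect_equal(got$LR_u, u, tolerance = 1e-12)
  expect_equal(got$LR_x, u * (rr - 1), tolerance = 1e-12)
  expect_equal(future_excess_number(got$LR_x, n_e), sum(u * (rr - 1) * n_e),
               tolerance = 1e-12)
})

test_that("future excess number and fraction are simple guarded products", {
  expect_equal(future_excess_number(0, 500), 0)
  expect_equal(future_excess_number(0.01, 1000), 10)
  expect_error(future_excess_number(-0.1, 10), class = "fef_validation_error")

  expect_equal(future_excess_fraction(7549, 23819), 7549 / 23819)
  expect_equal(future_excess_fraction(0, 100), 0)
  expect_error(future_excess_fraction(1, 0), class = "fef_undefined_error")
})

test_that("product of complements combines fractions", {
  expect_equal(combine_fractions(0.42), 0.42)
  expect_equal(combine_fractions(c(0.5, 0.5)), 0.75)
  set.seed(9)
  f <- runif(5)
  loop <- 1
  for (fk in f) loop <- loop * (1 - fk)
  expect_equal(combine_fractions(f), 1 - loop, tolerance = 1e-15)
  expect_equal(combine_fractions(f), combine_fractions(rev(f)))
  expect_gte(combine_fractions(f), max(f))
  expect_error(combine_fractions(c(0.2, 1.3)), class = "fef_validation_error")
  expect_error(combine_fractions(numeric(0)), class = "fef_validation_error")
})
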