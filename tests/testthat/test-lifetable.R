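test_that("survival tables match closed forms for degenerate and constant hazards", {
  ages <- 0:100
  # no decrement at all: everyone stays at risk
  s <- build_single_decrement(zero_schedule(ages), max_age = 100)
  expect_equal(s$p_at_risk, rep(1, 101))
  expect_identical(attr(s, "decrement_mode"), "single")

  # constant hazard: exponential survival
  s <- build_single_decrement(data.frame(age = ages, rate = 0.01), max_age = 100)
  expect_equal(s$p_at_risk, exp(-0.01 * (0:100)), tolerance = 1e-12)

  # competing constant hazards add under the constant-within-year convention
  d <- build_double_decrement(data.frame(age = ages, rate = 0.01),
                              data.frame(age = ages, rate = 0.02),
                              max_age = 100)
  expect_equal(d$p_at_risk, exp(-0.03 * (0:100)), tolerance = 1e-12)
  expect_identical(attr(d, "decrement_mode"), "double")

  # zero incidence degenerates double to single
  g <- gompertz_schedule(ages)
  expect_equal(build_double_decrement(g, zero_schedule(ages), 100)$p_at_risk,
               build_single_decrement(g, 100)$p_at_risk)
})

test_that("double decrement is dominated by single decrement, strictly under positive incidence", {
  ages <- 18:100
  mort <- gompertz_schedule(ages)
  inc <- power_incidence(ages, scale = 2e-4)
  s1 <- build_single_decrement(mort, 100)
  s2 <- build_double_decrement(mort, inc, 100)
  expect_true(all(s2$p_at_risk <= s1$p_at_risk))
  expect_true(all(s2$p_at_risk[-1] < s1$p_at_risk[-1]))
  expect_true(all(diff(s2$p_at_risk) <= 0))
  expect_true(all(s2$p_at_risk >= 0 & s2$p_at_risk <= 1))
})

test_that("raising mortality never increases survival or person-years", {
  ages <- 18:100
  strata <- data.frame(age_lower = c(18, 40), age_upper = c(39, 64),
                       population = c(1000, 2000))
  set.seed(42)
  for (rep in 1:5) {
    rate <- runif(length(ages), 0, 0.05)
    bump <- rate * (1 + runif(length(ages), 0, 1))
    s_lo <- build_single_decrement(data.frame(age = ages, rate = rate), 100)
    s_hi <- build_single_decrement(data.frame(age = ages, rate = bump), 100)
    expect_true(all(s_hi$p_at_risk <= s_lo$p_at_risk + 1e-15))
    p_lo <- compute_pyar(strata, s_lo, 5, 30)
    p_hi <- compute_pyar(strata, s_hi, 5, 30)
    expect_true(all(p_hi$pyar <= p_lo$pyar + 1e-9))
  }
})

test_that("person-years follow the declared conventions", {
  ages <- 0:100
  none <- build_single_decrement(zero_schedule(ages), 100)

  # no attrition: one person aged 60, horizon 10 in 5-year intervals
  one60 <- data.frame(age_lower = 60, age_upper = 60, population = 1)
  p <- compute_pyar(one60, none, 5, 10)
  expect_equal(as.numeric(p$pyar), c(5, 5))

  # zero hazards, unbounded horizon: exactly max_age - age person-years
  p <- compute_pyar(one60, none, 5, 60)
  expect_equal(sum(p$pyar), 40)

  # conservation: total PYAR = population x horizon when nobody exits
  many <- data.frame(age_lower = c(20, 30), age_upper = c(29, 39),
                     population = c(123, 456))
  p <- compute_pyar(many, none, 5, 20)
  expect_equal(sum(p$pyar), (123 + 456) * 20)
  # cell bound: no cell exceeds band population x interval length
  expect_true(all(p$pyar <= outer(many$population, rep(5, 4)) * (1 + 1e-12)))

  # within-year integral under constant hazard: (1 - exp(-h)) / h
  h <- 0.3
  s <- build_single_decrement(data.frame(age = ages, rate = h), 100)
  p <- compute_pyar(one60, s, 1, 1)
  expect_equal(as.numeric(p$pyar), (1 - exp(-h)) / h, tolerance = 1e-12)
})

test_that("schedule and coverage violations raise classed errors", {
  ages <- 0:80
  expect_error(build_single_decrement(gompertz_schedule(ages), max_age = 100),
               class = "fef_coverage_error")
  expect_error(build_single_decrement(data.frame(age = ages, rate = -0.1), 80),
               class = "fef_validation_error")
  gappy <- gompertz_schedule(ages)[-10, ]
  expect_error(build_single_decrement(gappy, 80), class = "fef_coverage_error")

  s <- build_single_decrement(gompertz_schedule(40:80), 80)
  outside <- data.frame(age_lower = 20, age_upper = 30, population = 10)
  expect_error(compute_pyar(outside, s, 5, 10), class = "fef_coverage_error")
})

test_that("cumulative risk sums rates and over-states the lifetime risk", {
  ages <- 0:90
  expect_equal(cumulative_risk(zero_schedule(ages), 85)$cumulative_rate, 0)
  expect_identical(cumulative_risk(zero_schedule(ages), 85)$one_in_n, Inf)

  cr <- cumulative_risk(data.frame(age = ages, rate = 0.001), 85)
  expect_equal(cr$cumulative_rate, 0.085, tolerance = 1e-12)
  expect_equal(cr$risk, 1 - exp(-0.085), tolerance = 1e-12)
  expect_equal(cr$one_in_n, 1 / 0.085, tolerance = 1e-12)

  expect_error(cumulative_risk(data.frame(age = 40:60, rate = 0.001), 85),
               class = "fef_coverage_error")

  # under positive competing mortality the cumulative risk exceeds the
  # person-years lifetime risk for the same cohort
  fit <- one_stratum_fef(p = 0.1, rr = 2, horizon = 50)
  cr <- cumulative_risk(fit$inputs$incidence, 90)
  expect_gt(cr$cumulative_rate, fit$results$LR_p)
})
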