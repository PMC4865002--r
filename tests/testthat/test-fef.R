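test_that("uniform one-stratum FEF collapses to Levin's fraction", {
  for (p in c(0.02, 0.2, 0.7)) {
    for (rr in c(1.5, 4, 15)) {
      fit <- one_stratum_fef(p, rr)
      expect_equal(fit$results$FEF, levin_af(p, rr), tolerance = 1e-13)
    }
  }
})

test_that("no exposure means no excess burden", {
  fit <- one_stratum_fef(0, 5)
  expect_equal(fit$results$FEN, 0)
  expect_equal(fit$results$FEF, 0)
  expect_equal(fit$results$LR_u, fit$results$LR_p)
})

test_that("burden outputs respect their bounds", {
  fit <- one_stratum_fef(0.3, 8)
  r <- fit$results
  expect_true(r$FEF >= 0 && r$FEF < 1)
  expect_lt(r$FEN, r$FN_p)
  expect_lte(r$LR_u, r$LR_p)
  expect_lte(r$LR_p, r$LR_u * 8)
  expect_gte(r$LR_x, 0)
})

test_that("FEF increases strictly with RR and with prevalence", {
  fefs_rr <- sapply(c(1.2, 2, 5, 10), function(rr) one_stratum_fef(0.1, rr)$results$FEF)
  expect_true(all(diff(fefs_rr) > 0))
  fefs_p <- sapply(c(0.01, 0.1, 0.3, 0.6), function(p) one_stratum_fef(p, 3)$results$FEF)
  expect_true(all(diff(fefs_p) > 0))
})

test_that("at low prevalence the excess risk approaches LR_p * (RR - 1)", {
  fit <- one_stratum_fef(1e-6, 5)
  r <- fit$results
  expect_equal(r$LR_x, r$LR_p * 4, tolerance = 1e-4)
})

test_that("group FENs sum to the pooled total", {
  sc <- generate_scenario(seed = 4, prevalence = c(male = 0.1, female = 0.05),
                          rr = 3)
  fit <- fef_from_scenario(sc)
  expect_equal(fit$total$FEN, sum(fit$results$FEN), tolerance = 1e-12)
  expect_equal(fit$total$FN_p, sum(fit$results$FN_p), tolerance = 1e-12)
  expect_equal(fit$total$FEF, fit$total$FEN / fit$total$FN_p, tolerance = 1e-12)
})

test_that("multi-level exposure computes per-level excess and sums the FENs", {
  levels <- data.frame(level = c("low", "high"),
                       prevalence = c(0.15, 0.05), rr = c(2, 8))
  pop <- data.frame(sex = "all", age_lower = 40L, age_upper = 44L,
                    population = 10000, prevalence_exposed = 0.2)
  ages <- 40:90
  mort <- gompertz_schedule(ages)
  inc <- power_incidence(ages, scale = 2e-4)
  fit <- fef(pop, mort, inc, rr = levels, index_year = 2020,
             interval_length = 5, horizon = 40, max_age = 90)
  r <- fit$results
  n_e <- 10000 * levels$prevalence
  ler <- lifetime_excess_risk(r$LR_p, 10000, n_e, levels$rr)
  expect_equal(r$FEN, sum(ler$LR_x * n_e), tolerance = 1e-12)
  expect_equal(r$N_e, sum(n_e))
  expect_error(
    fef(pop, mort, inc, rr = data.frame(prevalence = c(0.6, 0.5), rr = c(2, 3)),
        index_year = 2020, horizon = 40, max_age = 90),
    class = "fef_validation_error")
})

test_that("FEF is invariant to the projector under uniform prevalence", {
  # the excess fraction is algebra over LR_p, N_e, N_u, RR; projected rates
  # cancel, so constant and drifting projections agree on FEF (not on FN_p)
  sc <- generate_scenario(seed = 8, prevalence = c(male = 0.2, female = 0.2),
                          rr = 4, history_years = 8, drift = -0.01)
  fit_c <- fef_from_scenario(sc, projector = "constant")
  fit_l <- fef_from_scenario(sc, projector = "loglinear")
  expect_false(isTRUE(all.equal(fit_c$results$FN_p, fit_l$results$FN_p)))
  expect_equal(fit_c$results$FEF, fit_l$results$FEF, tolerance = 1e-10)
})

test_that("fitted objects print, summarise, plot and expose coefficients", {
  fit <- one_stratum_fef(0.1, 3)
  expect_output(print(fit), "Future excess fraction")
  expect_output(print(summary(fit)), "Per-band results")
  expect_named(coef(fit), "FEF_all")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("input validation names the offending rows and bands", {
  pop <- data.frame(sex = "m", age_lower = c(20, 25), age_upper = c(24, 29),
                    population = c(10, 10), prevalence_exposed = c(0.1, 1.2))
  expect_error(validate_population <- fef(pop, gompertz_schedule(20:100),
                                          power_incidence(20:100), rr = 2,
                                          index_year = 2020),
               regexp = "row 2", class = "fef_validation_error")
  pop$prevalence_exposed <- 0.1
  pop$age_lower[2] <- 23
  expect_error(fef(pop, gompertz_schedule(20:100), power_incidence(20:100),
                   rr = 2, index_year = 2020),
               regexp = "overlapping", class = "fef_validation_error")
})
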