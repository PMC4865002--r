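# Small, fast fixtures shared across test files; everything is built in code.

# Single-band cohort with a uniform exposure prevalence, run end to end.
# Cheap enough to call hundreds of times in property tests.
one_stratum_fef <- function(p, rr, incidence_rate = 2e-4, horizon = 40) {
  pop <- data.frame(sex = "all", age_lower = 40L, age_upper = 44L,
                    population = 10000, prevalence_exposed = p)
  ages <- 40:90
  mort <- data.frame(age = ages, rate = 1e-4 * exp(0.08 * (ages - 40)))
  inc <- data.frame(age = ages, rate = incidence_rate * (1 + (ages - 40) / 50))
  fef(pop, mort, inc, rr = rr, index_year = 2020, interval_length = 5,
      horizon = horizon, max_age = 90)
}

# Gompertz mortality / increasing incidence schedules over a given age range.
gompertz_schedule <- function(ages, a = 5e-5, b = 0.09) {
  data.frame(age = ages, rate = a * exp(b * ages))
}

power_incidence <- function(ages, scale = 5e-5, power = 3, ref = 70) {
  data.frame(age = ages, rate = scale * (ages / ref)^power)
}

zero_schedule <- function(ages) data.frame(age = ages, rate = 0)
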