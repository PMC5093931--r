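test_that("zero incidence produces no AMI records at all", {
  sc <- default_scenario("men", cohort_n = 200, incidence = 0)
  sim <- simulate_event_histories(sc, seed = 5)
  expect_equal(nrow(sim$admissions), 0L)
  expect_equal(sum(sim$deaths$underlying_cause_ami), 0L)
  expect_equal(sum(sim$deaths$ami_anywhere), 0L)
  expect_equal(nrow(sim$truth$first_events), 0L)
})

test_that("registry incidence matches a flat hazard within Monte-Carlo error", {
  # 500,000 persons aged 60-69 at the index year, constant hazard 0.002
  # in that decade, no trend, negligible background mortality
  i_vec <- ifelse(0:99 >= 60 & 0:99 <= 69, 0.002, 0)
  n_coh <- ifelse(0:99 >= 60 & 0:99 <= 69, 50000, 0)
  sc <- simulation_scenario(ages = 0:99, cohort_n = n_coh, incidence = i_vec,
                            case_fatality_30d = 0, other_mortality = 1e-6,
                            incidence_trend = 0, case_fatality_trend = 0,
                            registry_start_year = 1998, index_year = 2010)
  sim <- simulate_event_histories(sc, seed = 8)
  ev <- classify_events(sim$admissions, sim$deaths, as.Date("1998-01-01"))
  rt <- incidence_rates(ev, sim$truth$population, 2010,
                        bands = data.frame(age_low = 60, age_high = 69))
  # 3 Monte-Carlo standard errors of a Poisson count around 200 per 100,000
  mc_se <- 1e5 * sqrt(rt$count) / (rt$denominator * 1e5)
  expect_lt(abs(rt$rate - 200), 3 * mc_se + 1e-9)
})

test_that("a later registry start never reduces index-year first events", {
  sc <- default_scenario("men", cohort_n = 400,
                         registry_start_year = 1980)
  sim <- simulate_event_histories(sc, seed = 77)
  first_2010 <- function(start) {
    ev <- classify_events(sim$admissions, sim$deaths, start)
    sum(ev$first_event & format(ev$event_date, "%Y") == "2010")
  }
  expect_gte(first_2010("2005-01-01"), first_2010("1980-01-01"))
})

test_that("survey emulation reduces to the truth as the sample grows", {
  age <- 0:99
  p <- 0.1 / (1 + exp(-0.1 * (age - 65)))
  pop <- data.frame(age = age, pop = rep(1000, 100))
  prev <- data.frame(age = age, p = p)
  set.seed(15)
  big <- emulate_health_survey(prev, pop, n_total = 1e9)
  hi <- ifelse(is.na(big$age_high), 99, big$age_high)
  truth_band <- vapply(seq_len(nrow(big)), function(g)
    mean(p[age >= big$age_low[g] & age <= hi[g]]), numeric(1))
  informative <- truth_band >= 0.01
  expect_lt(max(abs(big$rate - truth_band)[informative] /
                  truth_band[informative]), 0.005)
  # binomial standard errors follow from the realised rates
  expect_equal(big$se, sqrt(big$rate * (1 - big$rate) / big$denominator),
               tolerance = 1e-12)
})

test_that("zero-prevalence truth surveys as all-zero with zero SEs", {
  age <- 0:99
  pop <- data.frame(age = age, pop = rep(1000, 100))
  prev <- data.frame(age = age, p = rep(0, 100))
  tab <- emulate_health_survey(prev, pop, n_total = 8610)
  expect_true(all(tab$rate == 0))
  expect_true(all(tab$se == 0))
})

test_that("vital-statistics emulation tabulates deaths per person-year", {
  deaths <- data.frame(person_id = 1:6,
                       death_date = as.Date("2010-06-01") + 0:5,
                       underlying_cause_ami = c(TRUE, TRUE, FALSE, FALSE,
                                                FALSE, FALSE),
                       ami_anywhere = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                        FALSE),
                       age_at_death = c(62, 63, 67, 67, 82, 90))
  py <- data.frame(age = 0:99, py = rep(100, 100))
  vt <- emulate_vital_statistics(deaths, py, 2010)
  b60 <- vt$ami[vt$ami$age_low == 60, ]
  expect_equal(b60$rate, 2 / 500)
  expect_equal(vt$all_cause[vt$all_cause$age_low == 65, ]$rate, 2 / 500)
  # no deaths -> all-zero tables; all deaths AMI-flagged -> identical tables
  vt0 <- emulate_vital_statistics(deaths[0, ], py, 2010)
  expect_true(all(vt0$ami$rate == 0) && all(vt0$all_cause$rate == 0))
  deaths_all <- deaths
  deaths_all$ami_anywhere <- TRUE
  vt1 <- emulate_vital_statistics(deaths_all, py, 2010)
  expect_equal(vt1$ami$rate, vt1$all_cause$rate)
})

test_that("simulated index-year death rates match the analytic schedule", {
  sc <- default_scenario("men", cohort_n = 3000)
  sim <- simulate_event_histories(sc, seed = 60)
  vt <- emulate_vital_statistics(sim$deaths, sim$truth$person_years, 2010)
  ai <- analytic_inputs(sc)
  # compare all-cause band rates against the analytic total death rate,
  # population-weighted within bands, to 3 Monte-Carlo SEs
  tab <- vt$all_cause
  hi <- ifelse(is.na(tab$age_high), max(ai$age), tab$age_high)
  pop <- merge(data.frame(age = ai$age), sim$truth$population, all.x = TRUE)
  pop$pop[is.na(pop$pop)] <- 0
  for (g in which(tab$age_low >= 40)) {
    inb <- ai$age >= tab$age_low[g] & ai$age <= hi[g]
    w <- pop$pop[inb]
    if (sum(w) == 0) next
    expected <- sum(ai$all_cause[inb] * w) / sum(w)
    mc_se <- sqrt(max(tab$count[g], 1)) / tab$denominator[g]
    expect_lt(abs(tab$rate[g] - expected), 3 * mc_se + 0.1 * expected)
  }
})

test_that("scenario validation rejects impossible inputs", {
  expect_error(default_scenario("men", incidence = -0.01), "non-negative")
  expect_error(default_scenario("men", case_fatality_30d = 1.2), "\\[0, 1\\]")
  expect_error(default_scenario("men", registry_start_year = 2020),
               "registry")
  expect_error(default_scenario("men", incidence = NaN), "non-finite")
})

test_that("noise-free single-year emulation lets the solver recover truth", {
  # the end-to-end ground-truth recovery property: no trend, exact survey
  # at single-year resolution, analytic vital statistics
  sc <- default_scenario("men", cohort_n = 10, incidence_trend = 0,
                         case_fatality_trend = 0)
  ai <- analytic_inputs(sc)
  pop <- data.frame(age = ai$age, pop = rep(1, nrow(ai)))
  bands1 <- data.frame(age_low = ai$age, age_high = ai$age)
  survey <- emulate_health_survey(data.frame(age = ai$age, p = ai$p), pop,
                                  n_total = 1e6, bands = bands1,
                                  exact = TRUE)
  fit <- solve_steady_state(pmin(survey$rate, 1 - 1e-9), ai$csmr_excess,
                            ai$all_cause, age = ai$age)
  sel <- ai$age >= 40 & ai$age <= 84
  rel <- abs(fit$incidence[sel] - ai$incidence_true[sel]) /
    ai$incidence_true[sel]
  expect_lt(max(rel), 0.05)
})

test_that("10-year-band sigmoid smoothing bias stays bounded", {
  # the realistic survey resolution: noise-free but banded and smoothed;
  # the logistic cannot represent the true curve exactly, which costs up
  # to ~11% locally in back-calculated incidence (regression bound 15%)
  sc <- default_scenario("men", cohort_n = 10, incidence_trend = 0,
                         case_fatality_trend = 0)
  ai <- analytic_inputs(sc)
  pop <- data.frame(age = ai$age, pop = exp(-((ai$age - 40) / 60)^2))
  survey <- emulate_health_survey(data.frame(age = ai$age, p = ai$p), pop,
                                  n_total = 8610, exact = TRUE)
  pf <- fit_sigmoid_prevalence(survey, ai$age)
  fit <- solve_steady_state(pmin(pf$prevalence, 1 - 1e-9), ai$csmr_excess,
                            ai$all_cause, age = ai$age)
  sel <- ai$age >= 40 & ai$age <= 84
  rel <- abs(fit$incidence[sel] - ai$incidence_true[sel]) /
    ai$incidence_true[sel]
  expect_lt(max(rel), 0.15)
})
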