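adm_row <- function(pid, date, los = 3, emergency = TRUE, primary = TRUE,
                    alive = TRUE, age = 65) {
  data.frame(person_id = pid, admission_date = as.Date(date),
             emergency = emergency, primary_diagnosis_ami = primary,
             length_of_stay = los, discharged_alive = alive,
             age_at_admission = age)
}

death_row <- function(pid, date, underlying = TRUE, anywhere = underlying,
                      age = 70) {
  data.frame(person_id = pid, death_date = as.Date(date),
             underlying_cause_ami = underlying, ami_anywhere = anywhere,
             age_at_death = age)
}

no_deaths <- data.frame(person_id = integer(0),
                        death_date = as.Date(character(0)),
                        underlying_cause_ami = logical(0),
                        ami_anywhere = logical(0),
                        age_at_death = numeric(0))

test_that("a single qualifying admission is one non-fatal first event", {
  ev <- classify_events(adm_row(1, "2010-03-01"), no_deaths, "1998-01-01")
  expect_equal(nrow(ev), 1L)
  expect_false(ev$fatal)
  expect_true(ev$first_event)
  expect_true(ev$from_admission)
})

test_that("a death within 30 days of an admission merges into one fatal event", {
  ev <- classify_events(adm_row(1, "2010-03-01"),
                        death_row(1, "2010-03-21"), "1998-01-01")
  expect_equal(nrow(ev), 1L)
  expect_true(ev$fatal)
  expect_equal(ev$event_date, as.Date("2010-03-01"))
  # day 30 exactly is still inside the window
  ev30 <- classify_events(adm_row(2, "2010-03-01"),
                          death_row(2, "2010-03-31"), "1998-01-01")
  expect_equal(nrow(ev30), 1L)
  expect_true(ev30$fatal)
  # day 31 opens a second (fatal, stand-alone death) event
  ev31 <- classify_events(adm_row(3, "2010-03-01"),
                          death_row(3, "2010-04-01"), "1998-01-01")
  expect_equal(nrow(ev31), 2L)
  expect_equal(sum(ev31$first_event), 1L)
})

test_that("an earlier event in the window makes a later one non-first", {
  adm <- rbind(adm_row(1, "2005-06-01"), adm_row(1, "2010-06-01"))
  ev <- classify_events(adm, no_deaths, "1998-01-01")
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$first_event[order(ev$event_date)], c(TRUE, FALSE))
})

test_that("a one-day stay discharged alive does not qualify", {
  ev <- classify_events(adm_row(1, "2010-03-01", los = 1), no_deaths,
                        "1998-01-01")
  expect_equal(nrow(ev), 0L)
  # nor do non-emergency or non-primary admissions
  expect_equal(nrow(classify_events(adm_row(1, "2010-03-01",
                                            emergency = FALSE),
                                    no_deaths, "1998-01-01")), 0L)
  expect_equal(nrow(classify_events(adm_row(1, "2010-03-01",
                                            primary = FALSE),
                                    no_deaths, "1998-01-01")), 0L)
})

test_that("a non-AMI death within 30 days of an admission marks it fatal", {
  ev <- classify_events(adm_row(1, "2010-03-01"),
                        death_row(1, "2010-03-15", underlying = FALSE,
                                  anywhere = FALSE),
                        "1998-01-01")
  expect_equal(nrow(ev), 1L)
  expect_true(ev$fatal)
})

test_that("event classification is invariant to record order", {
  set.seed(21)
  adm <- rbind(adm_row(1, "2005-06-01"), adm_row(1, "2010-06-01"),
               adm_row(2, "2009-02-01"), adm_row(3, "2010-11-30"))
  dth <- rbind(death_row(2, "2009-02-20"), death_row(4, "2010-07-07"))
  ev1 <- classify_events(adm, dth, "1998-01-01")
  perm_a <- adm[sample(nrow(adm)), ]
  perm_d <- dth[sample(nrow(dth)), ]
  ev2 <- classify_events(perm_a, perm_d, "1998-01-01")
  expect_equal(ev1, ev2, ignore_attr = TRUE)
})

test_that("deaths predating an admission are rejected with a diagnostic", {
  expect_warning(
    ev <- classify_events(adm_row(1, "2010-06-01"),
                          death_row(1, "2010-01-01"), "1998-01-01"),
    "predate")
  expect_equal(nrow(ev), 1L)  # the admission event survives
  expect_false(ev$fatal)
  expect_equal(nrow(attr(ev, "rejected")), 1L)
})

test_that("shorter lookback never decreases the count of 'first' events", {
  # recurrent histories: first events before a late registry start get
  # misclassified as first events of their recurrences
  set.seed(31)
  n <- 400
  adm <- do.call(rbind, lapply(seq_len(n), function(pid) {
    k <- 1 + rpois(1, 1.2)
    dates <- as.Date("1998-01-01") + sort(sample.int(4700, k))
    do.call(rbind, lapply(as.character(dates), function(d)
      adm_row(pid, d)))
  }))
  count_first_2010 <- function(start) {
    ev <- classify_events(adm, no_deaths, start)
    sum(ev$first_event & format(ev$event_date, "%Y") == "2010")
  }
  n_long <- count_first_2010("1998-01-01")
  n_short <- count_first_2010("2008-01-01")
  expect_gte(n_short, n_long)
})

test_that("incidence rates and intervals follow the Poisson formulas", {
  pop <- data.frame(age = 0:99, pop = rep(1e6 / 100, 100))
  ev <- data.frame(person_id = 1:100,
                   event_date = as.Date("2010-06-15"),
                   age_at_event = rep(seq(40, 49), 10),
                   fatal = FALSE, first_event = TRUE, from_admission = TRUE)
  bands <- data.frame(age_low = c(0, 40, 50), age_high = c(39, 49, NA))
  rt <- incidence_rates(ev, pop, 2010, bands = bands)
  r40 <- rt[rt$age_low == 40, ]
  expect_equal(r40$rate, 1e5 * 100 / 1e5)  # n=100, pop=100,000 -> 100
  # hand check at n=100, pop=1e6: rate 10, CI (8.04, 11.96)
  pop2 <- data.frame(age = 0:99, pop = rep(1e4, 100))
  rt2 <- incidence_rates(ev, pop2, 2010,
                         bands = data.frame(age_low = 0, age_high = NA))
  expect_equal(rt2$rate, 10)
  expect_equal(rt2$lo, 10 * (1 - qnorm(0.975) / 10), tolerance = 1e-10)
  expect_equal(rt2$hi, 10 * (1 + qnorm(0.975) / 10), tolerance = 1e-10)
  expect_equal(round(c(rt2$lo, rt2$hi), 2), c(8.04, 11.96))
})

test_that("large-count CIs have half-width 1.96 rate / sqrt(n)", {
  # the Table-2 scale: n = 41,689 events at rate 162 -> CI (160.4, 163.6)
  n <- 41689
  pop_size <- 1e5 * n / 162
  ev <- data.frame(person_id = seq_len(n),
                   event_date = as.Date("2010-06-15"),
                   age_at_event = 60, fatal = FALSE, first_event = TRUE,
                   from_admission = TRUE)
  pop <- data.frame(age = 60, pop = pop_size)
  rt <- incidence_rates(ev, pop, 2010,
                        bands = data.frame(age_low = 0, age_high = NA))
  expect_equal(rt$rate, 162, tolerance = 1e-10)
  expect_equal(rt$lo, 160.4, tolerance = 1e-3)
  expect_equal(rt$hi, 163.6, tolerance = 1e-3)
})

test_that("empty bands report zero with a rule-of-three upper bound", {
  pop <- data.frame(age = 0:99, pop = rep(1000, 100))
  ev <- data.frame(person_id = 1, event_date = as.Date("2010-06-15"),
                   age_at_event = 45, fatal = FALSE, first_event = TRUE,
                   from_admission = TRUE)
  bands <- data.frame(age_low = c(0, 40), age_high = c(39, NA))
  rt <- incidence_rates(ev, pop, 2010, bands = bands)
  r0 <- rt[rt$age_low == 0, ]
  expect_equal(r0$rate, 0)
  expect_equal(r0$lo, 0)
  expect_equal(r0$hi, 1e5 * 3 / (40 * 1000))
  # band counts sum to the year's first events
  expect_equal(sum(rt$count), 1)
  # missing population band is rejected naming the band
  expect_error(incidence_rates(ev, pop[pop$age < 30, ], 2010, bands = bands),
               "missing")
})

test_that("the exact-Poisson interval option matches the chi-square limits", {
  ev <- data.frame(person_id = 1:100, event_date = as.Date("2010-06-15"),
                   age_at_event = 60, fatal = FALSE, first_event = TRUE,
                   from_admission = TRUE)
  pop <- data.frame(age = 60, pop = 1e6)
  rt <- incidence_rates(ev, pop, 2010,
                        bands = data.frame(age_low = 0, age_high = NA),
                        ci = "exact")
  expect_equal(rt$lo, 1e5 * qchisq(0.025, 200) / 2 / 1e6, tolerance = 1e-12)
  expect_equal(rt$hi, 1e5 * qchisq(0.975, 202) / 2 / 1e6, tolerance = 1e-12)
})
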