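#' Define a synthetic AMI study scenario
#'
#' A scenario fixes the ground truth of the simulated world: birth-cohort
#' sizes, the index-year first-AMI hazard by age, the 30-day case-fatality
#' probability, other-cause mortality, the multipliers governing survivors
#' (long-term excess mortality and recurrence), the secular trends that
#' scale the AMI hazards back in calendar time, and the registry window.
#' Every person is simulated in continuous time from birth through the end
#' of the index year; the registry only observes records from
#' `registry_start_year` onwards, emulating a linked
#' admissions/death-certificate dataset with a fixed lookback.
#'
#' @param ages integer single-year age grid (default `0:99`).
#' @param cohort_n births per single-year cohort (scalar or per-age
#'   vector): the cohort aged `a` at the index year starts with
#'   `cohort_n[a]` live births.
#' @param incidence first-AMI hazard per disease-free person-year at the
#'   index year, by age.
#' @param case_fatality_30d probability that an AMI is fatal within 30
#'   days, by age (capped at 0.97 after trend scaling).
#' @param other_mortality other-cause mortality hazard per person-year, by
#'   age.
#' @param excess_mult total mortality of AMI survivors as a multiple of
#'   other-cause mortality (default 2: a doubled death rate).
#' @param recurrence_mult recurrent-AMI hazard as a multiple of the
#'   first-event hazard at the same age and calendar time (default 3).
#' @param incidence_trend,case_fatality_trend proportional annual calendar
#'   change of the AMI hazard and of 30-day case fatality (negative =
#'   historical rates were higher).
#' @param trend_horizon years before the index year over which the trends
#'   apply; earlier history is held flat at the horizon level.
#' @param index_year calendar year the cross-sectional comparison refers
#'   to.
#' @param registry_start_year first calendar year with linked records.
#' @param survey_underreport multiplicative self-report factor applied to
#'   true prevalence when emulating the health survey (1 = no bias).
#' @param sex label carried through to reports.
#' @return object of class `"simulation_scenario"`.
#' @seealso [default_scenario()], [simulate_event_histories()],
#'   [analytic_inputs()]
#' @export
simulation_scenario <- function(ages = 0:99, cohort_n = 3000,
                                incidence, case_fatality_30d,
                                other_mortality,
                                excess_mult = 2, recurrence_mult = 3,
                                incidence_trend = 0,
                                case_fatality_trend = 0,
                                trend_horizon = 28,
                                index_year = 2010,
                                registry_start_year = 1998,
                                survey_underreport = 1,
                                sex = "men") {
  A <- length(ages)
  cohort_n <- rep_len(as.numeric(cohort_n), A)
  incidence <- rep_len(as.numeric(incidence), A)
  case_fatality_30d <- rep_len(as.numeric(case_fatality_30d), A)
  other_mortality <- rep_len(as.numeric(other_mortality), A)
  incidence_trend <- rep_len(as.numeric(incidence_trend), A)
  if (any(!is.finite(c(incidence, other_mortality))))
    stop("non-finite hazards in scenario")
  if (any(incidence < 0) || any(other_mortality < 0))
    stop("hazards must be non-negative")
  if (any(case_fatality_30d < 0 | case_fatality_30d > 1))
    stop("case-fatality probabilities must lie in [0, 1]")
  if (registry_start_year > index_year)
    stop("registry must start no later than the index year")
  if (any(incidence_trend <= -1) || case_fatality_trend <= -1)
    stop("annual trends must exceed -1")
  structure(list(ages = as.integer(ages), cohort_n = cohort_n,
                 incidence = incidence,
                 case_fatality_30d = case_fatality_30d,
                 other_mortality = other_mortality,
                 excess_mult = excess_mult,
                 recurrence_mult = recurrence_mult,
                 incidence_trend = incidence_trend,
                 case_fatality_trend = case_fatality_trend,
                 trend_horizon = trend_horizon,
                 index_year = index_year,
                 registry_start_year = registry_start_year,
                 survey_underreport = survey_underreport,
                 sex = sex),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "<simulation_scenario> %s: %d cohorts (%.0f persons), index year %d, registry from %d\n",
    x$sex, length(x$ages), sum(x$cohort_n), x$index_year,
    x$registry_start_year))
  cat(sprintf("  incidence trend %+.1f%%/yr over %d y, 30-day CF trend %+.1f%%/yr\n",
              100 * x$incidence_trend[1], x$trend_horizon,
              100 * x$case_fatality_trend))
  invisible(x)
}

#' Default desk-scale AMI scenario
#'
#' A Gompertz-like first-AMI hazard calibrated to the magnitude and age
#' slope of measured English first-AMI rates (roughly 10^2 per 100,000
#' around age 55 rising to 10^3 beyond 85), a logistic-in-age 30-day case
#' fatality, Gompertz other-cause mortality, a 4% annual historical
#' decline in AMI incidence and 1% in case fatality over the previous 28
#' years, and a 1998 registry start with 2010 index year. Women get the
#' same shapes with incidence scaled by 0.45. `cohort_n = 3000` keeps a
#' full two-sex study tractable on a single desk CPU.
#'
#' @param sex `"men"` or `"women"`.
#' @param cohort_n births per single-year cohort.
#' @param ... overrides passed on to [simulation_scenario()].
#' @return a [simulation_scenario()].
#' @export
default_scenario <- function(sex = c("men", "women"), cohort_n = 3000, ...) {
  sex <- match.arg(sex)
  a <- 0:99
  i_star <- 6.6e-5 * exp(0.0626 * a) * if (sex == "men") 1 else 0.45
  cf30 <- 1 / (1 + exp(-(-4 + 0.045 * a)))
  m_star <- 5e-5 * exp(0.088 * a)
  args <- list(ages = a, cohort_n = cohort_n, incidence = i_star,
               case_fatality_30d = cf30, other_mortality = m_star,
               incidence_trend = -0.04, case_fatality_trend = -0.01,
               trend_horizon = 28, sex = sex)
  args[names(list(...))] <- list(...)
  do.call(simulation_scenario, args)
}

# continuous year fraction -> Date
.frac_to_date <- function(t) {
  as.Date("1970-01-01") + floor((t - 1970) * 365.25)
}

# calendar trend factor at continuous time t (vectorised over t)
.trend_factor <- function(t, tau, horizon, index_year) {
  back <- pmin(pmax(index_year + 0.5 - t, 0), horizon)
  (1 + tau)^(-back)
}

#' Simulate person-level event histories with known ground truth
#'
#' Draws every person's life history in continuous time from birth through
#' the end of the index year under competing piecewise-constant hazards:
#' while healthy, first AMI (scaled back in calendar time by the incidence
#' trend) competes with other-cause death; an AMI is immediately fatal
#' with the age-specific 30-day probability (a death record with AMI as
#' underlying cause), otherwise it produces an emergency admission record
#' (primary AMI diagnosis, length of stay of at least 2 days, discharged
#' alive) and moves the person to the diseased state, where mortality is
#' `excess_mult` times the other-cause hazard and recurrent AMIs occur at
#' `recurrence_mult` times the first-event hazard. Deaths of survivors
#' carry the AMI-anywhere certificate flag. At most one transition is
#' drawn per person per one-year age interval (the 30-day fatality of an
#' event is still resolved at the event itself).
#'
#' Only records dated from `registry_start_year` onwards are emitted,
#' reproducing the left truncation of a lookback-limited registry.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed RNG seed.
#' @return list with `admissions` and `deaths` record tables (see
#'   [classify_events()] for columns) and `truth`, a list of tables the
#'   registry cannot see: `population` (alive persons by completed age at
#'   the index-year midpoint), `person_years` (exposure in the index year
#'   by age), `prevalence` (ever-had-AMI proportion among the living, by
#'   age), `first_events` (true first-ever AMI events in the index year by
#'   age, regardless of the registry window), and `incidence_true` (the
#'   scenario's index-year hazard schedule).
#' @export
simulate_event_histories <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(seed)
  sc <- scenario
  ages <- sc$ages
  A <- length(ages)
  idx <- sc$index_year
  T_end <- idx + 1
  H <- sc$trend_horizon

  n_a <- round(sc$cohort_n)
  N <- sum(n_a)
  birth_year <- rep(idx - ages, n_a)
  tb <- birth_year + runif(N)

  state <- integer(N)              # 0 healthy, 1 diseased, 2 dead
  t_death <- rep(Inf, N)
  death_underlying <- logical(N)
  death_anywhere <- logical(N)
  first_ami <- rep(NA_real_, N)

  adm_pid <- integer(0); adm_t <- numeric(0); adm_age <- integer(0)

  for (j in seq_len(A)) {
    a <- ages[j]
    live <- which(state != 2L & (tb + a) < T_end)
    if (!length(live)) next
    t0 <- tb[live] + a
    len <- pmin(1, T_end - t0)
    fac_i <- .trend_factor(t0 + len / 2, sc$incidence_trend[j], H, idx)
    fac_f <- .trend_factor(t0 + len / 2, sc$case_fatality_trend, H, idx)

    healthy <- state[live] == 0L
    dis <- !healthy

    r_ami <- numeric(length(live))
    r_die <- numeric(length(live))
    r_ami[healthy] <- sc$incidence[j] * fac_i[healthy]
    r_die[healthy] <- sc$other_mortality[j]
    r_ami[dis] <- sc$recurrence_mult * sc$incidence[j] * fac_i[dis]
    r_die[dis] <- sc$excess_mult * sc$other_mortality[j]

    t_ami <- ifelse(r_ami > 0, rexp(length(live), pmax(r_ami, 1e-300)), Inf)
    t_die <- ifelse(r_die > 0, rexp(length(live), pmax(r_die, 1e-300)), Inf)
    hit <- pmin(t_ami, t_die) < len

    # other-cause (or survivor) deaths
    dd <- hit & t_die <= t_ami
    if (any(dd)) {
      w <- live[dd]
      t_death[w] <- t0[dd] + t_die[dd]
      state[w] <- 2L
      death_anywhere[w] <- dis[dd]   # survivors die "with" AMI on the cert
    }

    # AMI events (first or recurrent)
    ev <- hit & t_ami < t_die
    if (any(ev)) {
      w <- live[ev]
      t_ev <- t0[ev] + t_ami[ev]
      newly <- healthy[ev]
      first_ami[w[newly]] <- t_ev[newly]
      cf <- pmin(sc$case_fatality_30d[j] * fac_f[ev], 0.97)
      fatal <- runif(length(w)) < cf
      if (any(fatal)) {
        wf <- w[fatal]
        t_death[wf] <- t_ev[fatal] + runif(length(wf), 0, 30) / 365.25
        state[wf] <- 2L
        death_underlying[wf] <- TRUE
        death_anywhere[wf] <- TRUE
      }
      if (any(!fatal)) {
        ws <- w[!fatal]
        adm_pid <- c(adm_pid, ws)
        adm_t <- c(adm_t, t_ev[!fatal])
        adm_age <- c(adm_age, rep(a, length(ws)))
        state[ws] <- 1L
      }
    }
  }

  reg_start <- sc$registry_start_year
  keep_adm <- adm_t >= reg_start & adm_t < T_end
  n_adm <- sum(keep_adm)
  admissions <- data.frame(
    person_id = adm_pid[keep_adm],
    admission_date = .frac_to_date(adm_t[keep_adm]),
    emergency = rep(TRUE, n_adm),
    primary_diagnosis_ami = rep(TRUE, n_adm),
    length_of_stay = 2 + rpois(n_adm, 1.5),
    discharged_alive = rep(TRUE, n_adm),
    age_at_admission = adm_age[keep_adm])

  died_obs <- which(t_death >= reg_start & t_death < T_end)
  deaths <- data.frame(
    person_id = died_obs,
    death_date = .frac_to_date(t_death[died_obs]),
    underlying_cause_ami = death_underlying[died_obs],
    ami_anywhere = death_anywhere[died_obs],
    age_at_death = floor(t_death[died_obs] - tb[died_obs]))

  # truth tables -----------------------------------------------------------
  mid <- idx + 0.5
  alive_mid <- t_death > mid & tb < mid
  age_mid <- floor(mid - tb)
  pop <- tapply(alive_mid, age_mid, sum)
  population <- data.frame(age = as.integer(names(pop)),
                           pop = as.numeric(pop))
  population <- population[population$pop > 0 & population$age >= 0, ]

  entry <- pmax(tb, idx)
  exit <- pmin(t_death, T_end)
  py <- pmax(exit - entry, 0)
  age_py <- floor(pmax((entry + exit) / 2, entry) - tb)
  py_tab <- tapply(py, age_py, sum)
  person_years <- data.frame(age = as.integer(names(py_tab)),
                             py = as.numeric(py_tab))
  person_years <- person_years[person_years$py > 0 & person_years$age >= 0, ]

  ever <- alive_mid & !is.na(first_ami) & first_ami < mid
  prev_tab <- tapply(ever, age_mid, sum)
  prevalence <- data.frame(age = as.integer(names(prev_tab)),
                           p = as.numeric(prev_tab) / as.numeric(pop))
  prevalence <- prevalence[!is.na(prevalence$p) & prevalence$age >= 0, ]

  fe <- !is.na(first_ami) & first_ami >= idx & first_ami < T_end
  age_fe <- floor(first_ami - tb)
  fe_tab <- tapply(fe, age_fe, sum, default = 0)
  first_events <- data.frame(age = as.integer(names(fe_tab)),
                             events = as.numeric(fe_tab))
  first_events <- first_events[!is.na(first_events$events) &
                                 first_events$events > 0, ]

  list(admissions = admissions, deaths = deaths,
       truth = list(population = population, person_years = person_years,
                    prevalence = prevalence, first_events = first_events,
                    incidence_true = data.frame(age = ages,
                                                i = sc$incidence)),
       scenario = sc)
}

#' Emulate a health-survey prevalence table
#'
#' Samples a survey of `n_total` respondents allocated to age bands in
#' proportion to the population, draws each band's number of ever-had-AMI
#' reports from a binomial with the band's population-weighted true
#' prevalence, and reports the band rate with its binomial standard error
#' `sqrt(p_hat (1 - p_hat) / n_band)`. With `exact = TRUE` the band rates
#' equal the true band prevalences (no sampling noise) while the standard
#' errors still reflect the allocated sample sizes.
#'
#' @param prevalence `data.frame` with columns `age`, `p`: true prevalence
#'   by single year of age (e.g. `truth$prevalence` from
#'   [simulate_event_histories()]).
#' @param population `data.frame` with columns `age`, `pop`.
#' @param n_total total survey sample size.
#' @param bands optional band scheme (`age_low`, `age_high`); by default
#'   ages 16-24 then 10-year bands to 85+.
#' @param underreport multiplicative self-report factor (1 = none).
#' @param exact suppress sampling noise (see above).
#' @return a [grouped_rate_table()]; bands allocated no respondents are
#'   dropped with a warning.
#' @export
emulate_health_survey <- function(prevalence, population, n_total = 8610,
                                  bands = NULL, underreport = 1,
                                  exact = FALSE) {
  if (is.null(bands)) {
    lows <- c(16, seq(25, 85, 10))
    bands <- data.frame(age_low = lows,
                        age_high = c(lows[-1] - 1, NA))
  }
  d <- merge(population, prevalence, by = "age")
  hi <- ifelse(is.na(bands$age_high), Inf, bands$age_high)
  nb <- nrow(bands)
  p_true <- pop_b <- numeric(nb)
  for (g in seq_len(nb)) {
    inb <- d$age >= bands$age_low[g] & d$age <= hi[g]
    pop_b[g] <- sum(d$pop[inb])
    p_true[g] <- if (pop_b[g] > 0)
      sum(d$pop[inb] * d$p[inb]) / pop_b[g] else NA_real_
  }
  n_b <- round(n_total * pop_b / sum(pop_b))
  keep <- n_b > 0 & !is.na(p_true)
  if (any(!keep))
    warning(sprintf("%d band(s) with no survey sample dropped", sum(!keep)))
  p_eff <- pmin(p_true * underreport, 1)
  if (exact) {
    p_hat <- p_eff
  } else {
    p_hat <- rbinom(nb, n_b, pmin(pmax(p_eff, 0), 1)) / pmax(n_b, 1)
  }
  se <- sqrt(p_hat * (1 - p_hat) / pmax(n_b, 1))
  grouped_rate_table(bands$age_low[keep], bands$age_high[keep],
                     p_hat[keep], se[keep],
                     count = round(p_hat[keep] * n_b[keep]),
                     denominator = n_b[keep])
}

#' Emulate vital-statistics mortality tables
#'
#' Tabulates index-year deaths into 5-year age bands over person-years at
#' risk, producing the two mortality inputs of the modelling pipeline: the
#' AMI-anywhere-on-certificate rate (disease-specific mortality) and the
#' all-cause rate.
#'
#' @param deaths death record table (see [simulate_event_histories()]).
#' @param person_years `data.frame` with columns `age`, `py`.
#' @param index_year deaths in this calendar year are tabulated.
#' @param bands optional band scheme; default 5-year bands 0-4 ... 80-84,
#'   85+.
#' @return list of two [grouped_rate_table()]s: `ami` and `all_cause`.
#' @export
emulate_vital_statistics <- function(deaths, person_years, index_year,
                                     bands = NULL) {
  if (is.null(bands)) {
    lows <- seq(0, 85, 5)
    bands <- data.frame(age_low = lows, age_high = c(lows[-1] - 1, NA))
  }
  dy <- deaths[format(as.Date(deaths$death_date), "%Y") ==
                 as.character(index_year), , drop = FALSE]
  hi <- ifelse(is.na(bands$age_high), Inf, bands$age_high)
  nb <- nrow(bands)
  n_ami <- n_all <- py_b <- numeric(nb)
  for (g in seq_len(nb)) {
    inb <- dy$age_at_death >= bands$age_low[g] & dy$age_at_death <= hi[g]
    n_ami[g] <- sum(dy$ami_anywhere[inb])
    n_all[g] <- sum(inb)
    inp <- person_years$age >= bands$age_low[g] & person_years$age <= hi[g]
    py_b[g] <- sum(person_years$py[inp])
  }
  keep <- py_b > 0
  mk <- function(n) grouped_rate_table(
    bands$age_low[keep], bands$age_high[keep],
    rate = n[keep] / py_b[keep],
    se = sqrt(n[keep]) / py_b[keep],
    count = n[keep], denominator = py_b[keep])
  list(ami = mk(n_ami), all_cause = mk(n_all))
}

#' Deterministic model-consistent inputs for a scenario
#'
#' Integrates the scenario's exact transition structure (fatal first
#' events, survivor excess mortality, calendar trend scaling per birth
#' cohort) without sampling noise, returning the index-year cross-section
#' on the single-year grid: the quantities an infinitely large survey and
#' registry would measure. `csmr_excess` is the disease-attributable
#' mortality rate (fatal first events plus the excess over other-cause
#' mortality among survivors) — the ideal model input; `csmr_anywhere`
#' additionally counts the baseline deaths of survivors, as an
#' AMI-anywhere-on-the-certificate tabulation does.
#'
#' @param scenario a [simulation_scenario()].
#' @return `data.frame` with columns `age`, `p` (prevalence of ever-had
#'   among the living), `csmr_excess`, `csmr_anywhere`, `all_cause`,
#'   `incidence_true` (index-year first-AMI hazard) and
#'   `first_event_rate` (true first events per 100,000 population).
#' @export
analytic_inputs <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  ages <- sc$ages
  A <- length(ages)
  H <- sc$trend_horizon
  p <- numeric(A)
  for (a_idx in seq_len(A)) {
    S <- 1; C <- 0
    for (j in seq_len(a_idx - 1L)) {
      k <- ages[a_idx] - ages[j]
      fi <- (1 + sc$incidence_trend[j])^(-min(k, H))
      ff <- (1 + sc$case_fatality_trend)^(-min(k, H))
      ih <- sc$incidence[j] * fi
      cf <- min(sc$case_fatality_30d[j] * ff, 0.97)
      aS <- ih + sc$other_mortality[j]
      cC <- sc$excess_mult * sc$other_mortality[j]
      b <- (1 - cf) * ih
      eS <- exp(-aS); eC <- exp(-cC)
      C <- C * eC + b * S *
        (if (abs(cC - aS) > 1e-12) (eS - eC) / (cC - aS) else eS)
      S <- S * eS
    }
    p[a_idx] <- C / (S + C)
  }
  i0 <- sc$incidence
  cf0 <- pmin(sc$case_fatality_30d, 0.97)
  m <- sc$other_mortality
  mult <- sc$excess_mult
  # a disease-attributable death rate is only representable as f * p where
  # prevalence is positive; at p = 0 ages it is projected to 0
  cs_x <- ifelse(p > 0, cf0 * i0 * (1 - p) + (mult - 1) * m * p, 0)
  cs_a <- ifelse(p > 0, cf0 * i0 * (1 - p) + mult * m * p, 0)
  data.frame(age = ages, p = p,
             csmr_excess = cs_x,
             csmr_anywhere = cs_a,
             all_cause = m + cs_x,
             incidence_true = i0,
             first_event_rate = 1e5 * i0 * (1 - p))
}
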