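#' Classify first AMI events from linked admission and death records
#'
#' Applies the registry case definition to person-linked hospital admission
#' and death-certificate records. A qualifying admission is an emergency
#' admission with a primary diagnosis of AMI and a length of stay of more
#' than 1 day for someone discharged alive. A qualifying death has AMI
#' coded as the underlying cause. Qualifying records of the same person
#' within 30 days (inclusive) after an existing event are absorbed into it;
#' any death (whatever the cause) within 30 days after an event that
#' stems from an admission marks that event fatal, on the assumption that
#' it relates to the same event. `first_event` is `TRUE` for a person's
#' earliest event on or after `registry_start_date`: the registry cannot
#' see earlier history, so a recurrence whose first event predates the
#' window is (mis)classified as a first event — the left-truncation bias
#' inherent to a fixed lookback.
#'
#' @param admissions `data.frame` with columns `person_id`,
#'   `admission_date` (`Date` or ISO-8601 text), `emergency`,
#'   `primary_diagnosis_ami`, `length_of_stay` (days), `discharged_alive`,
#'   and `age_at_admission` (completed years; the analogue of
#'   date-of-birth linkage, needed to band events by age).
#' @param deaths `data.frame` with columns `person_id`, `death_date`,
#'   `underlying_cause_ami`, `ami_anywhere`, `age_at_death`.
#' @param registry_start_date start of the registry window (`Date` or
#'   ISO-8601 text); records before it are ignored, and "first" means
#'   first since this date.
#' @return `data.frame` of events, one row per event: `person_id`,
#'   `event_date`, `age_at_event` (completed years), `fatal`,
#'   `first_event`, `from_admission`. Deaths of a person dated before one
#'   of their admissions indicate broken linkage; such death records are
#'   dropped with a warning and listed in the `"rejected"` attribute.
#'   The result is invariant to input row order.
#' @export
classify_events <- function(admissions, deaths, registry_start_date) {
  start <- as.Date(registry_start_date)
  adm <- data.table::as.data.table(admissions)
  dth <- data.table::as.data.table(deaths)
  if (nrow(adm)) adm[, admission_date := as.Date(admission_date)]
  if (nrow(dth)) dth[, death_date := as.Date(death_date)]
  if (nrow(dth) && anyDuplicated(dth$person_id))
    stop("more than one death record for the same person")

  rejected <- NULL
  if (nrow(adm) && nrow(dth)) {
    last_adm <- adm[, .(last_admission = max(admission_date)), by = person_id]
    chk <- merge(dth, last_adm, by = "person_id")
    bad <- chk[death_date < last_admission, person_id]
    if (length(bad)) {
      warning(sprintf(
        "%d death record(s) predate an admission for the same person; rejected",
        length(bad)))
      rejected <- dth[person_id %in% bad]
      dth <- dth[!person_id %in% bad]
    }
  }

  qa <- adm[emergency & primary_diagnosis_ami & discharged_alive &
              length_of_stay > 1 & admission_date >= start,
            .(person_id, date = admission_date, age = age_at_admission,
              is_death = FALSE)]
  qd <- dth[underlying_cause_ami & death_date >= start,
            .(person_id, date = death_date, age = age_at_death,
              is_death = TRUE)]
  rec <- rbind(qa, qd)
  if (!nrow(rec)) {
    out <- data.frame(person_id = character(), event_date = as.Date(character()),
                      age_at_event = numeric(), fatal = logical(),
                      first_event = logical(), from_admission = logical())
    attr(out, "rejected") <- rejected
    return(out)
  }
  # deterministic order: by person, date, admissions before deaths on ties
  data.table::setorder(rec, person_id, date, is_death)

  # greedy per-person absorption: a record within 30 days after the current
  # event belongs to it; a later record opens a new event
  rec[, gap := c(Inf, diff(as.numeric(date))), by = person_id]
  assign_events <- function(gaps) {
    ev <- integer(length(gaps))
    cur <- 0L
    anchor_elapsed <- Inf
    for (idx in seq_along(gaps)) {
      anchor_elapsed <- anchor_elapsed + gaps[idx]
      if (anchor_elapsed > 30) {
        cur <- cur + 1L
        anchor_elapsed <- 0
      }
      ev[idx] <- cur
    }
    ev
  }
  rec[, event_no := assign_events(gap), by = person_id]
  ev <- rec[, .(event_date = date[1], age_at_event = age[1],
                fatal = any(is_death), from_admission = !is_death[1]),
            by = .(person_id, event_no)]

  # any death within 30 days after an admission-based event marks it fatal
  if (nrow(dth)) {
    dd <- dth[, .(person_id, death_date)]
    ev <- merge(ev, dd, by = "person_id", all.x = TRUE)
    ev[, fatal := fatal | (!is.na(death_date) & from_admission &
                             death_date >= event_date &
                             death_date - event_date <= 30)]
    ev[, death_date := NULL]
  }
  data.table::setorder(ev, person_id, event_date)
  ev[, first_event := seq_len(.N) == 1L, by = person_id]
  out <- as.data.frame(ev[, .(person_id, event_date, age_at_event, fatal,
                              first_event, from_admission)])
  attr(out, "rejected") <- if (is.null(rejected)) NULL
                           else as.data.frame(rejected)
  out
}

#' Age-banded incidence rates with confidence intervals
#'
#' Counts first events in the target calendar year per age band and
#' converts them to rates per 100,000 person-years with 95% confidence
#' intervals from the sampling variance of the count. The default interval
#' treats the count as Poisson and uses the normal approximation
#' `rate * (1 +/- z / sqrt(n))`, truncated below at 0; `ci = "exact"`
#' uses the exact Poisson (chi-square) limits instead. Bands with no
#' events report rate 0 with an upper bound from the "rule of three"
#' (3 expected events).
#'
#' @param events event table from [classify_events()]; only rows with
#'   `first_event = TRUE` whose `event_date` falls in `year` are counted.
#' @param population `data.frame` with single-year columns `age` and `pop`
#'   (person-years at risk in `year`).
#' @param year target calendar year.
#' @param bands band scheme `data.frame` with columns `age_low`,
#'   `age_high` (`NA` = open-ended top band); defaults to [ami_age_bands()].
#' @param level confidence level.
#' @param ci `"normal"` or `"exact"`.
#' @return a [grouped_rate_table()] with `rate` per 100,000, `se`, `count`,
#'   `denominator`, plus columns `lo` and `hi` (the interval, same scale).
#' @export
incidence_rates <- function(events, population, year,
                            bands = ami_age_bands(), level = 0.95,
                            ci = c("normal", "exact")) {
  ci <- match.arg(ci)
  z <- stats::qnorm(1 - (1 - level) / 2)
  first <- events[events$first_event &
                    format(as.Date(events$event_date), "%Y") == as.character(year), ,
                  drop = FALSE]
  hi_edge <- ifelse(is.na(bands$age_high), Inf, bands$age_high)
  n_g <- pop_g <- numeric(nrow(bands))
  for (g in seq_len(nrow(bands))) {
    in_band_pop <- population$age >= bands$age_low[g] &
      population$age <= hi_edge[g]
    if (!any(in_band_pop))
      stop(sprintf("population missing for band %g-%s", bands$age_low[g],
                   ifelse(is.na(bands$age_high[g]), "plus",
                          bands$age_high[g])))
    pop_g[g] <- sum(population$pop[in_band_pop])
    n_g[g] <- sum(first$age_at_event >= bands$age_low[g] &
                    first$age_at_event <= hi_edge[g])
  }
  if (any(pop_g <= 0)) stop("non-positive population in a band")
  unbanded <- sum(first$age_at_event < min(bands$age_low)) +
    sum(first$age_at_event > max(hi_edge))
  if (unbanded > 0)
    stop(sprintf("%d first event(s) fall outside the band scheme", unbanded))
  rate <- 1e5 * n_g / pop_g
  se <- 1e5 * sqrt(n_g) / pop_g
  if (ci == "normal") {
    lo <- pmax(rate * (1 - z / sqrt(pmax(n_g, 1))), 0)
    hi <- rate * (1 + z / sqrt(pmax(n_g, 1)))
  } else {
    a <- (1 - level) / 2
    lo <- 1e5 * ifelse(n_g == 0, 0, stats::qchisq(a, 2 * n_g) / 2) / pop_g
    hi <- 1e5 * stats::qchisq(1 - a, 2 * n_g + 2) / 2 / pop_g
  }
  zero <- n_g == 0
  lo[zero] <- 0
  hi[zero] <- 1e5 * 3 / pop_g[zero]
  out <- grouped_rate_table(bands$age_low, bands$age_high, rate, se,
                            count = n_g, denominator = pop_g / 1e5)
  out$lo <- lo[order(bands$age_low)]
  out$hi <- hi[order(bands$age_low)]
  out
}
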