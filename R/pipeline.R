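#' Run the full synthetic external-validity study
#'
#' Executes the whole design end to end for one or more scenarios
#' (typically one per sex): simulate person-level histories; estimate
#' measured first-AMI incidence from the registry records; emulate the
#' health-survey prevalence table and vital-statistics mortality tables;
#' smooth them to single-year inputs (sigmoid prevalence, log-spline
#' mortality); back-calculate incidence without and, optionally, with the
#' secular-trend adjustment; propagate survey uncertainty by parametric
#' bootstrap; and assemble the banded modelled-versus-measured comparison
#' report.
#'
#' The modelled hazard is reported per 100,000 and compared directly with
#' the registry rate per 100,000 population, as an external-validity
#' comparison does. Band intervals for the modelled rates are obtained by
#' aggregating each bootstrap replicate's schedule to bands and taking
#' percentile bounds of the banded values.
#'
#' @param scenarios a [simulation_scenario()] or list of them.
#' @param seed master RNG seed; per-scenario streams are derived from it.
#' @param B bootstrap replicates (0 skips the uncertainty analysis).
#' @param trend a [trend_spec()], preset name, or `NULL` to skip the
#'   trended variant.
#' @param survey_n total health-survey sample size split across scenarios
#'   in proportion to nothing fancier than equal shares.
#' @return list of class `"validation_study"` with one element per
#'   scenario (`report`, `measured`, `fit`, `fit_trended`, `bootstrap`,
#'   `inputs`, `sim`) and a combined `report` data.frame at the top level.
#' @export
run_validation_study <- function(scenarios, seed = 1, B = 200,
                                 trend = trend_preset("chd_longrun"),
                                 survey_n = 8610) {
  if (inherits(scenarios, "simulation_scenario"))
    scenarios <- list(scenarios)
  if (is.character(trend)) trend <- trend_preset(trend)
  n_sc <- length(scenarios)
  per <- lapply(seq_len(n_sc), function(s) {
    sc <- scenarios[[s]]
    seed_s <- seed + 1000L * s
    sim <- simulate_event_histories(sc, seed = seed_s)
    idx <- sc$index_year

    ev <- classify_events(sim$admissions, sim$deaths,
                          as.Date(sprintf("%d-01-01", sc$registry_start_year)))
    measured <- incidence_rates(ev, sim$truth$population, idx)

    set.seed(seed_s + 1L)
    survey <- emulate_health_survey(sim$truth$prevalence,
                                    sim$truth$population,
                                    n_total = round(survey_n / n_sc),
                                    underreport = sc$survey_underreport)
    vital <- emulate_vital_statistics(sim$deaths, sim$truth$person_years,
                                      idx)

    age <- sc$ages
    prev_fit <- fit_sigmoid_prevalence(survey, age)
    p_curve <- pmin(prev_fit$prevalence, 1 - 1e-9)
    csmr <- expand_mortality(vital$ami, age)
    all_cause <- pmax(expand_mortality(vital$all_cause, age), csmr)

    fit <- solve_steady_state(p_curve, csmr, all_cause, age = age)
    fit_tr <- if (!is.null(trend))
      solve_with_trend(p_curve, csmr, all_cause, trend, age = age)

    pop_grid <- merge(data.frame(age = age), sim$truth$population,
                      by = "age", all.x = TRUE)
    pop_grid$pop[is.na(pop_grid$pop) | pop_grid$pop <= 0] <- 1e-9
    wts <- pop_grid$pop[order(pop_grid$age)]

    mod_bands <- aggregate_to_bands(1e5 * fit$incidence, wts, age)
    boot <- NULL
    if (B >= 2) {
      boot <- bootstrap_incidence(survey, csmr, all_cause, age, B = B,
                                  seed = seed_s + 2L,
                                  keep_replicates = TRUE)
      if (nrow(boot$replicates) >= 2) {
        banded_reps <- apply(boot$replicates, 1, function(ii)
          aggregate_to_bands(1e5 * ii, wts, age)$rate)
        mod_bands$lo <- apply(banded_reps, 1, quantile, probs = 0.025,
                              type = 1, names = FALSE)
        mod_bands$hi <- apply(banded_reps, 1, quantile, probs = 0.975,
                              type = 1, names = FALSE)
      }
    }
    tr_bands <- if (!is.null(fit_tr))
      aggregate_to_bands(1e5 * fit_tr$incidence, wts, age)

    report <- build_report(measured, mod_bands, tr_bands, sex = sc$sex)
    list(report = report, measured = measured, fit = fit,
         fit_trended = fit_tr, bootstrap = boot,
         inputs = list(survey = survey, vital = vital,
                       prevalence_curve = p_curve, csmr = csmr,
                       all_cause = all_cause, prevalence_fit = prev_fit),
         sim = sim)
  })
  names(per) <- vapply(scenarios, function(s) s$sex, character(1))
  combined <- do.call(rbind, lapply(per, function(x) as.data.frame(x$report)))
  rownames(combined) <- NULL
  structure(c(per, list(report = combined)), class = "validation_study")
}

#' @export
print.validation_study <- function(x, ...) {
  cat("<validation_study>\n")
  nm <- setdiff(names(x), "report")
  for (s in nm) {
    cat(sprintf("\n== %s ==\n", s))
    print(x[[s]]$report)
  }
  invisible(x)
}
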