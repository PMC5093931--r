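#' Parametric bootstrap uncertainty for back-calculated incidence
#'
#' Propagates survey sampling uncertainty through the preprocessing and the
#' consistency solver. Each replicate draws new band prevalences from
#' `Normal(rate, se)` truncated at 0 and capped at 1 (redrawn up to 100
#' times, then clipped), refits the sigmoid prevalence curve and re-runs
#' the solver; the interval at each age is the percentile interval (plain
#' order statistics, no smoothing) of the replicate incidence values.
#' Mortality and remission inputs are never perturbed, so they are
#' identical in every replicate.
#'
#' @param prevalence_table a [grouped_rate_table()] of survey prevalences
#'   with standard errors (`se > 0` for the bands that should vary).
#' @param csmr,all_cause_mortality single-year mortality inputs passed
#'   unchanged to the solver.
#' @param age integer age grid of the single-year inputs.
#' @param B number of bootstrap replicates (at least 2). The default
#'   resolves a 95% percentile interval comfortably; tests and exploratory
#'   runs can lower it.
#' @param seed RNG seed; the same seed and configuration give bit-identical
#'   intervals.
#' @param interval_level coverage of the percentile interval, in (0, 1).
#' @param trend optional [trend_spec()]; when supplied each replicate runs
#'   [solve_with_trend()] instead of [solve_steady_state()]. Off by
#'   default: the uncertainty analysis mirrors the untrended configuration.
#' @param remission remission rate, default 0.
#' @param keep_replicates if `TRUE`, the `B x n_ages` matrix of replicate
#'   incidence schedules is returned (needed to band-aggregate intervals).
#' @return list with `age`, `incidence` (point estimate from the
#'   unperturbed inputs), `lo`, `hi` (percentile bounds per age), `fit`
#'   (the point-estimate `idm_fit`), `n_failed` (replicates that did not
#'   converge, excluded from the interval), `flagged` (`TRUE` when more
#'   than 20% of replicates failed), and optionally `replicates`.
#' @export
bootstrap_incidence <- function(prevalence_table, csmr, all_cause_mortality,
                                age, B = 1000, seed = 1,
                                interval_level = 0.95, trend = NULL,
                                remission = 0, keep_replicates = FALSE) {
  stopifnot(inherits(prevalence_table, "grouped_rate_table"))
  if (B < 2) stop("need at least 2 bootstrap replicates")
  if (interval_level <= 0 || interval_level >= 1)
    stop("interval_level must be in (0, 1)")

  solve_one <- function(p_curve) {
    if (is.null(trend))
      solve_steady_state(p_curve, csmr, all_cause_mortality,
                         remission = remission, age = age)
    else
      solve_with_trend(p_curve, csmr, all_cause_mortality, trend,
                       remission = remission, age = age)
  }

  point_fit_prev <- fit_sigmoid_prevalence(prevalence_table, age)
  point <- solve_one(pmin(point_fit_prev$prevalence, 1 - 1e-9))
  n <- length(age)

  set.seed(seed)
  draws <- matrix(NA_real_, nrow = B, ncol = n)
  n_failed <- 0L
  rate0 <- prevalence_table$rate
  se0 <- prevalence_table$se
  warm <- as.list(point_fit_prev$par)
  for (b in seq_len(B)) {
    p_band <- rate0
    vary <- se0 > 0
    if (any(vary)) {
      x <- rnorm(sum(vary), rate0[vary], se0[vary])
      for (tries in seq_len(100)) {
        bad <- x < 0 | x > 1
        if (!any(bad)) break
        x[bad] <- rnorm(sum(bad), rate0[vary][bad], se0[vary][bad])
      }
      p_band[vary] <- pmin(pmax(x, 0), 1)
    }
    tab_b <- prevalence_table
    tab_b$rate <- p_band
    fit_b <- tryCatch({
      prev_b <- fit_sigmoid_prevalence(tab_b, age, start = warm)
      solve_one(pmin(prev_b$prevalence, 1 - 1e-9))
    }, error = function(e) NULL)
    if (is.null(fit_b) || !fit_b$converged) {
      n_failed <- n_failed + 1L
    } else {
      draws[b, ] <- fit_b$incidence
    }
  }
  ok <- stats::complete.cases(draws)
  alpha <- (1 - interval_level) / 2
  if (sum(ok) >= 2) {
    lo <- apply(draws[ok, , drop = FALSE], 2, quantile,
                probs = alpha, type = 1, names = FALSE)
    hi <- apply(draws[ok, , drop = FALSE], 2, quantile,
                probs = 1 - alpha, type = 1, names = FALSE)
  } else {
    lo <- hi <- rep(NA_real_, n)
  }
  out <- list(age = age, incidence = point$incidence, lo = lo, hi = hi,
              fit = point, n_failed = n_failed,
              flagged = n_failed > 0.2 * B,
              interval_level = interval_level, B = B, seed = seed)
  if (keep_replicates) out$replicates <- draws[ok, , drop = FALSE]
  out
}
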