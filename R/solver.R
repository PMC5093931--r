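#' Secular-trend specification for the consistency solver
#'
#' Describes proportional annual change in incidence and case fatality over
#' a fixed number of years of history before the index year of the
#' cross-sectional inputs. A cohort aged `a` at the index year is assumed to
#' have experienced, at age `a'`, the index-year hazard scaled by
#' `(1 + tau)^(-min(k, horizon))` with `k = a - a'` years before the index
#' year; beyond the horizon hazards are held at the `(1 + tau)^(-horizon)`
#' level. Every age group changes at the same annual rate (no age-stratified
#' trends).
#'
#' @param incidence_trend proportional annual change in incidence,
#'   e.g. `-0.04` for a 4% annual decline; must exceed -1.
#' @param case_fatality_trend proportional annual change in case fatality.
#' @param horizon integer years of history the trend applies over.
#' @param index_year optional calendar year of the cross-sectional inputs
#'   (bookkeeping only).
#' @return object of class `"trend_spec"`.
#' @seealso [trend_preset()] for the configurations shipped with the
#'   package.
#' @export
trend_spec <- function(incidence_trend, case_fatality_trend, horizon = 28,
                       index_year = NULL) {
  if (incidence_trend <= -1 || case_fatality_trend <= -1)
    stop("annual trends must be greater than -1")
  if (horizon < 0 || horizon != round(horizon))
    stop("horizon must be a non-negative integer")
  structure(list(incidence_trend = incidence_trend,
                 case_fatality_trend = case_fatality_trend,
                 horizon = as.integer(horizon), index_year = index_year),
            class = "trend_spec")
}

#' Named trend configurations
#'
#' `"none"` turns the trend layer off. `"chd_longrun"` is the long-run
#' coronary-heart-disease decline used for the main trended analysis: -4%
#' per year in incidence and -1% per year in case fatality over the
#' previous 28 years. `"sensitivity"` is the larger recent-decade decline
#' used as a sensitivity analysis: -5% incidence and -4% case fatality
#' (applied over the same 28-year history).
#'
#' @param name preset name.
#' @return a [trend_spec()].
#' @export
trend_preset <- function(name = c("none", "chd_longrun", "sensitivity")) {
  switch(match.arg(name),
         none = trend_spec(0, 0, 28),
         chd_longrun = trend_spec(-0.04, -0.01, 28),
         sensitivity = trend_spec(-0.05, -0.04, 28))
}

#' @export
print.trend_spec <- function(x, ...) {
  cat(sprintf(
    "<trend_spec> incidence %+.1f%%/yr, case fatality %+.1f%%/yr over %d years\n",
    100 * x$incidence_trend, 100 * x$case_fatality_trend, x$horizon))
  invisible(x)
}

# Find i >= 0 such that stepping (S, C) one year with rates (i, r, f, m)
# reaches prevalence p_target. The objective is monotone increasing in i;
# a safeguarded Newton iteration (bisection fallback inside a bracket) is
# started from the zero-remission closed-form estimate.
.invert_interval <- function(S, C, r, f, m, p_target) {
  pnext <- function(i) {
    st <- .step_state(S, C, i, r, f, m)
    st[2] / (st[1] + st[2])
  }
  g0 <- pnext(0) - p_target
  if (g0 >= -1e-15) return(list(i = 0, floored = g0 > 1e-12))
  p_cur <- C / (S + C)
  pb <- (p_cur + p_target) / 2
  x <- max((p_target - p_cur) / max(1 - pb, 1e-6) + f * pb, 1e-10)
  lo <- 0
  hi <- max(4 * x, 1e-6)
  ghi <- pnext(hi) - p_target
  while (ghi < 0 && hi < 50) {
    hi <- hi * 4
    ghi <- pnext(hi) - p_target
  }
  if (ghi < 0) return(list(i = hi, floored = TRUE))
  if (x >= hi) x <- hi / 2
  gx <- pnext(x) - p_target
  for (it in 1:100) {
    if (abs(gx) < 1e-15) break
    if (gx > 0) hi <- x else lo <- x
    h <- max(1e-9, 1e-6 * x)
    d <- (pnext(x + h) - (gx + p_target)) / h
    xn <- if (is.finite(d) && d > 0) x - gx / d else (lo + hi) / 2
    if (!(xn > lo && xn < hi)) xn <- (lo + hi) / 2
    if (abs(xn - x) <= 1e-15 * (1 + x) || hi - lo < 1e-16 * (1 + hi)) {
      x <- xn
      break
    }
    x <- xn
    gx <- pnext(x) - p_target
  }
  list(i = x, floored = FALSE)
}

# shared validation for the two solver entry points
.check_solver_inputs <- function(p, csmr, all_cause, r, age) {
  n <- length(p)
  if (length(csmr) != n || length(all_cause) != n || length(age) != n)
    stop("prevalence, csmr, all-cause mortality and age must be the same length")
  if (any(p < 0 | p >= 1))
    stop(sprintf("prevalence must lie in [0, 1); offending age %d",
                 age[which(p < 0 | p >= 1)[1]]))
  if (any(csmr < 0))
    stop(sprintf("negative csmr at age %d", age[which(csmr < 0)[1]]))
  if (any(r < 0))
    stop(sprintf("negative remission at age %d", age[which(r < 0)[1]]))
  bad <- which(all_cause - csmr < -1e-12)
  if (length(bad))
    stop(sprintf(
      "all-cause mortality below disease-specific mortality at age %d",
      age[bad[1]]))
  bad <- which(csmr > 0 & p == 0)
  if (length(bad))
    stop(sprintf(
      "infeasible inputs: csmr > 0 where prevalence = 0 at age %d",
      age[bad[1]]))
  invisible(TRUE)
}

.new_idm_fit <- function(age, i_hat, f_hat, r, m, floored, traj, p_in, csmr_in,
                         p_tol, m_tol, trend = NULL) {
  n <- length(age)
  p_fit <- traj$p[seq_len(n)]
  res <- data.frame(age = age,
                    prevalence = p_fit - p_in,
                    csmr = f_hat * p_fit - csmr_in)
  converged <- max(abs(res$prevalence)) <= p_tol &&
    max(abs(res$csmr)) <= m_tol
  structure(list(age = age, incidence = i_hat, case_fatality = f_hat,
                 remission = r, other_mortality = m,
                 hazards = hazard_schedule(age, i_hat, r, f_hat, m),
                 trajectory = traj, residuals = res, floored = floored,
                 converged = converged, trend = trend),
            class = "idm_fit")
}

#' @export
print.idm_fit <- function(x, ...) {
  cat(sprintf("<idm_fit> ages %d-%d, %s, %s\n",
              min(x$age), max(x$age),
              if (is.null(x$trend) ||
                  (x$trend$incidence_trend == 0 &&
                   x$trend$case_fatality_trend == 0))
                "steady state" else "trend-adjusted",
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  max |prevalence residual| %.2e, max |csmr residual| %.2e\n",
              max(abs(x$residuals$prevalence)), max(abs(x$residuals$csmr))))
  if (any(x$floored))
    cat(sprintf("  incidence floored at 0 at %d age(s)\n", sum(x$floored)))
  invisible(x)
}

#' Back-calculate incidence and case fatality under the steady-state assumption
#'
#' The inverse of [integrate_cohort()]: given single-year prevalence of
#' ever-had disease, remission (zero for an ever-had measure),
#' disease-specific population mortality `M(a)` and all-cause mortality,
#' find the incidence and case-fatality schedules that make the
#' illness-death model reproduce the inputs. Case fatality comes from the
#' identity `f(a) = M(a) / p(a)`; incidence is then solved age by age so
#' that the cohort stepped from age `a` with the fitted hazards lands
#' exactly on the input prevalence at age `a + 1`. The "steady state"
#' assumption is that one cross-section stands in for every cohort's
#' history, i.e. age-specific rates are static in calendar time.
#'
#' Where the input prevalence at `a + 1` is lower than even zero incidence
#' can produce, incidence is floored at 0 and the age flagged; hazards are
#' never negative.
#'
#' @param prevalence numeric vector of prevalence in `[0, 1)` per single
#'   year of age.
#' @param csmr disease-specific mortality rate per living person-year
#'   (population level), same length.
#' @param all_cause_mortality all-cause mortality rate per person-year;
#'   must be at least `csmr` everywhere (their difference is the
#'   other-cause hazard).
#' @param remission remission rate per person-year; defaults to 0.
#' @param age integer age grid; defaults to `0:(n-1)`.
#' @param p_tol,m_tol forward-consistency tolerances on the reproduced
#'   prevalence and csmr used for the convergence flag.
#' @return An object of class `"idm_fit"`: a list with `incidence`,
#'   `case_fatality`, `hazards` (a [hazard_schedule()]), `trajectory` (the
#'   re-integrated fit), `residuals` (fitted minus input prevalence and
#'   csmr), `floored`, and `converged`. The top-age incidence has no
#'   prevalence gradient to determine it and carries the previous age's
#'   value.
#' @examples
#' hz <- hazard_schedule(0:80, i = 0.008, f = 0.1, m = 0.01)
#' tr <- integrate_cohort(hz)
#' M <- csmr_from_trajectory(tr, hz)
#' fit <- solve_steady_state(tr$p[1:81], M$M, M$M + 0.01, age = 0:80)
#' max(abs(fit$incidence[1:80] - 0.008))  # recovers the truth
#' @export
solve_steady_state <- function(prevalence, csmr, all_cause_mortality,
                               remission = 0, age = NULL,
                               p_tol = 1e-4, m_tol = 1e-5) {
  n <- length(prevalence)
  if (is.null(age)) age <- seq_len(n) - 1L
  r <- rep_len(as.numeric(remission), n)
  .check_solver_inputs(prevalence, csmr, all_cause_mortality, r, age)
  m <- pmax(all_cause_mortality - csmr, 0)
  f_hat <- ifelse(prevalence > 0, csmr / prevalence, 0)
  i_hat <- numeric(n)
  floored <- logical(n)
  S <- 1 - prevalence[1]
  C <- prevalence[1]
  for (k in seq_len(n - 1L)) {
    sol <- .invert_interval(S, C, r[k], f_hat[k], m[k], prevalence[k + 1])
    i_hat[k] <- sol$i
    floored[k] <- sol$floored
    st <- .step_state(S, C, i_hat[k], r[k], f_hat[k], m[k])
    S <- st[1]
    C <- st[2]
  }
  i_hat[n] <- if (n > 1) i_hat[n - 1] else 0
  traj <- integrate_cohort(hazard_schedule(age, i_hat, r, f_hat, m),
                           init = c(1 - prevalence[1], prevalence[1]))
  .new_idm_fit(age, i_hat, f_hat, r, m, floored, traj,
               prevalence, csmr, p_tol, m_tol)
}

#' Back-calculate incidence with a secular-trend adjustment
#'
#' Like [solve_steady_state()], but each birth cohort's history is scaled
#' by the trend before matching the index-year cross-section: the cohort
#' observed at age `a` experienced, at age `a'`, incidence
#' `i_hat(a') * (1 + tau_i)^(-min(a - a', H))` and case fatality scaled the
#' same way with `tau_f`. The returned `incidence` is the index-year
#' schedule `i_hat(a)`. With declining rates (`tau < 0`), observed
#' prevalence was accumulated under historically higher incidence, so the
#' trend-adjusted index-year estimate is lower than the steady-state one.
#'
#' With both trends zero the result equals [solve_steady_state()] exactly.
#'
#' @inheritParams solve_steady_state
#' @param trend a [trend_spec()] or preset name accepted by
#'   [trend_preset()].
#' @return An `"idm_fit"` (see [solve_steady_state()]); its `trajectory` is
#'   the index-year cross-section, each cohort integrated under its own
#'   scaled history, and `residuals` compare that cross-section with the
#'   inputs.
#' @export
solve_with_trend <- function(prevalence, csmr, all_cause_mortality, trend,
                             remission = 0, age = NULL,
                             p_tol = 1e-4, m_tol = 1e-5) {
  if (is.character(trend)) trend <- trend_preset(trend)
  stopifnot(inherits(trend, "trend_spec"))
  n <- length(prevalence)
  if (is.null(age)) age <- seq_len(n) - 1L
  r <- rep_len(as.numeric(remission), n)
  .check_solver_inputs(prevalence, csmr, all_cause_mortality, r, age)
  m <- pmax(all_cause_mortality - csmr, 0)
  f_hat <- ifelse(prevalence > 0, csmr / prevalence, 0)
  tau_i <- trend$incidence_trend
  tau_f <- trend$case_fatality_trend
  H <- trend$horizon
  i_hat <- numeric(n)
  floored <- logical(n)
  # matching the cross-section at observed age a determines i_hat(a - 1):
  # every earlier hazard in that cohort's history is already solved
  for (a_idx in seq_len(n)[-1]) {
    S <- 1 - prevalence[1]
    C <- prevalence[1]
    for (j in seq_len(a_idx - 2L)) {
      k <- age[a_idx] - age[j]
      si <- (1 + tau_i)^(-min(k, H))
      sf <- (1 + tau_f)^(-min(k, H))
      st <- .step_state(S, C, i_hat[j] * si, r[j], f_hat[j] * sf, m[j])
      S <- st[1]
      C <- st[2]
    }
    j <- a_idx - 1L
    si <- (1 + tau_i)^(-min(age[a_idx] - age[j], H))
    sf <- (1 + tau_f)^(-min(age[a_idx] - age[j], H))
    sol <- .invert_interval(S, C, r[j], f_hat[j] * sf, m[j],
                            prevalence[a_idx])
    # the solved hazard is the historical (k = 1) one; report the
    # index-year level
    i_hat[j] <- sol$i / si
    floored[j] <- sol$floored
  }
  i_hat[n] <- if (n > 1) i_hat[n - 1] else 0
  Sx <- Cx <- numeric(n)
  Sx[1] <- 1 - prevalence[1]
  Cx[1] <- prevalence[1]
  # honest forward check: re-simulate every cohort with the final schedule
  p_fit <- numeric(n)
  p_fit[1] <- prevalence[1]
  for (a_idx in seq_len(n)[-1]) {
    S <- 1 - prevalence[1]
    C <- prevalence[1]
    for (j in seq_len(a_idx - 1L)) {
      k <- age[a_idx] - age[j]
      si <- (1 + tau_i)^(-min(k, H))
      sf <- (1 + tau_f)^(-min(k, H))
      st <- .step_state(S, C, i_hat[j] * si, r[j], f_hat[j] * sf, m[j])
      S <- st[1]
      C <- st[2]
    }
    Sx[a_idx] <- S
    Cx[a_idx] <- C
    p_fit[a_idx] <- C / (S + C)
  }
  alive <- Sx + Cx
  traj <- data.frame(age = age, S = Sx, C = Cx,
                     p = ifelse(alive > 0, Cx / alive, NA_real_),
                     D_disease = NA_real_, D_other = NA_real_)
  class(traj) <- c("state_trajectory", "data.frame")
  .new_idm_fit(age, i_hat, f_hat, r, m, floored, traj,
               prevalence, csmr, p_tol, m_tol, trend = trend)
}
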