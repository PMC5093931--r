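# Closed-form propagation of the illness-death cohort across one interval.
#
# Within an interval all four rates are constant, so the disease submodel
#   dS/dt = -i S + r C,   dC/dt = i S - (r + f) C
# is a 2x2 linear system with real eigenvalues (the discriminant
# (i - f)^2 + r^2 + 2 r (i + f) is non-negative), and other-cause mortality
# factors out multiplicatively as exp(-m t) because it acts equally on both
# living states. Death flows are integrated in closed form as well, so
# S + C + D_disease + D_other is conserved to machine precision.

# integral of exp(x t) over [0, dt]
.J <- function(x, dt) {
  if (abs(x * dt) < 1e-8) dt * (1 + x * dt / 2) else expm1(x * dt) / x
}

# integral of t exp(x t) over [0, dt]
.K <- function(x, dt) {
  if (abs(x * dt) < 1e-6) dt^2 / 2 + x * dt^3 / 3
  else (exp(x * dt) * (x * dt - 1) + 1) / x^2
}

# advance (S, C) one interval; returns c(S1, C1, d_disease, d_other).
# Putzer form e^{At} = e^{l1 t} I + phi(t) (A - l1 I) with the divided
# difference phi computed through expm1 so nearly-coincident eigenvalues
# (r = 0, i = f) need no separate branch for the states.
.step_state <- function(S, C, i, r, f, m, dt = 1) {
  disc <- sqrt(max((r + f - i)^2 + 4 * r * i, 0))
  l1 <- (-(i + r + f) + disc) / 2
  l2 <- l1 - disc
  uS <- (-i - l1) * S + r * C
  uC <- i * S + (-(r + f) - l1) * C
  x1 <- l1 - m
  x2 <- l2 - m
  e1 <- exp(x1 * dt)
  phi <- if (disc > 0) e1 * (-expm1(-disc * dt)) / disc else dt * e1
  S1 <- e1 * S + phi * uS
  C1 <- e1 * C + phi * uC
  J1 <- .J(x1, dt)
  Jd <- if (disc * dt > 1e-5) (J1 - .J(x2, dt)) / disc
        else .K(x1 - disc / 2, dt)
  dd <- f * (C * J1 + uC * Jd)
  do <- m * ((S + C) * J1 + (uS + uC) * Jd)
  c(S1, C1, dd, do)
}

#' Integrate the illness-death cohort model over the age grid
#'
#' Solves the coupled system `dS/da = -(i + m) S + r C`,
#' `dC/da = i S - (r + f + m) C` for a birth cohort, with the hazards of a
#' [hazard_schedule()] held constant within each one-year age interval.
#' The default method uses the exact closed-form solution of the 2x2 linear
#' system within each interval (other-cause survival factors out
#' multiplicatively, so prevalence `p = C / (S + C)` is invariant to `m`);
#' `method = "ode"` integrates the same system numerically with
#' [deSolve::ode()] as a cross-check.
#'
#' @param hazards a [hazard_schedule()].
#' @param init numeric length-2 vector `c(S0, C0)` of initial proportions at
#'   the first grid age; must be non-negative and sum to 1. Default: the
#'   whole cohort starts disease-free.
#' @param method `"closed"` (exact per-interval solution) or `"ode"`
#'   (numerical integration).
#' @return A `data.frame` of class `"state_trajectory"` with one row per
#'   exact age from the first grid age to one past the last, and columns
#'   `age`, `S` (alive, disease-free), `C` (alive, diseased), `p`
#'   (prevalence among the living), `D_disease` and `D_other` (cumulative
#'   deaths by cause). `S + C + D_disease + D_other = S0 + C0` at every age.
#' @examples
#' hz <- hazard_schedule(0:60, i = 0.01)
#' tr <- integrate_cohort(hz)
#' tr$p[tr$age == 40]  # 1 - exp(-0.4)
#' @export
integrate_cohort <- function(hazards, init = c(1, 0),
                             method = c("closed", "ode")) {
  method <- match.arg(method)
  if (!inherits(hazards, "hazard_schedule"))
    hazards <- hazard_schedule(hazards$age, hazards$i, hazards$r,
                               hazards$f, hazards$m)
  init <- as.numeric(init)
  if (length(init) != 2 || any(init < 0) || abs(sum(init) - 1) > 1e-8)
    stop("initial state must be two non-negative proportions summing to 1")
  n <- nrow(hazards)
  S <- C <- Dd <- Do <- numeric(n + 1L)
  S[1] <- init[1]; C[1] <- init[2]
  if (method == "closed") {
    for (k in seq_len(n)) {
      st <- .step_state(S[k], C[k], hazards$i[k], hazards$r[k],
                        hazards$f[k], hazards$m[k])
      S[k + 1] <- st[1]; C[k + 1] <- st[2]
      Dd[k + 1] <- Dd[k] + st[3]; Do[k + 1] <- Do[k] + st[4]
    }
  } else {
    deriv <- function(t, y, parms) {
      list(c(-(parms[1] + parms[4]) * y[1] + parms[2] * y[2],
             parms[1] * y[1] - (parms[2] + parms[3] + parms[4]) * y[2],
             parms[3] * y[2],
             parms[4] * (y[1] + y[2])))
    }
    y <- c(S[1], C[1], 0, 0)
    for (k in seq_len(n)) {
      p <- c(hazards$i[k], hazards$r[k], hazards$f[k], hazards$m[k])
      sol <- deSolve::ode(y, c(0, 1), deriv, p, method = "lsoda",
                          rtol = 1e-12, atol = 1e-14)
      y <- as.numeric(sol[2, -1])
      S[k + 1] <- y[1]; C[k + 1] <- y[2]; Dd[k + 1] <- y[3]; Do[k + 1] <- y[4]
    }
  }
  alive <- S + C
  out <- data.frame(age = c(hazards$age, max(hazards$age) + 1L),
                    S = S, C = C,
                    p = ifelse(alive > 0, C / alive, NA_real_),
                    D_disease = Dd, D_other = Do)
  class(out) <- c("state_trajectory", "data.frame")
  out
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> ages %d-%d\n", min(x$age), max(x$age)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Disease-attributable population mortality rate from a trajectory
#'
#' Returns the cause-specific mortality rate `M(a) = f(a) * p(a)`: disease
#' deaths per living person-year in the whole population, the quantity a
#' death-certificate tabulation of disease-attributable mortality measures.
#'
#' @param traj a [state_trajectory][integrate_cohort()] produced from
#'   `hazards`.
#' @param hazards the [hazard_schedule()] the trajectory was produced from.
#' @return `data.frame` with columns `age` and `M`, one row per hazard grid
#'   age.
#' @export
csmr_from_trajectory <- function(traj, hazards) {
  idx <- match(hazards$age, traj$age)
  if (anyNA(idx))
    stop("trajectory does not cover the hazard age grid (length mismatch)")
  data.frame(age = hazards$age, M = hazards$f * traj$p[idx])
}
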