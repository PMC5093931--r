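#' Expand grouped mortality rates to single years of age
#'
#' Interpolates banded mortality rates onto a single-year age grid with a
#' natural cubic spline through `(band midpoint, log rate)`, evaluated and
#' exponentiated at every grid age — the standard log-scale interpolation
#' used when preparing vital-statistics inputs for a consistency model.
#' Outside the outer midpoints the extrapolation is linear in log-rate
#' (natural end conditions), which avoids spline blow-up at the youngest
#' and oldest ages.
#'
#' Zero rates cannot enter the log transform; they are replaced by half the
#' smallest positive rate in the table (with a warning), which keeps the
#' spline defined without distorting the fitted region.
#'
#' @param table a [grouped_rate_table()] with at least 4 bands.
#' @param age_grid integer vector of single-year ages to evaluate at.
#' @return numeric vector of strictly positive rates, one per grid age; the
#'   band midpoints are reproduced exactly.
#' @examples
#' tab <- grouped_rate_table(seq(30, 70, 10), seq(39, 79, 10),
#'                           rate = 0.001 * exp(0.08 * seq(35, 75, 10)))
#' expand_mortality(tab, 30:80)
#' @export
expand_mortality <- function(table, age_grid) {
  stopifnot(inherits(table, "grouped_rate_table"))
  if (any(table$rate < 0)) stop("negative rate in mortality table")
  rate <- table$rate
  if (any(rate == 0)) {
    pos <- rate[rate > 0]
    if (!length(pos))
      stop("all rates are zero; log-scale interpolation undefined")
    rate[rate == 0] <- min(pos) / 2
    warning("zero rates replaced by half the smallest positive rate ",
            "before log transform")
  }
  if (length(rate) < 4)
    stop("need at least 4 bands for a cubic spline expansion")
  mid <- band_midpoints(table)
  fit <- stats::spline(mid, log(rate), xout = age_grid, method = "natural")
  exp(fit$y)
}

#' Fit a sigmoid prevalence curve to grouped survey data
#'
#' Smooths banded ever-had-disease prevalence into a single-year-of-age
#' curve by fitting the 3-parameter logistic
#' `P(a) = L / (1 + exp(-k (a - a0)))` by weighted least squares, treating
#' each band's rate as the curve value at the band midpoint. Weights are
#' `1 / se^2` when every band reports a positive standard error, equal
#' otherwise. With `k > 0` enforced, the fitted curve is monotone
#' non-decreasing in age, as ever-had prevalence must be when mortality
#' differentials are modest. Multi-start initialisation over
#' `a0 in {50, 65, 80}` guards against local minima.
#'
#' @param table a [grouped_rate_table()] of prevalences in `[0, 1]` with at
#'   least 4 bands.
#' @param age_grid integer ages to evaluate the fitted curve at.
#' @param start optional named list `list(L=, k=, a0=)` used as the single
#'   start (e.g. to warm-start bootstrap replicates).
#' @param max_iter Levenberg-Marquardt iteration budget per start.
#' @return list with elements `prevalence` (curve on `age_grid`), `par`
#'   (named vector `L`, `k`, `a0`), `se_par` (asymptotic standard errors,
#'   `NA` if unavailable), `rss` (weighted residual sum of squares),
#'   `degraded` (`TRUE` when no start converged; best parameters so far are
#'   still returned).
#' @examples
#' a <- seq(20, 80, 10)
#' tab <- grouped_rate_table(a, a + 9, 0.2 / (1 + exp(-0.15 * (a + 5 - 65))))
#' fit <- fit_sigmoid_prevalence(tab, 0:99)
#' fit$par
#' @export
fit_sigmoid_prevalence <- function(table, age_grid, start = NULL,
                                   max_iter = 200) {
  stopifnot(inherits(table, "grouped_rate_table"))
  p <- table$rate
  if (any(p < 0 | p > 1))
    stop("prevalence outside [0, 1]")
  if (length(p) < 4) stop("need at least 4 bands to fit a sigmoid")
  mid <- band_midpoints(table)
  w <- if (all(table$se > 0)) 1 / table$se^2 else rep(1, length(p))
  w <- w / mean(w)

  if (all(p == 0)) {
    # no disease observed anywhere: the curve is pinned at the lower bound
    par <- c(L = 1e-8, k = 0.1, a0 = stats::median(mid))
    return(list(prevalence = rep(0, length(age_grid)), par = par,
                se_par = c(L = NA, k = NA, a0 = NA), rss = 0,
                degraded = FALSE))
  }

  sig <- function(a, L, k, a0) L / (1 + exp(-k * (a - a0)))
  lower <- c(L = 1e-8, k = 1e-6, a0 = -100)
  upper <- c(L = 1, k = 2, a0 = 200)
  starts <- if (!is.null(start)) list(unlist(start)[c("L", "k", "a0")])
            else lapply(c(50, 65, 80), function(a0)
              c(L = min(max(max(p) * 1.2, 1e-4), 1), k = 0.1, a0 = a0))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(rate ~ L / (1 + exp(-k * (mid - a0))),
                        data = data.frame(rate = p, mid = mid),
                        start = as.list(s), weights = w,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    conv <- fit$convInfo$isConv
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss, conv = isTRUE(conv))
  }

  if (is.null(best)) {
    # LM never produced a fit: fall back to the first start, flagged
    s <- starts[[1]]
    warning("sigmoid fit failed to converge; returning starting values")
    return(list(prevalence = sig(age_grid, s["L"], s["k"], s["a0"]),
                par = s, se_par = c(L = NA, k = NA, a0 = NA),
                rss = sum(w * (p - sig(mid, s["L"], s["k"], s["a0"]))^2),
                degraded = TRUE))
  }
  par <- stats::coef(best$fit)
  se_par <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                     error = function(e) c(L = NA, k = NA, a0 = NA))
  list(prevalence = sig(age_grid, par["L"], par["k"], par["a0"]),
       par = par, se_par = se_par, rss = best$rss,
       degraded = !best$conv)
}
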