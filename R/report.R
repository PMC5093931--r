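#' Age-band scheme of the external comparison
#'
#' The bands the modelled-versus-measured comparison is reported on:
#' 0-29, 30-54, 55-64, 65-74, 75-84 and 85+.
#'
#' @return `data.frame` with columns `age_low` and `age_high` (`NA` marks
#'   the open-ended top band).
#' @export
ami_age_bands <- function() {
  data.frame(age_low = c(0, 30, 55, 65, 75, 85),
             age_high = c(29, 54, 64, 74, 84, NA))
}

#' Percentage difference with the measured rate as baseline
#'
#' `100 * (modelled - measured) / measured`, rounded to the nearest
#' integer half away from zero for display (set `round = FALSE` for the
#' unrounded value). A zero measured rate leaves the difference undefined;
#' it is returned as `NA` with a warning so both rates can be shown
#' instead.
#'
#' @param modelled,measured rates on the same scale; vectorised.
#' @param round round to integers (display convention)?
#' @return signed percentage difference(s).
#' @examples
#' percent_difference(250, 162)   # +54
#' percent_difference(733, 1107)  # -34
#' @export
percent_difference <- function(modelled, measured, round = TRUE) {
  out <- ifelse(measured > 0, 100 * (modelled - measured) / measured,
                NA_real_)
  if (anyNA(out))
    warning("measured rate of 0: percentage difference undefined, NA returned")
  if (round) round_half_away(out) else out
}

#' Aggregate single-year rates to age bands
#'
#' Population-weighted mean of single-year rates within each band, plus a
#' `Total` row over all grid ages. Computing the total from the band rates
#' with band population weights gives the same value as computing it from
#' the single years directly.
#'
#' @param rate numeric vector of single-year rates.
#' @param weights positive person-year weights, same length (the
#'   index-year population, so banded values are population rates, not
#'   age-standardised ones).
#' @param age integer ages the rates refer to.
#' @param bands band scheme (`age_low`, `age_high` with `NA` top); must
#'   cover every grid age. Default [ami_age_bands()].
#' @return `data.frame` with columns `band`, `age_low`, `age_high`,
#'   `rate`, `weight`; the last row is `Total`.
#' @export
aggregate_to_bands <- function(rate, weights, age, bands = ami_age_bands()) {
  n <- length(rate)
  stopifnot(length(weights) == n, length(age) == n)
  if (any(weights <= 0)) stop("weights must be positive")
  hi <- ifelse(is.na(bands$age_high), Inf, bands$age_high)
  lab <- ifelse(is.na(bands$age_high),
                paste0(bands$age_low, "+"),
                paste0(bands$age_low, "-", bands$age_high))
  covered <- logical(n)
  out <- data.frame(band = c(lab, "Total"),
                    age_low = c(bands$age_low, min(age)),
                    age_high = c(bands$age_high, max(age)),
                    rate = NA_real_, weight = NA_real_)
  for (g in seq_len(nrow(bands))) {
    inb <- age >= bands$age_low[g] & age <= hi[g]
    covered <- covered | inb
    if (!any(inb)) stop(sprintf("band %s covers no grid ages", lab[g]))
    out$rate[g] <- sum(rate[inb] * weights[inb]) / sum(weights[inb])
    out$weight[g] <- sum(weights[inb])
  }
  if (!all(covered)) stop("band scheme does not cover the whole age grid")
  nb <- nrow(bands)
  out$rate[nb + 1] <- sum(out$rate[1:nb] * out$weight[1:nb]) /
    sum(out$weight[1:nb])
  out$weight[nb + 1] <- sum(out$weight[1:nb])
  out
}

#' Build the modelled-versus-measured comparison table
#'
#' One row per age band (and Total) per model variant, with the measured
#' registry rate and its confidence interval, the modelled rate (and
#' bootstrap credible interval when available), the rounded percentage
#' difference with the measured rate as baseline, and a flag for whether
#' the two intervals overlap. A plain-text summary names the bands whose
#' intervals fail to overlap. Report generation is deterministic: the same
#' inputs give a byte-identical table.
#'
#' @param measured banded registry rates: output of [incidence_rates()]
#'   (columns `rate`, `lo`, `hi`, `count`), or any `data.frame` with
#'   `age_low`, `age_high`, `rate` and optionally `lo`, `hi`, `count`.
#' @param modelled `data.frame` of banded modelled rates with columns
#'   `band`, `rate` and optionally `lo`, `hi` (e.g. from
#'   [aggregate_to_bands()], with intervals aggregated per bootstrap
#'   replicate). Must include the same bands plus `Total`.
#' @param trended optional second modelled variant (point estimates only,
#'   mirroring a trended run without uncertainty analysis).
#' @param sex label column.
#' @return `data.frame` of class `"ami_comparison"` with one row per band
#'   per variant and columns `sex`, `variant`, `band`, `events`,
#'   `measured`, `measured_lo`, `measured_hi`, `modelled`, `modelled_lo`,
#'   `modelled_hi`, `pct_difference`, `interval_overlap`; the text summary
#'   is in `attr(, "summary")`.
#' @export
build_report <- function(measured, modelled, trended = NULL, sex = "all") {
  m_lab <- ifelse(is.na(measured$age_high),
                  paste0(measured$age_low, "+"),
                  paste0(measured$age_low, "-", measured$age_high))
  w <- if (!is.null(measured$denominator)) measured$denominator
       else rep(1, nrow(measured))
  meas <- data.frame(band = c(m_lab, "Total"),
                     events = c(measured$count,
                                sum(measured$count)),
                     measured = c(measured$rate,
                                  sum(measured$rate * w) / sum(w)),
                     measured_lo = NA_real_, measured_hi = NA_real_)
  if (!is.null(measured$lo)) {
    n_tot <- sum(measured$count)
    tot <- meas$measured[nrow(meas)]
    meas$measured_lo <- c(measured$lo,
                          max(tot * (1 - .z975() / sqrt(max(n_tot, 1))), 0))
    meas$measured_hi <- c(measured$hi,
                          tot * (1 + .z975() / sqrt(max(n_tot, 1))))
  }

  variants <- list(untrended = modelled)
  if (!is.null(trended)) variants$trended <- trended
  rows <- lapply(names(variants), function(v) {
    mod <- variants[[v]]
    if (!all(meas$band %in% mod$band))
      stop(sprintf("band scheme mismatch: modelled table lacks band(s) %s",
                   paste(setdiff(meas$band, mod$band), collapse = ", ")))
    mod <- mod[match(meas$band, mod$band), , drop = FALSE]
    has_ci <- !is.null(mod$lo)
    data.frame(sex = sex, variant = v, band = meas$band,
               events = meas$events,
               measured = meas$measured,
               measured_lo = meas$measured_lo,
               measured_hi = meas$measured_hi,
               modelled = mod$rate,
               modelled_lo = if (has_ci) mod$lo else NA_real_,
               modelled_hi = if (has_ci) mod$hi else NA_real_,
               pct_difference = suppressWarnings(
                 percent_difference(mod$rate, meas$measured)),
               interval_overlap = if (has_ci && !is.null(measured$lo))
                 mod$lo <= meas$measured_hi & meas$measured_lo <= mod$hi
               else NA)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  miss <- out$band[!is.na(out$interval_overlap) & !out$interval_overlap]
  attr(out, "summary") <- if (length(miss))
    sprintf("intervals fail to overlap in band(s): %s (%s)",
            paste(unique(miss), collapse = ", "), sex)
  else sprintf("all compared intervals overlap (%s)", sex)
  class(out) <- c("ami_comparison", "data.frame")
  out
}

#' @export
print.ami_comparison <- function(x, digits = 0, ...) {
  y <- as.data.frame(x)
  for (cn in c("measured", "measured_lo", "measured_hi",
               "modelled", "modelled_lo", "modelled_hi"))
    y[[cn]] <- round_half_away(y[[cn]], digits)
  print.data.frame(y, row.names = FALSE)
  cat(attr(x, "summary"), "\n")
  invisible(x)
}
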