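#' Grouped age-band rate table
#'
#' The exchange format for survey and vital-statistics inputs: one row per
#' age band with a rate, its standard error, and optionally the event count
#' and denominator it came from. Bands are ascending, non-overlapping, and
#' at most the top band may be open-ended (`age_high = NA`, e.g. "85+").
#'
#' @param age_low,age_high integer band bounds in completed years;
#'   `age_high` is inclusive, `NA` marks an open-ended top band.
#' @param rate non-negative rate per person or per person-year.
#' @param se non-negative standard error of `rate`; defaults to 0.
#' @param count,denominator optional event counts and denominators; where
#'   both are given, `rate` must equal `count / denominator` to 0.5% or
#'   rounding of small counts.
#' @return `data.frame` of class `"grouped_rate_table"`.
#' @examples
#' grouped_rate_table(c(35, 45, 55, 65, 75), c(44, 54, 64, 74, NA),
#'                    rate = c(1, 3, 8, 20, 45) / 1000)
#' @export
grouped_rate_table <- function(age_low, age_high, rate, se = 0,
                               count = NA_real_, denominator = NA_real_) {
  n <- length(age_low)
  se <- rep_len(as.numeric(se), n)
  count <- rep_len(as.numeric(count), n)
  denominator <- rep_len(as.numeric(denominator), n)
  tab <- data.frame(age_low = as.numeric(age_low),
                    age_high = as.numeric(age_high),
                    rate = as.numeric(rate), se = se,
                    count = count, denominator = denominator)
  tab <- tab[order(tab$age_low), , drop = FALSE]
  rownames(tab) <- NULL
  if (any(tab$rate < 0)) stop("rates must be non-negative")
  if (any(tab$se < 0)) stop("standard errors must be non-negative")
  open <- is.na(tab$age_high)
  if (sum(open) > 1 || (any(open) && which(open) != n))
    stop("only the top band may be open-ended")
  hi <- ifelse(open, Inf, tab$age_high)
  if (any(tab$age_low > hi)) stop("band bounds out of order")
  if (n > 1 && any(tab$age_low[-1] <= hi[-n]))
    stop("age bands overlap or are not ascending")
  ok <- !is.na(tab$count) & !is.na(tab$denominator) & tab$denominator > 0
  if (any(ok)) {
    imp <- tab$count[ok] / tab$denominator[ok]
    tol <- pmax(0.005 * pmax(imp, 1e-12), 0.5 / tab$denominator[ok])
    if (any(abs(tab$rate[ok] - imp) > tol))
      stop("rate does not equal count / denominator")
  }
  class(tab) <- c("grouped_rate_table", "data.frame")
  tab
}

#' @export
print.grouped_rate_table <- function(x, ...) {
  cat(sprintf("<grouped_rate_table> %d bands, ages %g-%s\n", nrow(x),
              min(x$age_low),
              if (anyNA(x$age_high)) paste0(max(x$age_low), "+")
              else max(x$age_high)))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Band midpoints of a grouped rate table
#'
#' Ages are completed years, so the band `[a_low, a_high]` covers exact ages
#' `[a_low, a_high + 1)` and its midpoint is `(a_low + a_high + 1) / 2`.
#' An open-ended top band gets midpoint `age_low + 5`, reflecting how
#' quickly survivorship thins the open interval.
#'
#' @param table a [grouped_rate_table()].
#' @return numeric vector of midpoints in exact years.
#' @export
band_midpoints <- function(table) {
  ifelse(is.na(table$age_high), table$age_low + 5,
         (table$age_low + table$age_high + 1) / 2)
}

#' Read or write grouped rate tables as delimited text
#'
#' Tab-delimited with header `age_low, age_high, rate, se, count,
#' denominator`; an open-ended top band is written with `age_high` empty or
#' the word `"plus"`.
#'
#' @param path file path.
#' @param x a [grouped_rate_table()].
#' @return `read_grouped_rates()` returns a validated
#'   [grouped_rate_table()]; `write_grouped_rates()` returns `path`
#'   invisibly.
#' @export
read_grouped_rates <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = list(age_high = "character"))
  need <- c("age_low", "age_high", "rate")
  if (!all(need %in% names(d)))
    stop("grouped rate file must have columns age_low, age_high, rate")
  ah <- trimws(d$age_high)
  ah[ah %in% c("", "plus", "NA")] <- NA
  if (is.null(d$se)) d$se <- 0
  if (is.null(d$count)) d$count <- NA_real_
  if (is.null(d$denominator)) d$denominator <- NA_real_
  grouped_rate_table(d$age_low, as.numeric(ah), d$rate, d$se,
                     d$count, d$denominator)
}

#' @rdname read_grouped_rates
#' @export
write_grouped_rates <- function(x, path) {
  stopifnot(inherits(x, "grouped_rate_table"))
  out <- as.data.frame(x)
  out$age_high <- ifelse(is.na(out$age_high), "plus", out$age_high)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
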