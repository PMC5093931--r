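#' Age-indexed schedule of illness-death transition hazards
#'
#' A hazard schedule holds the four transition rates of the three-state
#' illness-death model on a single-year-of-age grid: incidence `i` (first
#' disease events per disease-free person-year), remission `r` (per diseased
#' person-year), case fatality `f` (disease deaths per diseased person-year)
#' and other-cause mortality `m` (per person-year, acting equally on both
#' living states). Each rate is constant on the half-open year `[a, a + 1)`
#' starting at its grid age.
#'
#' @param age integer vector of consecutive single-year ages (e.g. `0:99`).
#' @param i,r,f,m numeric vectors of rates per person-year, recycled if of
#'   length 1; all must be finite and non-negative and the same length as
#'   `age`.
#'
#' @return A `data.frame` of class `"hazard_schedule"` with columns
#'   `age`, `i`, `r`, `f`, `m`.
#' @examples
#' hz <- hazard_schedule(0:80, i = 0.01, r = 0, f = 0.2, m = 0.01)
#' @seealso [integrate_cohort()]
#' @export
hazard_schedule <- function(age, i, r = 0, f = 0, m = 0) {
  age <- as.integer(age)
  n <- length(age)
  if (n < 1L) stop("age grid is empty")
  if (any(diff(age) != 1L)) stop("age grid must be consecutive single years")
  rates <- list(i = i, r = r, f = f, m = m)
  for (nm in names(rates)) {
    x <- rates[[nm]]
    if (length(x) == 1L) x <- rep(as.numeric(x), n)
    if (length(x) != n)
      stop(sprintf("rate '%s' has length %d but age grid has length %d",
                   nm, length(x), n))
    if (any(!is.finite(x)))
      stop(sprintf("rate '%s' is non-finite at age %d",
                   nm, age[which(!is.finite(x))[1]]))
    if (any(x < 0))
      stop(sprintf("rate '%s' is negative (%g) at age %d",
                   nm, x[which(x < 0)[1]], age[which(x < 0)[1]]))
    rates[[nm]] <- as.numeric(x)
  }
  out <- data.frame(age = age, i = rates$i, r = rates$r,
                    f = rates$f, m = rates$m)
  class(out) <- c("hazard_schedule", "data.frame")
  out
}

#' @export
print.hazard_schedule <- function(x, ...) {
  cat(sprintf("<hazard_schedule> ages %d-%d (%d one-year intervals)\n",
              min(x$age), max(x$age), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read or write a hazard schedule as delimited text
#'
#' Plain tab-delimited text with a header row and columns `age`, `i`, `r`,
#' `f`, `m`, one row per single year of age.
#'
#' @param path file path.
#' @param x a [hazard_schedule()].
#' @return `read_hazard_schedule()` returns a validated
#'   [hazard_schedule()]; `write_hazard_schedule()` returns `path`
#'   invisibly.
#' @export
read_hazard_schedule <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("age", "i", "r", "f", "m")
  if (!all(need %in% names(d)))
    stop("hazard schedule file must have columns age, i, r, f, m")
  hazard_schedule(d$age, d$i, d$r, d$f, d$m)
}

#' @rdname read_hazard_schedule
#' @export
write_hazard_schedule <- function(x, path) {
  stopifnot(inherits(x, "hazard_schedule"))
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
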