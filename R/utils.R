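#' @importFrom methods new validObject is slot
#' @importFrom stats approx rnorm runif sd median quantile setNames
#' @importFrom utils read.csv read.delim head tail
NULL

# 1 uCi = 3.7e4 Bq, exact by definition of the curie.
UCI_TO_BQ <- 3.7e4
MEV_TO_J <- 1.602176634e-13
SECONDS_PER_DAY <- 86400
DAYS_PER_YEAR <- 365.25

#' Convert microcuries to becquerels
#'
#' Exact unit conversion, 1 uCi = 3.7e4 Bq.
#'
#' @param activity_uCi numeric vector of activities in microcuries; must be
#'   finite and non-negative.
#' @return activities in Bq.
#' @examples
#' toBecquerel(1)      # 37000
#' toBecquerel(0.620)  # 22940
#' @export
toBecquerel <- function(activity_uCi) {
  stopifnot(is.numeric(activity_uCi))
  if (any(!is.finite(activity_uCi))) stop("activity must be finite")
  if (any(activity_uCi < 0)) stop("activity must be non-negative")
  activity_uCi * UCI_TO_BQ
}

#' Convert becquerels to microcuries
#' @param activity_Bq numeric vector in Bq.
#' @return activities in uCi.
#' @export
toMicrocurie <- function(activity_Bq) {
  stopifnot(is.numeric(activity_Bq))
  activity_Bq / UCI_TO_BQ
}

# Round half away from zero (the convention of the historical tables;
# base::round rounds half to even).
roundHalfUp <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Calendar difference in days (numeric).
daysBetween <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from))
}

# Convert a half-life (value, unit) to days. Units: y, d, min, s, us.
halfLifeToDays <- function(value, unit) {
  mult <- c(y = DAYS_PER_YEAR, d = 1, min = 1 / 1440, s = 1 / SECONDS_PER_DAY,
            us = 1e-6 / SECONDS_PER_DAY)
  if (!unit %in% names(mult)) {
    stop("malformed half-life unit: '", unit, "' (expected one of ",
         paste(names(mult), collapse = ", "), ")")
  }
  value * mult[[unit]]
}

# Trapezoidal integral of y(x) over the full grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

.asDate <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}
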