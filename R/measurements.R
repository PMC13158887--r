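MEASUREMENT_METHODS <- c("tilting_chair", "seven_crystal", "rn_breath_plus_external")

#' Retained fraction from an emanating fraction
#'
#' The retained ("non-emanating") fraction is the complement of the
#' emanating fraction; the round trip is exact.
#'
#' @param emanating_fraction numeric in [0, 1].
#' @return retained fraction, \code{1 - emanating_fraction}.
#' @examples
#' emanatingComplement(0.69)  # 0.31
#' @export
emanatingComplement <- function(emanating_fraction) {
  stopifnot(is.numeric(emanating_fraction))
  if (any(emanating_fraction < 0 | emanating_fraction > 1)) {
    stop("emanating fraction must lie in [0, 1]")
  }
  1 - emanating_fraction
}

.burdenEstimate <- function(date, burden_uCi, provenance) {
  data.frame(date = .asDate(date),
             body_burden_uCi = roundHalfUp(burden_uCi, 3),
             body_burden_Bq = burden_uCi * UCI_TO_BQ,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Body burden from an external-only whole-body count
#'
#' External counting detects only the radon progeny retained in the body, so
#' the measured activity is divided by an assumed retained fraction to give
#' the total Ra-226 body burden. The reported uCi value is rounded half away
#' from zero to 3 decimals (the convention of the historical tables); the Bq
#' value is unrounded.
#'
#' @param measured_uCi externally measured activity (uCi).
#' @param retained_fraction assumed retained (non-emanating) fraction, in (0, 1].
#' @param date optional measurement date (default NA).
#' @return one-row data.frame: \code{date}, \code{body_burden_uCi} (rounded),
#'   \code{body_burden_Bq} (exact), \code{provenance}.
#' @examples
#' burdenFromExternal(0.570, 0.31)$body_burden_uCi  # 1.839
#' @export
burdenFromExternal <- function(measured_uCi, retained_fraction, date = NA) {
  if (!is.finite(measured_uCi) || measured_uCi < 0) stop("measured activity must be finite and non-negative")
  if (!is.finite(retained_fraction) || retained_fraction <= 0 || retained_fraction > 1) {
    stop("retained fraction must lie in (0, 1]")
  }
  .burdenEstimate(date, measured_uCi / retained_fraction,
                  sprintf("external %0.3f uCi / retained %0.3g", measured_uCi, retained_fraction))
}

#' Body burden from a paired radon-breath plus external measurement
#'
#' When a radon-breath measurement (the emanating portion, expressed as its
#' Ra-226 equivalent) and an external count (the retained portion) are made
#' on the same date, the two activities are simply summed; no emanating
#' correction is needed.
#'
#' @param breath_equiv_uCi radon-breath Ra-226-equivalent activity (uCi).
#' @param external_uCi externally counted activity (uCi).
#' @param date optional measurement date (default NA).
#' @return one-row data.frame as in \code{\link{burdenFromExternal}}.
#' @examples
#' burdenFromPaired(1.024, 0.548)$body_burden_uCi  # 1.572
#' burdenFromPaired(0.659, 0.510)$body_burden_uCi  # 1.169
#' @export
burdenFromPaired <- function(breath_equiv_uCi, external_uCi, date = NA) {
  if (!is.finite(breath_equiv_uCi) || breath_equiv_uCi < 0 ||
      !is.finite(external_uCi) || external_uCi < 0) {
    stop("activities must be finite and non-negative")
  }
  .burdenEstimate(date, breath_equiv_uCi + external_uCi,
                  sprintf("breath %0.3f + external %0.3f uCi", breath_equiv_uCi, external_uCi))
}

#' Parse a historical measurement table
#'
#' Reads the standard measurement CSV schema: columns \code{date} (ISO 8601),
#' \code{age}, \code{method} (\code{tilting_chair}, \code{seven_crystal} or
#' \code{rn_breath_plus_external}), \code{external_uCi}, \code{breath_uCi},
#' \code{retained_fraction}, \code{flag}; empty cells are absent values.
#' Validation enforces the method/field pairing: paired breath+external rows
#' must carry both activities and no retained fraction; external-only rows
#' must carry an external activity and a retained fraction in (0, 1]. Rows
#' with quality flags are parsed normally -- exclusion is an analysis-stage
#' choice.
#'
#' @param path path to the CSV file; default is the bundled case-study table.
#' @return data.frame of validated measurement records.
#' @examples
#' recs <- parseMeasurementTable()
#' nrow(recs)  # 8
#' @export
parseMeasurementTable <- function(path = system.file("extdata", "case_03_429_measurements.csv",
                                                     package = "radrecon")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("date", "age", "method", "external_uCi", "breath_uCi",
                "retained_fraction", "flag")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("measurement table lacks column(s): ", paste(missing, collapse = ", "))
  tab$date <- as.character(tab$date)
  tab$method <- as.character(tab$method)
  tab$flag <- as.character(tab$flag)
  for (col in c("external_uCi", "breath_uCi", "retained_fraction")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  if (nrow(tab) == 0) {
    tab$date <- as.Date(character())
    return(tab)
  }
  dates <- as.Date(tab$date, format = "%Y-%m-%d")
  if (any(is.na(dates))) {
    stop("unparseable date in row ", which(is.na(dates))[1], ": '",
         tab$date[which(is.na(dates))[1]], "'")
  }
  tab$date <- dates
  tab$flag[is.na(tab$flag)] <- ""
  for (i in seq_len(nrow(tab))) {
    m <- tab$method[i]
    if (!m %in% MEASUREMENT_METHODS) {
      stop("row ", i, ": unknown method '", m, "'")
    }
    if (m == "rn_breath_plus_external") {
      if (is.na(tab$external_uCi[i]) || is.na(tab$breath_uCi[i])) {
        stop("row ", i, ": paired method requires both external_uCi and breath_uCi")
      }
      if (!is.na(tab$retained_fraction[i])) {
        stop("row ", i, ": paired method must not carry a retained_fraction")
      }
    } else {
      if (is.na(tab$external_uCi[i])) {
        stop("row ", i, ": external-only method requires external_uCi")
      }
      rf <- tab$retained_fraction[i]
      if (is.na(rf) || rf <= 0 || rf > 1) {
        stop("row ", i, ": external-only method requires retained_fraction in (0, 1]")
      }
    }
  }
  tab
}

#' Body-burden estimates for a table of measurement records
#'
#' Applies \code{\link{burdenFromExternal}} or \code{\link{burdenFromPaired}}
#' per record according to its method, carrying dates, flags and provenance.
#'
#' @param records data.frame from \code{\link{parseMeasurementTable}}.
#' @return data.frame: \code{date}, \code{method}, \code{body_burden_uCi}
#'   (rounded to 3 decimals), \code{body_burden_Bq} (exact),
#'   \code{provenance}, \code{flag}.
#' @export
computeBurdens <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(date = as.Date(character()), method = character(),
                      body_burden_uCi = numeric(), body_burden_Bq = numeric(),
                      provenance = character(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    est <- if (r$method == "rn_breath_plus_external") {
      burdenFromPaired(r$breath_uCi, r$external_uCi, date = r$date)
    } else {
      burdenFromExternal(r$external_uCi, r$retained_fraction, date = r$date)
    }
    est$method <- r$method
    est$flag <- r$flag
    est
  })
  out <- do.call(rbind, rows)
  out[, c("date", "method", "body_burden_uCi", "body_burden_Bq", "provenance", "flag")]
}
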