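#' Scaling factor of a measured burden against the unit-intake model
#'
#' Ratio of a measured body burden to the body burden of the unit-intake
#' forward model at the same time. By linearity of the compartment system,
#' multiplying the unit model by this factor reproduces the measurement.
#'
#' @param measured_bb measured body burden (Bq).
#' @param model_bb_unit_intake unit-intake model body burden (Bq) at the same
#'   date; must be positive (a zero model burden means the measurement
#'   predates the modeled intake).
#' @return dimensionless scaling factor.
#' @examples
#' scalingFactor(2, 1)  # 2
#' @export
scalingFactor <- function(measured_bb, model_bb_unit_intake) {
  if (any(model_bb_unit_intake <= 0)) {
    stop("unit-model body burden is zero at a measurement date (measurement predates intake)")
  }
  measured_bb / model_bb_unit_intake
}

#' Fit the ingestion rate by scaling a unit-intake model
#'
#' Computes one scaling factor per body-burden estimate, averages them
#' (arithmetically by default), and converts the mean factor into an implied
#' ingestion rate and total ingestion. The band is the unit body-burden
#' curve multiplied by mean plus/minus one sample standard deviation.
#'
#' @param estimates data.frame of body-burden estimates with columns
#'   \code{date} and \code{body_burden_Bq} (from \code{\link{computeBurdens}}).
#' @param unit_tad \linkS4class{TimeActivityDistribution} of the unit-intake
#'   model; its grid must cover every estimate date.
#' @param unit_rate base ingestion rate (Bq/d) the unit model was solved at
#'   (default 1).
#' @param log_space average the factors in log space (geometric mean) instead
#'   of arithmetically; off by default.
#' @return a \linkS4class{ScalingFit}.
#' @export
fitIntake <- function(estimates, unit_tad, unit_rate = 1, log_space = FALSE) {
  if (nrow(estimates) == 0) stop("no body-burden estimates supplied")
  modelBB <- bodyBurden(unit_tad, estimates$date)
  bad <- which(modelBB <= 0)
  if (length(bad)) {
    stop("measurement dated ", estimates$date[bad[1]],
         " predates the modeled intake (unit-model burden is zero)")
  }
  f <- estimates$body_burden_Bq / modelBB
  names(f) <- as.character(estimates$date)
  if (log_space) {
    m <- exp(mean(log(f)))
    s <- if (length(f) > 1) m * sd(log(f)) else NA_real_
  } else {
    m <- mean(f)
    s <- if (length(f) > 1) sd(f) else NA_real_
  }
  sched <- .scaleSchedule(unit_tad@schedule, m)
  body <- unit_tad@model@compartments
  first <- unit_tad@nuclides[1]
  unitCurve <- rowSums(unit_tad@activities[, body, first, drop = FALSE][, , 1, drop = FALSE])
  sBand <- if (is.na(s)) 0 else s
  band <- data.frame(time_d = unit_tad@timesDays,
                     date = unit_tad@birthDate + unit_tad@timesDays,
                     mean_Bq = m * unitCurve,
                     lo_Bq = pmax(m - sBand, 0) * unitCurve,
                     hi_Bq = (m + sBand) * unitCurve)
  new("ScalingFit", factors = f, mean = m, sd = s, unitRate = unit_rate,
      rate = m * unit_rate, totalIngestion = totalIntake(sched),
      schedule = sched, band = band, logSpace = log_space)
}

#' Single-measurement (legacy-anchored) fit
#'
#' Historical assessments anchored the intake to a single measurement. This
#' restricts \code{\link{fitIntake}} to one selected record; the standard
#' deviation is reported as \code{NA}.
#'
#' @param estimates data.frame of body-burden estimates.
#' @param unit_tad unit-intake \linkS4class{TimeActivityDistribution}.
#' @param selector \code{"latest"} or a 1-based row index.
#' @param unit_rate base rate of the unit model (Bq/d).
#' @return a \linkS4class{ScalingFit} with a single factor.
#' @export
singleMeasurementMode <- function(estimates, unit_tad, selector = "latest",
                                  unit_rate = 1) {
  if (nrow(estimates) == 0) stop("no body-burden estimates supplied")
  i <- if (identical(selector, "latest")) {
    which.max(as.numeric(estimates$date))
  } else {
    sel <- as.integer(selector)
    if (is.na(sel) || sel < 1 || sel > nrow(estimates)) {
      stop("selector index out of range: ", selector)
    }
    sel
  }
  fitIntake(estimates[i, , drop = FALSE], unit_tad, unit_rate = unit_rate)
}

#' Back-calculate total ingestion from a systemic intake
#'
#' Converts a systemic (absorbed-to-blood) intake into the total ingested
#' activity by dividing by the fractional alimentary absorption, as done in
#' historical single-compartment assessments.
#'
#' @param systemic_intake_Bq systemic intake (Bq; any activity unit works,
#'   the result carries the same unit).
#' @param f_absorption fractional absorption, in (0, 1].
#' @return total ingestion in the unit of \code{systemic_intake_Bq}.
#' @examples
#' anlBackCalculation(toBecquerel(273.7), 0.2) / 1e6  # 50.63 MBq
#' @export
anlBackCalculation <- function(systemic_intake_Bq, f_absorption) {
  if (!is.finite(f_absorption) || f_absorption <= 0 || f_absorption > 1) {
    stop("absorption fraction must lie in (0, 1]")
  }
  systemic_intake_Bq / f_absorption
}

#' @rdname radrecon-generics
#' @export
setMethod("scalingFactors", "ScalingFit", function(object, ...) object@factors)

#' @rdname radrecon-generics
#' @export
setMethod("intakeRate", "ScalingFit", function(object, ...) object@rate)

#' @rdname radrecon-generics
#' @export
setMethod("totalIngestion", "ScalingFit", function(object, ...) object@totalIngestion)

setMethod("show", "ScalingFit", function(object) {
  cat("ScalingFit from", length(object@factors), "measurement(s)\n")
  cat(sprintf("  mean factor %0.6g (sd %s, %s mean)\n", object@mean,
              if (is.na(object@sd)) "NA" else sprintf("%0.6g", object@sd),
              if (object@logSpace) "geometric" else "arithmetic"))
  cat(sprintf("  ingestion rate %0.6g Bq/d; total ingestion %0.6g Bq\n",
              object@rate, object@totalIngestion))
})

#' Write a scaling-fit report
#'
#' Emits the per-measurement factors as a delimited table and the summary as
#' key/value lines, mirroring the points-plus-band presentation of the fit.
#'
#' @param fit a \linkS4class{ScalingFit}.
#' @param path_factors path for the per-measurement factor CSV.
#' @param path_summary path for the key/value summary.
#' @return invisibly, the summary as a named character vector.
#' @export
writeFitReport <- function(fit, path_factors, path_summary) {
  fac <- data.frame(date = names(fit@factors),
                    scaling_factor = signif(fit@factors, 6))
  utils::write.csv(fac, path_factors, row.names = FALSE, quote = FALSE)
  kv <- c(n_measurements = length(fit@factors),
          mean_factor = signif(fit@mean, 6),
          sd_factor = signif(fit@sd, 6),
          unit_rate_Bq_per_d = signif(fit@unitRate, 6),
          ingestion_rate_Bq_per_d = signif(fit@rate, 6),
          ingestion_rate_uCi_per_d = signif(toMicrocurie(fit@rate), 6),
          total_ingestion_Bq = signif(fit@totalIngestion, 6),
          total_ingestion_uCi = signif(toMicrocurie(fit@totalIngestion), 6))
  writeLines(paste(names(kv), kv, sep = "\t"), path_summary)
  invisible(kv)
}
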