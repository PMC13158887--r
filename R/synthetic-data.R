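#' Default synthetic dial-worker configuration
#'
#' Study conditions for generated cases: a two-period chronic ingestion
#' (work 1923--1927, lip-pointing cutoff 1927-01-01, post/pre ratio 1/100),
#' a sparse schedule of measurements decades after exposure, external-only
#' counting before 1970 and paired radon-breath plus external counting after
#' (mirroring how instrumentation evolved), multiplicative lognormal
#' measurement noise with geometric SD 1.2, and a per-case emanating
#' fraction drawn uniformly from the historically reported 37--75% range.
#'
#' @param ... named overrides of any default.
#' @return configuration list.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    birth_date = "1908-08-01",
    work_start = "1923-08-01",
    work_end = "1927-08-01",
    cutoff = "1927-01-01",
    death_date = "1976-07-01",
    post_ratio = 0.01,
    base_rate_Bq_per_d = 1e4,
    emanating_range = c(0.37, 0.75),
    gsd = 1.2,
    n_measurements = 8,
    measurement_window = c("1957-01-01", "1975-01-01"),
    paired_after = "1970-01-01",
    assumed_retained = NULL  # NULL: the estimator is told the true value
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

.validateSynthConfig <- function(cfg) {
  if (cfg$gsd < 1) stop("noise GSD must be >= 1")
  er <- cfg$emanating_range
  if (length(er) != 2 || er[1] > er[2] || er[1] < 0 || er[2] > 1) {
    stop("emanating_range must be an increasing pair within [0, 1]")
  }
  w <- .asDate(cfg$measurement_window)
  if (w[1] < .asDate(cfg$birth_date) || w[2] > .asDate(cfg$death_date)) {
    stop("measurement dates outside life span")
  }
  if (cfg$n_measurements < 1) stop("need at least one measurement")
  invisible(cfg)
}

# Unit-intake forward model for a config's worker metadata.
.unitModelFor <- function(cfg, model = loadBiokineticModel(), chain = loadChain()) {
  sched <- buildSchedule(cfg$work_start, cfg$work_end, cfg$cutoff,
                         post_ratio = cfg$post_ratio, base_rate = 1)
  solveBiokinetics(model, sched, chain, cfg$birth_date, cfg$death_date)
}

#' Generate one synthetic dial-worker case
#'
#' Forward-models the true body burden at the configured base rate, draws a
#' per-case emanating fraction and measurement schedule, and emits a
#' measurement table in the standard CSV schema with multiplicative
#' lognormal noise. External-only rows report
#' \code{retained_fraction x burden x noise}; paired rows split the burden
#' into emanating and retained portions with independent noise on each. The
#' truth record retains the generating rate, total ingestion and true
#' burden at the measurement dates for scoring.
#'
#' @param config list from \code{\link{syntheticConfig}}.
#' @param seed integer seed; the case is reproducible from it.
#' @param unit_tad optional precomputed unit-intake
#'   \linkS4class{TimeActivityDistribution} for the config's worker metadata
#'   (computed if missing; pass one when generating many cases).
#' @return a \linkS4class{SyntheticCase}.
#' @export
generateCase <- function(config = syntheticConfig(), seed = 1, unit_tad = NULL) {
  .validateSynthConfig(config)
  if (is.null(unit_tad)) unit_tad <- .unitModelFor(config)
  set.seed(seed)
  emanating <- runif(1, config$emanating_range[1], config$emanating_range[2])
  retainedTrue <- emanatingComplement(emanating)
  w <- .asDate(config$measurement_window)
  dates <- sort(w[1] + round(runif(config$n_measurements, 0, daysBetween(w[1], w[2]))))
  trueBB <- config$base_rate_Bq_per_d * bodyBurden(unit_tad, dates)
  sdlog <- log(config$gsd)
  paired <- dates >= .asDate(config$paired_after)
  birth <- .asDate(config$birth_date)
  rows <- lapply(seq_along(dates), function(i) {
    bbuCi <- toMicrocurie(trueBB[i])
    if (paired[i]) {
      noise <- exp(rnorm(2, 0, sdlog))
      data.frame(date = format(dates[i]),
                 age = floor(daysBetween(birth, dates[i]) / DAYS_PER_YEAR),
                 method = "rn_breath_plus_external",
                 external_uCi = retainedTrue * bbuCi * noise[1],
                 breath_uCi = emanating * bbuCi * noise[2],
                 retained_fraction = NA_real_, flag = "",
                 stringsAsFactors = FALSE)
    } else {
      noise <- exp(rnorm(1, 0, sdlog))
      rf <- if (is.null(config$assumed_retained)) retainedTrue else config$assumed_retained
      data.frame(date = format(dates[i]),
                 age = floor(daysBetween(birth, dates[i]) / DAYS_PER_YEAR),
                 method = "tilting_chair",
                 external_uCi = retainedTrue * bbuCi * noise,
                 breath_uCi = NA_real_,
                 retained_fraction = rf, flag = "",
                 stringsAsFactors = FALSE)
    }
  })
  meas <- do.call(rbind, rows)
  sched <- buildSchedule(config$work_start, config$work_end, config$cutoff,
                         post_ratio = config$post_ratio,
                         base_rate = config$base_rate_Bq_per_d)
  new("SyntheticCase", seed = as.numeric(seed), config = config,
      emanatingFraction = emanating, measurements = meas,
      truth = list(rate_Bq_per_d = config$base_rate_Bq_per_d,
                   total_ingestion_Bq = totalIntake(sched),
                   burden_Bq = data.frame(date = dates, burden_Bq = trueBB)))
}

#' Generate a cohort of synthetic cases
#'
#' Cases carry independent sub-seeds derived deterministically from the
#' master seed; the unit-intake forward model is solved once and shared.
#'
#' @param n number of cases (>= 1).
#' @param config list from \code{\link{syntheticConfig}}.
#' @param seed master seed.
#' @param unit_tad optional precomputed unit model.
#' @return list of \linkS4class{SyntheticCase}.
#' @export
generateCohort <- function(n, config = syntheticConfig(), seed = 1,
                           unit_tad = NULL) {
  if (n < 1) stop("n must be at least 1")
  .validateSynthConfig(config)
  if (is.null(unit_tad)) unit_tad <- .unitModelFor(config)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1, n)
  lapply(subseeds, function(s) generateCase(config, seed = s, unit_tad = unit_tad))
}

#' Fit a synthetic case's measurements
#'
#' Runs the standard estimation path on a generated case: burdens from the
#' measurement table, then a scaling-factor fit against the unit model.
#'
#' @param case a \linkS4class{SyntheticCase}.
#' @param unit_tad unit-intake model for the case's worker metadata.
#' @param assumed_retained optional retained fraction overriding the table's
#'   (for mis-specification studies of external-only schedules).
#' @return a \linkS4class{ScalingFit}.
#' @export
fitSyntheticCase <- function(case, unit_tad, assumed_retained = NULL) {
  meas <- case@measurements
  if (!is.null(assumed_retained)) {
    ext <- meas$method != "rn_breath_plus_external"
    meas$retained_fraction[ext] <- assumed_retained
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(meas, tmp, row.names = FALSE, na = "")
  burdens <- computeBurdens(parseMeasurementTable(tmp))
  fitIntake(burdens, unit_tad, unit_rate = 1)
}

#' Score parameter recovery over a cohort
#'
#' Per-case relative errors of the recovered ingestion rate and total
#' ingestion against the generator's truth, with median and IQR summaries.
#'
#' @param cases list of \linkS4class{SyntheticCase}.
#' @param fits list of \linkS4class{ScalingFit}, one per case.
#' @return list: \code{per_case} data.frame and \code{summary} (median and
#'   IQR of the absolute relative errors).
#' @export
scoreRecovery <- function(cases, fits) {
  if (length(cases) != length(fits)) stop("one fit per case is required")
  per <- do.call(rbind, lapply(seq_along(cases), function(i) {
    tr <- cases[[i]]@truth
    data.frame(case = i,
               rel_error_rate = (fits[[i]]@rate - tr$rate_Bq_per_d) / tr$rate_Bq_per_d,
               rel_error_total = (fits[[i]]@totalIngestion - tr$total_ingestion_Bq) /
                 tr$total_ingestion_Bq)
  }))
  summ <- list(
    median_abs_rel_error_rate = median(abs(per$rel_error_rate)),
    iqr_rel_error_rate = unname(diff(quantile(per$rel_error_rate, c(0.25, 0.75)))),
    median_abs_rel_error_total = median(abs(per$rel_error_total)),
    iqr_rel_error_total = unname(diff(quantile(per$rel_error_total, c(0.25, 0.75)))))
  list(per_case = per, summary = summ)
}

setMethod("show", "SyntheticCase", function(object) {
  cat("SyntheticCase (seed ", object@seed, "): ", nrow(object@measurements),
      " measurements; emanating fraction ", signif(object@emanatingFraction, 3),
      "\n  true rate ", signif(object@truth$rate_Bq_per_d, 4), " Bq/d, total ",
      signif(object@truth$total_ingestion_Bq, 4), " Bq\n", sep = "")
})

#' Write a synthetic case to disk
#'
#' Emits the measurement table in the standard CSV schema consumed by
#' \code{\link{parseMeasurementTable}} and a key/value truth sidecar.
#'
#' @param case a \linkS4class{SyntheticCase}.
#' @param dir output directory (created if needed).
#' @param stem file stem (default \code{"case"}).
#' @return invisibly, the two file paths.
#' @export
writeSyntheticCase <- function(case, dir, stem = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fMeas <- file.path(dir, paste0(stem, "_measurements.csv"))
  fTruth <- file.path(dir, paste0(stem, "_truth.txt"))
  utils::write.csv(case@measurements, fMeas, row.names = FALSE, na = "")
  kv <- c(seed = case@seed,
          emanating_fraction = signif(case@emanatingFraction, 6),
          rate_Bq_per_d = signif(case@truth$rate_Bq_per_d, 6),
          total_ingestion_Bq = signif(case@truth$total_ingestion_Bq, 6))
  writeLines(paste(names(kv), kv, sep = "\t"), fTruth)
  invisible(c(fMeas, fTruth))
}
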