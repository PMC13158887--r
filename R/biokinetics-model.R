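#' Load a compartmental biokinetic model from a YAML parameter file
#'
#' The schema lists compartments, sinks, reference ages, fA per age, the
#' total alimentary transit rate, long-format radium transfer coefficients
#' per reference age, radon escape rates per compartment, the progeny-mode
#' flag and the secular-equilibrium half-life cutoff. The loader validates
#' the file against the \linkS4class{CompartmentModel} invariants.
#'
#' @param path path to the YAML file; default is the bundled simplified model.
#' @return a validated \linkS4class{CompartmentModel}.
#' @examples
#' model <- loadBiokineticModel()
#' compartments(model)
#' @export
loadBiokineticModel <- function(path = system.file("extdata", "biokinetics_default.yaml",
                                                   package = "radrecon")) {
  cfg <- yaml::read_yaml(path)
  required <- c("compartments", "sinks", "reference_ages", "fA",
                "alimentary_transit_rate_per_d", "radium_transfers",
                "radon_escape_per_d")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) stop("biokinetic parameter file lacks section(s): ",
                            paste(missing, collapse = ", "))
  ages <- as.numeric(cfg$reference_ages)
  fA <- setNames(as.numeric(unlist(cfg$fA[as.character(ages)])), as.character(ages))
  tr <- do.call(rbind, lapply(cfg$radium_transfers, function(x) {
    rates <- x$rate
    data.frame(from = x$from, to = x$to, age = as.numeric(names(rates)),
               rate = as.numeric(unlist(rates)), stringsAsFactors = FALSE)
  }))
  esc <- setNames(as.numeric(unlist(cfg$radon_escape_per_d)),
                  names(cfg$radon_escape_per_d))
  new("CompartmentModel",
      name = if (is.null(cfg$name)) "unnamed" else cfg$name,
      compartments = as.character(cfg$compartments),
      sinks = as.character(cfg$sinks),
      referenceAges = ages, fA = fA,
      alimentaryTransit = as.numeric(cfg$alimentary_transit_rate_per_d),
      transfers = tr, radonEscape = esc,
      progenyMode = if (is.null(cfg$progeny_mode)) "independent_kinetics" else cfg$progeny_mode,
      equilibriumCutoffHours = if (is.null(cfg$equilibrium_cutoff_hours)) 1.0
                               else as.numeric(cfg$equilibrium_cutoff_hours))
}

#' @rdname radrecon-generics
#' @export
setMethod("compartments", "CompartmentModel", function(object, ...) object@compartments)

setMethod("show", "CompartmentModel", function(object) {
  cat("CompartmentModel '", object@name, "'\n", sep = "")
  cat("  compartments:", paste(object@compartments, collapse = ", "), "\n")
  cat("  sinks:", paste(object@sinks, collapse = ", "), "\n")
  cat("  reference ages:", paste(object@referenceAges, collapse = ", "),
      "y; fA:", paste(object@fA, collapse = ", "), "\n")
  cat("  progeny mode:", object@progenyMode, "\n")
})

# Radium transfer-rate matrix (from x to, 1/d) at one reference age,
# including the fA-split outflow from the alimentary pool.
.radiumMatrixAtAge <- function(model, refAge) {
  states <- c(model@compartments, model@sinks)
  K <- matrix(0, length(states), length(states), dimnames = list(states, states))
  tr <- model@transfers[model@transfers$age == refAge, , drop = FALSE]
  for (i in seq_len(nrow(tr))) K[tr$from[i], tr$to[i]] <- K[tr$from[i], tr$to[i]] + tr$rate[i]
  fA <- model@fA[[as.character(refAge)]]
  gut <- model@compartments[1]
  K[gut, "blood"] <- K[gut, "blood"] + fA * model@alimentaryTransit
  K[gut, "excreta"] <- K[gut, "excreta"] + (1 - fA) * model@alimentaryTransit
  K
}

#' Age-interpolated transfer coefficients
#'
#' Linearly interpolates every radium transfer coefficient (and fA) between
#' the bracketing reference ages. Ages at or above the oldest reference age
#' return the adult set unchanged; ages below the youngest are an error.
#'
#' @param model a \linkS4class{CompartmentModel}.
#' @param age_years age at which coefficients are required.
#' @return list with \code{matrix} (from x to rate matrix, 1/d, including
#'   the fA-split alimentary outflows) and \code{fA}.
#' @examples
#' model <- loadBiokineticModel()
#' interpolateParameters(model, 15)$fA  # 0.3
#' interpolateParameters(model, 40)$fA  # 0.2
#' @export
interpolateParameters <- function(model, age_years) {
  ages <- model@referenceAges
  if (age_years < min(ages)) {
    stop("age ", age_years, " is below the youngest reference age (", min(ages), ")")
  }
  if (age_years >= max(ages)) {
    return(list(matrix = .radiumMatrixAtAge(model, max(ages)),
                fA = model@fA[[as.character(max(ages))]]))
  }
  hi <- min(which(ages >= age_years))
  if (ages[hi] == age_years) {
    return(list(matrix = .radiumMatrixAtAge(model, age_years),
                fA = model@fA[[as.character(age_years)]]))
  }
  lo <- hi - 1
  w <- (age_years - ages[lo]) / (ages[hi] - ages[lo])
  Klo <- .radiumMatrixAtAge(model, ages[lo])
  Khi <- .radiumMatrixAtAge(model, ages[hi])
  fAlo <- model@fA[[as.character(ages[lo])]]
  fAhi <- model@fA[[as.character(ages[hi])]]
  list(matrix = (1 - w) * Klo + w * Khi, fA = (1 - w) * fAlo + w * fAhi)
}

#' Build a two-period chronic ingestion schedule
#'
#' The ingestion rate is \code{base_rate} while lip-pointing is practised and
#' \code{post_ratio * base_rate} from the cutoff date to the end of work. A
#' cutoff at or after the work end gives a single high-rate period; a cutoff
#' at or before the work start gives a single reduced-rate period; equal
#' start and end dates give an empty schedule with zero total intake.
#'
#' @param work_start,work_end calendar dates bounding employment.
#' @param cutoff date lip-pointing stopped.
#' @param post_ratio post/pre rate ratio (default 0.01).
#' @param base_rate ingestion rate during lip-pointing (Bq/d; default 1 for
#'   a unit-intake model).
#' @return an \linkS4class{IntakeSchedule}.
#' @examples
#' sch <- buildSchedule("1923-08-01", "1927-08-01", "1927-01-01", 0.01, 1)
#' periods(sch)
#' @export
buildSchedule <- function(work_start, work_end, cutoff, post_ratio = 0.01,
                          base_rate = 1) {
  work_start <- .asDate(work_start); work_end <- .asDate(work_end)
  cutoff <- .asDate(cutoff)
  if (work_end < work_start) stop("work_end precedes work_start")
  if (base_rate < 0 || post_ratio < 0) stop("rates must be non-negative")
  if (work_start == work_end) {
    p <- data.frame(start = as.Date(character()), end = as.Date(character()),
                    rate_Bq_per_d = numeric())
  } else if (cutoff >= work_end) {
    p <- data.frame(start = work_start, end = work_end, rate_Bq_per_d = base_rate)
  } else if (cutoff <= work_start) {
    p <- data.frame(start = work_start, end = work_end,
                    rate_Bq_per_d = base_rate * post_ratio)
  } else {
    p <- data.frame(start = c(work_start, cutoff), end = c(cutoff, work_end),
                    rate_Bq_per_d = c(base_rate, base_rate * post_ratio))
  }
  new("IntakeSchedule", periods = p, cutoff = cutoff, postRatio = post_ratio)
}

#' @rdname radrecon-generics
#' @export
setMethod("periods", "IntakeSchedule", function(object, ...) object@periods)

#' @describeIn radrecon-generics total ingested activity (Bq) of a schedule:
#'   the exact calendar-duration integral of the piecewise-constant rates.
#' @export
setMethod("totalIntake", "IntakeSchedule", function(object, ...) {
  p <- object@periods
  if (nrow(p) == 0) return(0)
  sum(p$rate_Bq_per_d * daysBetween(p$start, p$end))
})

setMethod("show", "IntakeSchedule", function(object) {
  p <- object@periods
  cat("IntakeSchedule with", nrow(p), "period(s); total intake",
      format(totalIntake(object), digits = 6), "Bq\n")
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      cat(sprintf("  %s .. %s at %g Bq/d\n", p$start[i], p$end[i], p$rate_Bq_per_d[i]))
    }
  }
})

# Ingestion rate (Bq/d) at a calendar date (left-closed periods).
.scheduleRateAt <- function(schedule, date) {
  p <- schedule@periods
  if (nrow(p) == 0) return(0)
  for (i in seq_len(nrow(p))) {
    if (date >= p$start[i] && date < p$end[i]) return(p$rate_Bq_per_d[i])
  }
  0
}

# Uniformly rescale the rates of a schedule.
.scaleSchedule <- function(schedule, k) {
  p <- schedule@periods
  if (nrow(p)) p$rate_Bq_per_d <- p$rate_Bq_per_d * k
  new("IntakeSchedule", periods = p, cutoff = schedule@cutoff,
      postRatio = schedule@postRatio)
}

#' Legacy power-law whole-body retention
#'
#' Sum-of-power-terms retention function \eqn{R(t) = \sum_i A_i t^{-b_i}}
#' used only for comparison against historical intake assessments that
#' applied a modified power-law retention model (with the legacy convention
#' that exposure bridging the lip-pointing era is assigned entirely to the
#' earlier period). Coefficients are caller-supplied; the historical
#' publication-specific values are not hard-coded.
#'
#' @param t_since_intake time since intake (days); must be positive when any
#'   exponent is non-zero.
#' @param params data.frame with columns \code{A} and \code{b} (exponents
#'   \code{b >= 0}).
#' @return retained fraction of systemic intake at \code{t_since_intake}.
#' @examples
#' legacyRetention(4, data.frame(A = 1, b = 0.5))  # 0.5
#' @export
legacyRetention <- function(t_since_intake, params) {
  stopifnot(is.data.frame(params), all(c("A", "b") %in% names(params)))
  if (any(params$b < 0)) stop("power-law exponents must be non-negative")
  if (any(params$b > 0) && any(t_since_intake <= 0)) {
    stop("t must be positive for a pure power-law term")
  }
  vapply(t_since_intake, function(t) sum(params$A * t^(-params$b)), numeric(1))
}
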