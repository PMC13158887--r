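#' Linear radioactive decay chain
#'
#' Ordered parent-to-progeny chain of nuclides with half-lives, decay modes
#' and dominant gamma lines. The terminal member may be stable. Historical
#' aliases (e.g. "Radium C" for Bi-214) are carried alongside.
#'
#' @slot nuclides data.frame with columns \code{name}, \code{alias},
#'   \code{half_life_d} (days, \code{Inf} for a stable terminus),
#'   \code{lambda_per_d} (decay constant, 0 for stable) and \code{mode}
#'   (\code{alpha}, \code{beta} or \code{stable}).
#' @slot gammaLines data.frame with columns \code{nuclide},
#'   \code{energy_keV}, \code{yield} (probability per decay).
#' @export
setClass("DecayChain",
  representation(nuclides = "data.frame", gammaLines = "data.frame"),
  validity = function(object) {
    nuc <- object@nuclides
    msg <- character()
    if (nrow(nuc) < 1) msg <- c(msg, "chain must contain at least one nuclide")
    if (anyDuplicated(nuc$name)) {
      msg <- c(msg, paste("duplicate nuclide name:",
                          nuc$name[duplicated(nuc$name)][1]))
    }
    stable <- nuc$mode == "stable"
    if (any(stable & seq_len(nrow(nuc)) < nrow(nuc))) {
      msg <- c(msg, "only the terminal chain member may be stable")
    }
    if (any(!stable & !(nuc$half_life_d > 0))) {
      msg <- c(msg, "half-lives must be positive")
    }
    gl <- object@gammaLines
    if (nrow(gl) > 0) {
      if (any(gl$yield < 0 | gl$yield > 1)) msg <- c(msg, "gamma yields must lie in [0, 1]")
      if (any(gl$energy_keV <= 0)) msg <- c(msg, "gamma energies must be positive")
      if (!all(gl$nuclide %in% nuc$name)) msg <- c(msg, "gamma line for unknown nuclide")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Piecewise-constant chronic ingestion schedule
#'
#' Two-period occupational ingestion history: a high rate while lip-pointing
#' was practised and a reduced rate (\code{postRatio} times the high rate,
#' default 1/100) from the cutoff date to the end of work.
#'
#' @slot periods data.frame with columns \code{start}, \code{end} (Date) and
#'   \code{rate_Bq_per_d}; non-overlapping, chronologically ordered.
#' @slot cutoff Date at which lip-pointing is assumed to stop.
#' @slot postRatio ratio of post- to pre-cutoff ingestion rate.
#' @export
setClass("IntakeSchedule",
  representation(periods = "data.frame", cutoff = "Date", postRatio = "numeric"),
  validity = function(object) {
    p <- object@periods
    msg <- character()
    if (nrow(p) > 0) {
      if (any(p$rate_Bq_per_d < 0)) msg <- c(msg, "ingestion rates must be non-negative")
      if (any(p$end < p$start)) msg <- c(msg, "period end precedes start")
      if (nrow(p) > 1 && any(diff(as.numeric(p$start)) < 0)) {
        msg <- c(msg, "periods must be chronologically ordered")
      }
      if (nrow(p) > 1 && any(as.numeric(p$start[-1]) < as.numeric(p$end[-nrow(p)]))) {
        msg <- c(msg, "periods must not overlap")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' First-order compartmental biokinetic model
#'
#' Compartment structure and age-indexed transfer coefficients for radium,
#' with first-order radon escape to an exhaled-air sink and a rule for the
#' kinetics of progeny born in the body.
#'
#' @slot name model identifier from the parameter file.
#' @slot compartments in-body compartment names (first is the alimentary
#'   contents pool receiving ingested activity).
#' @slot sinks out-of-body accumulators (excreta, exhaled air).
#' @slot referenceAges ages (years) at which coefficient sets are tabulated.
#' @slot fA fractional alimentary absorption per reference age.
#' @slot alimentaryTransit total transit rate out of the alimentary pool (1/d).
#' @slot transfers long-format data.frame \code{from}, \code{to}, \code{age},
#'   \code{rate} (1/d) of radium transfer coefficients.
#' @slot radonEscape named numeric, escape rate (1/d) of radon gas from each
#'   compartment to the exhaled sink.
#' @slot progenyMode \code{"independent_kinetics"} (radon escapes, heavy
#'   progeny decay in place) or \code{"shared_kinetics"} (all progeny follow
#'   the radium coefficients).
#' @slot equilibriumCutoffHours chain members with half-life below this are
#'   reported in secular equilibrium with in-compartment Rn-222.
#' @export
setClass("CompartmentModel",
  representation(name = "character", compartments = "character",
                 sinks = "character", referenceAges = "numeric",
                 fA = "numeric", alimentaryTransit = "numeric",
                 transfers = "data.frame", radonEscape = "numeric",
                 progenyMode = "character", equilibriumCutoffHours = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@fA <= 0 | object@fA >= 1)) msg <- c(msg, "fA must lie in (0, 1)")
    if (is.unsorted(object@referenceAges, strictly = TRUE)) {
      msg <- c(msg, "reference ages must be strictly increasing")
    }
    if (!setequal(names(object@fA), as.character(object@referenceAges))) {
      msg <- c(msg, "fA must be given for every reference age")
    }
    tr <- object@transfers
    if (nrow(tr) > 0) {
      if (any(tr$rate < 0)) msg <- c(msg, "transfer coefficients must be non-negative")
      known <- c(object@compartments, object@sinks)
      if (!all(tr$from %in% object@compartments)) msg <- c(msg, "transfer from unknown compartment")
      if (!all(tr$to %in% known)) msg <- c(msg, "transfer to unknown compartment or sink")
    }
    if (any(object@radonEscape < 0)) msg <- c(msg, "radon escape rates must be non-negative")
    if (!object@progenyMode %in% c("independent_kinetics", "shared_kinetics")) {
      msg <- c(msg, "progenyMode must be independent_kinetics or shared_kinetics")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Time-activity distribution over body compartments
#'
#' Solution of the biokinetic system: per-compartment, per-nuclide activity
#' curves on a time grid in days since birth. Activities are zero before the
#' first intake; sink columns accumulate excreted/exhaled material.
#'
#' @slot timesDays grid in days since birth.
#' @slot birthDate worker's birth date (calendar anchor of the grid).
#' @slot states compartment then sink names (column order of the arrays).
#' @slot nuclides chain member names (slice order of the arrays).
#' @slot activities 3-d array [time, state, nuclide] of activities (Bq).
#' @slot atoms 3-d array [time, state, nuclide] of atom numbers.
#' @slot model the CompartmentModel that produced the solution.
#' @slot schedule the IntakeSchedule driving the solution.
#' @slot chain the DecayChain solved.
#' @export
setClass("TimeActivityDistribution",
  representation(timesDays = "numeric", birthDate = "Date",
                 states = "character", nuclides = "character",
                 activities = "array", atoms = "array",
                 model = "CompartmentModel", schedule = "IntakeSchedule",
                 chain = "DecayChain"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@activities)
    if (!identical(d, c(length(object@timesDays), length(object@states),
                        length(object@nuclides)))) {
      msg <- c(msg, "activity array dimensions inconsistent with grid/states/nuclides")
    }
    if (any(object@activities < -1e-9 * max(abs(object@activities), 1))) {
      msg <- c(msg, "activities must be non-negative")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Scaling-factor intake fit
#'
#' Per-measurement ratios of measured body burden to the unit-intake model
#' burden at the same date, their mean and sample standard deviation, and the
#' implied ingestion rate and total ingestion.
#'
#' @slot factors per-measurement scaling factors, named by measurement date.
#' @slot mean arithmetic (or geometric, if \code{logSpace}) mean factor.
#' @slot sd sample standard deviation of the factors (n-1 denominator;
#'   \code{NA} for a single measurement).
#' @slot unitRate the base ingestion rate (Bq/d) of the unit model.
#' @slot rate implied ingestion rate, \code{mean * unitRate} (Bq/d).
#' @slot totalIngestion integral of the scaled schedule (Bq).
#' @slot schedule the scaled IntakeSchedule.
#' @slot band data.frame \code{time_d}, \code{date}, \code{mean_Bq},
#'   \code{lo_Bq}, \code{hi_Bq}: the scaled body-burden curve with the
#'   multiplicative one-standard-deviation band.
#' @slot logSpace whether factors were averaged in log space.
#' @export
setClass("ScalingFit",
  representation(factors = "numeric", mean = "numeric", sd = "numeric",
                 unitRate = "numeric", rate = "numeric",
                 totalIngestion = "numeric", schedule = "IntakeSchedule",
                 band = "data.frame", logSpace = "logical"),
  validity = function(object) {
    msg <- character()
    if (any(object@factors < 0)) msg <- c(msg, "scaling factors must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' S-coefficient (dose-per-decay) tables
#'
#' Target masses, charged-particle emission energies and absorbed fractions
#' from which source-to-target dose-rate coefficients (Gy/d per Bq) are
#' assembled.
#'
#' @slot name table identifier.
#' @slot targets data.frame \code{target}, \code{mass_kg}.
#' @slot sourceMap named character, model compartment -> source region.
#' @slot emissions data.frame \code{nuclide}, \code{type}, \code{energy_MeV},
#'   \code{yield}.
#' @slot af data.frame \code{source}, \code{target}, \code{af}; pairs absent
#'   from the table contribute no dose by explicit omission.
#' @export
setClass("SCoefficientTable",
  representation(name = "character", targets = "data.frame",
                 sourceMap = "character", emissions = "data.frame",
                 af = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (any(object@targets$mass_kg <= 0)) msg <- c(msg, "target masses must be positive")
    if (nrow(object@af) > 0) {
      if (any(object@af$af < 0)) msg <- c(msg, "absorbed fractions must be non-negative")
      if (!all(object@af$target %in% object@targets$target)) {
        msg <- c(msg, "absorbed fraction for unknown target")
      }
      if (!all(object@af$source %in% object@sourceMap)) {
        msg <- c(msg, "absorbed fraction for source region not mapped from any compartment")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Absorbed dose report
#'
#' Per-target absorbed dose-rate curves and lifetime integrals, with peak
#' rates and their dates. External radiotherapy recorded for a case is
#' carried in \code{metadata} only and never added to the internal doses.
#'
#' @slot targets target tissue names.
#' @slot timesDays time grid (days since birth).
#' @slot birthDate calendar anchor.
#' @slot rates matrix [time, target] of absorbed dose rates (Gy/d).
#' @slot peakRate named numeric, maximum rate per target (Gy/d).
#' @slot peakDate named Date-coded numeric, date of the peak per target.
#' @slot lifetimeGy named numeric, lifetime absorbed dose per target (Gy).
#' @slot metadata free-form list (e.g. radiotherapy notes).
#' @slot legacy optional comparison block against user-supplied legacy values.
#' @export
setClass("DoseReport",
  representation(targets = "character", timesDays = "numeric",
                 birthDate = "Date", rates = "matrix",
                 peakRate = "numeric", peakDate = "Date",
                 lifetimeGy = "numeric", metadata = "list", legacy = "list"),
  validity = function(object) {
    msg <- character()
    if (any(object@lifetimeGy < 0)) msg <- c(msg, "lifetime doses must be non-negative")
    if (!identical(colnames(object@rates), object@targets)) {
      msg <- c(msg, "rate matrix columns must match targets")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic dial-worker case with known ground truth
#'
#' A generated worker: intake history, per-case emanating fraction, a sparse
#' measurement schedule with multiplicative lognormal noise, and a truth
#' record for scoring parameter recovery.
#'
#' @slot seed integer seed the case was generated from.
#' @slot config the generator configuration used.
#' @slot emanatingFraction the case's true emanating fraction.
#' @slot measurements measurement table in the standard CSV schema.
#' @slot truth list: \code{rate_Bq_per_d}, \code{total_ingestion_Bq},
#'   \code{burden_Bq} (data.frame date, burden at the measurement dates).
#' @export
setClass("SyntheticCase",
  representation(seed = "numeric", config = "list",
                 emanatingFraction = "numeric", measurements = "data.frame",
                 truth = "list"),
  validity = function(object) {
    msg <- character()
    if (object@emanatingFraction < 0 || object@emanatingFraction > 1) {
      msg <- c(msg, "emanating fraction must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  }
)
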