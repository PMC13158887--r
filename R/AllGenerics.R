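#' @name radrecon-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 classes.
#' @param object an object of the appropriate class.
#' @param ... passed to methods.
NULL

#' @rdname radrecon-generics
#' @export
setGeneric("nuclides", function(object, ...) standardGeneric("nuclides"))

#' @rdname radrecon-generics
#' @export
setGeneric("gammaLines", function(object, ...) standardGeneric("gammaLines"))

#' @rdname radrecon-generics
#' @export
setGeneric("compartments", function(object, ...) standardGeneric("compartments"))

#' @rdname radrecon-generics
#' @export
setGeneric("periods", function(object, ...) standardGeneric("periods"))

#' @rdname radrecon-generics
#' @export
setGeneric("totalIntake", function(object, ...) standardGeneric("totalIntake"))

#' @rdname radrecon-generics
#' @export
setGeneric("activities", function(object, ...) standardGeneric("activities"))

#' @rdname radrecon-generics
#' @export
setGeneric("scalingFactors", function(object, ...) standardGeneric("scalingFactors"))

#' @rdname radrecon-generics
#' @export
setGeneric("intakeRate", function(object, ...) standardGeneric("intakeRate"))

#' @rdname radrecon-generics
#' @export
setGeneric("totalIngestion", function(object, ...) standardGeneric("totalIngestion"))

#' @rdname radrecon-generics
#' @export
setGeneric("lifetimeDoses", function(object, ...) standardGeneric("lifetimeDoses"))

#' Whole-body radium activity at a time point
#'
#' Sum of Ra-226 activity over all in-body compartments (systemic plus
#' alimentary contents; excreta and exhaled sinks excluded), linearly
#' interpolated on the solution grid. Zero before the first intake.
#'
#' @param tad a \linkS4class{TimeActivityDistribution}.
#' @param t time: days since birth, or a Date/ISO date string.
#' @return activity in Bq (vectorised over \code{t}).
#' @export
setGeneric("bodyBurden", function(tad, t) standardGeneric("bodyBurden"))

#' Instantaneous emanating fraction
#'
#' Rate of Rn-222 atoms exhaled divided by the rate of Rn-222 atoms produced
#' in the body at time \code{t}; lies in [0, 1]. Errors if the production
#' rate is zero.
#'
#' @param tad a \linkS4class{TimeActivityDistribution}.
#' @param chain the \linkS4class{DecayChain} used in the solution.
#' @param t time: days since birth, or a Date/ISO date string.
#' @return dimensionless fraction in [0, 1].
#' @export
setGeneric("emanatingFraction", function(tad, chain, t) standardGeneric("emanatingFraction"))
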