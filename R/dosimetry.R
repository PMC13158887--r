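#' Load dosimetry tables from a YAML file
#'
#' Reads target masses, the compartment-to-source-region map,
#' charged-particle emission energies/yields per nuclide, and absorbed
#' fractions for (source, target) pairs. The bundled default is an
#' illustrative set: bone-surface and bone-volume sources irradiating
#' endosteum and red marrow, and soft-tissue self-irradiation of four soft
#' organs; it is not a transcription of any reference compendium.
#'
#' @param path path to the YAML file; default is the bundled illustrative set.
#' @return a validated \linkS4class{SCoefficientTable}.
#' @export
loadDosimetry <- function(path = system.file("extdata", "dosimetry_default.yaml",
                                             package = "radrecon")) {
  cfg <- yaml::read_yaml(path)
  required <- c("targets", "source_map", "emissions", "absorbed_fractions")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) stop("dosimetry file lacks section(s): ",
                            paste(missing, collapse = ", "))
  targets <- data.frame(target = names(cfg$targets),
                        mass_kg = vapply(cfg$targets, function(x) as.numeric(x$mass_kg), numeric(1)),
                        stringsAsFactors = FALSE)
  srcMap <- vapply(cfg$source_map, as.character, character(1))
  em <- do.call(rbind, lapply(names(cfg$emissions), function(nuc) {
    do.call(rbind, lapply(cfg$emissions[[nuc]], function(e) {
      data.frame(nuclide = nuc, type = e$type, energy_MeV = as.numeric(e$energy_MeV),
                 yield = as.numeric(e$yield), stringsAsFactors = FALSE)
    }))
  }))
  af <- do.call(rbind, lapply(cfg$absorbed_fractions, function(x) {
    data.frame(source = x$source, target = x$target, af = as.numeric(x$af),
               stringsAsFactors = FALSE)
  }))
  new("SCoefficientTable",
      name = if (is.null(cfg$name)) "unnamed" else cfg$name,
      targets = targets, sourceMap = srcMap, emissions = em, af = af)
}

setMethod("show", "SCoefficientTable", function(object) {
  cat("SCoefficientTable '", object@name, "': ", nrow(object@targets),
      " targets, ", nrow(object@af), " (source, target) pairs, ",
      nrow(object@emissions), " emissions\n", sep = "")
})

#' S-coefficient: dose rate per unit source activity
#'
#' Sums over the nuclide's charged-particle emissions: energy times yield
#' times the absorbed fraction for the (source, target) pair, divided by the
#' target mass, converted to Gy/d per Bq. A missing absorbed-fraction entry
#' for the requested pair is an explicit error, never a silent zero; a
#' nuclide with no tabulated emissions contributes zero.
#'
#' @param s_table an \linkS4class{SCoefficientTable}.
#' @param source source region name.
#' @param target target tissue name.
#' @param nuclide nuclide name.
#' @return dose-rate coefficient, Gy/d per Bq of source activity.
#' @examples
#' # single 1-MeV emission, yield 1, AF 1, 1-kg target:
#' # 1.602e-13 J x 86400 s/d = 1.384e-8 Gy/d per Bq
#' @export
sCoefficient <- function(s_table, source, target, nuclide) {
  if (!target %in% s_table@targets$target) stop("unknown target tissue: ", target)
  hit <- s_table@af$source == source & s_table@af$target == target
  if (!any(hit)) {
    stop("no absorbed-fraction entry for source '", source, "' -> target '",
         target, "'; add an explicit entry (possibly 0) to the table")
  }
  af <- s_table@af$af[hit][1]
  em <- s_table@emissions[s_table@emissions$nuclide == nuclide, , drop = FALSE]
  if (nrow(em) == 0) return(0)
  mass <- s_table@targets$mass_kg[s_table@targets$target == target]
  sum(em$energy_MeV * MEV_TO_J * em$yield) * af / mass * SECONDS_PER_DAY
}

#' Absorbed dose-rate curves per target tissue
#'
#' For each target, sums activity times S-coefficient over all mapped source
#' regions and chain nuclides on the solution grid. Linear in activity. A
#' body compartment carrying activity but absent from the source map is an
#' error; sink compartments (excreta, exhaled air) are outside the body and
#' are excluded.
#'
#' @param tad a \linkS4class{TimeActivityDistribution}.
#' @param s_table an \linkS4class{SCoefficientTable}.
#' @param targets target tissues (default: all in the table).
#' @return matrix [time, target] of dose rates (Gy/d), with the grid in
#'   \code{attr(, "timesDays")}.
#' @export
doseRateCurve <- function(tad, s_table, targets = s_table@targets$target) {
  body <- tad@model@compartments
  unmapped <- setdiff(body, names(s_table@sourceMap))
  if (length(unmapped)) {
    act <- max(abs(tad@activities[, unmapped, , drop = FALSE]))
    if (act > 0) {
      stop("compartment '", unmapped[1], "' carries activity but is not mapped to a source region")
    }
  }
  nt <- length(tad@timesDays)
  rates <- matrix(0, nt, length(targets), dimnames = list(NULL, targets))
  for (comp in intersect(body, names(s_table@sourceMap))) {
    src <- s_table@sourceMap[[comp]]
    for (tg in targets) {
      if (!any(s_table@af$source == src & s_table@af$target == tg)) next
      for (nuc in tad@nuclides) {
        s <- sCoefficient(s_table, src, tg, nuc)
        if (s == 0) next
        rates[, tg] <- rates[, tg] + tad@activities[, comp, nuc] * s
      }
    }
  }
  attr(rates, "timesDays") <- tad@timesDays
  rates
}

#' Lifetime absorbed dose from a dose-rate curve
#'
#' Trapezoidal integral of the dose-rate curve over [t_start, t_end] on the
#' solver grid (with interpolated end points).
#'
#' @param rates vector of dose rates (Gy/d) on \code{times}.
#' @param times grid (days).
#' @param t_start,t_end integration bounds (days); \code{t_end} must not
#'   exceed the grid.
#' @return absorbed dose in Gy.
#' @export
lifetimeDose <- function(rates, times, t_start = min(times), t_end = max(times)) {
  if (t_end < t_start) stop("inverted integration bounds")
  if (t_end > max(times) + 1e-9) stop("t_end beyond the curve")
  keep <- times > t_start & times < t_end
  tt <- c(t_start, times[keep], t_end)
  yy <- approx(times, rates, xout = tt, rule = 2)$y
  trapz(tt, yy)
}

#' Assemble a dose report for a time-activity distribution
#'
#' Computes per-target dose-rate curves, their peaks and dates, and lifetime
#' integrals up to \code{t_end} (e.g. death). External radiotherapy recorded
#' for a case is carried in \code{metadata} only, never added to internal
#' doses. An optional legacy comparison block reports user-supplied
#' historical values side by side (with any caveat text preserved).
#'
#' @param tad a \linkS4class{TimeActivityDistribution}.
#' @param s_table an \linkS4class{SCoefficientTable}.
#' @param targets target tissues (default: all in the table).
#' @param t_end end of the lifetime integral (Date or days since birth;
#'   default: end of the solution grid).
#' @param metadata free-form list carried into the report.
#' @param legacy optional list of legacy comparison values.
#' @return a \linkS4class{DoseReport}.
#' @export
doseReport <- function(tad, s_table, targets = s_table@targets$target,
                       t_end = NULL, metadata = list(), legacy = list()) {
  rates <- doseRateCurve(tad, s_table, targets)
  times <- attr(rates, "timesDays")
  tEnd <- if (is.null(t_end)) max(times) else .tToDays(tad, t_end)
  peakI <- apply(rates, 2, which.max)
  peakRate <- rates[cbind(peakI, seq_along(targets))]
  names(peakRate) <- targets
  peakDate <- tad@birthDate + times[peakI]
  names(peakDate) <- targets
  life <- vapply(targets, function(tg) {
    lifetimeDose(rates[, tg], times, min(times), tEnd)
  }, numeric(1))
  new("DoseReport", targets = targets, timesDays = times,
      birthDate = tad@birthDate, rates = unclass(rates[, , drop = FALSE]),
      peakRate = peakRate, peakDate = peakDate, lifetimeGy = life,
      metadata = metadata, legacy = legacy)
}

#' @rdname radrecon-generics
#' @export
setMethod("lifetimeDoses", "DoseReport", function(object, ...) object@lifetimeGy)

setMethod("show", "DoseReport", function(object) {
  cat("DoseReport for", length(object@targets), "target(s)\n")
  ord <- order(object@lifetimeGy, decreasing = TRUE)
  for (i in ord) {
    cat(sprintf("  %-15s lifetime %8.4g Gy; peak %8.4g Gy/d on %s\n",
                object@targets[i], object@lifetimeGy[i], object@peakRate[i],
                format(object@peakDate[i])))
  }
  if (length(object@legacy)) cat("  legacy comparison block attached\n")
})

#' Write a dose report as delimited text plus key/value lines
#'
#' @param report a \linkS4class{DoseReport}.
#' @param path_table path for the per-target CSV (target, peak rate, peak
#'   date, lifetime dose).
#' @param path_summary path for the key/value document (includes any legacy
#'   comparison and metadata notes).
#' @return invisibly, the per-target data.frame.
#' @export
writeDoseReport <- function(report, path_table, path_summary) {
  tab <- data.frame(target = report@targets,
                    peak_rate_Gy_per_d = signif(report@peakRate, 6),
                    peak_date = format(report@peakDate),
                    lifetime_Gy = signif(report@lifetimeGy, 6))
  utils::write.csv(tab, path_table, row.names = FALSE, quote = FALSE)
  kv <- character()
  for (i in seq_along(report@targets)) {
    kv <- c(kv, paste0("lifetime_Gy.", report@targets[i], "\t",
                       signif(report@lifetimeGy[i], 6)))
  }
  for (nm in names(report@legacy)) {
    kv <- c(kv, paste0("legacy.", nm, "\t", report@legacy[[nm]]))
  }
  for (nm in names(report@metadata)) {
    kv <- c(kv, paste0("metadata.", nm, "\t", report@metadata[[nm]]))
  }
  writeLines(kv, path_summary)
  invisible(tab)
}
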