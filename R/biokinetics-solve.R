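# Chain members propagated in the ODE state vs reported in secular
# equilibrium with in-compartment Rn-222. The cutoff keeps sub-hour
# half-lives (rates up to ~4e8/d) out of the matrix exponential; on the
# minutes timescale the equilibrium assumption is exact for the decades-long
# problems solved here.
.trackedMask <- function(chain, cutoff_hours) {
  nuc <- chain@nuclides
  nuc$half_life_d > cutoff_hours / 24 | nuc$mode == "stable"
}

# Transfer-rate matrix (from x to, 1/d) for one tracked nuclide.
# The ingested element (first chain member) follows the age-interpolated
# radium coefficients; Rn-222 follows first-order escape to the exhaled sink
# (independent kinetics) or the radium coefficients (shared); remaining
# progeny decay in place under independent kinetics.
.nuclideMatrix <- function(model, nuclideName, isFirst, radiumK) {
  states <- c(model@compartments, model@sinks)
  if (isFirst) return(radiumK)
  if (model@progenyMode == "shared_kinetics") return(radiumK)
  K <- matrix(0, length(states), length(states), dimnames = list(states, states))
  if (nuclideName == "Rn-222") {
    esc <- model@radonEscape
    for (c in intersect(names(esc), model@compartments)) {
      K[c, "exhaled"] <- esc[[c]]
    }
  }
  K
}

# Generator block for one nuclide: column convention dN/dt = A N.
.generatorBlock <- function(K, lambda) {
  t(K) - diag(rowSums(K), nrow = nrow(K)) - diag(lambda, nrow = nrow(K))
}

#' Solve the biokinetic system for an intake schedule
#'
#' Piecewise solution of the linear first-order compartment system for the
#' ingested nuclide and its tracked progeny. Coefficients (age-interpolated
#' monthly) and the ingestion rate are held constant over sub-intervals no
#' longer than \code{max_step_d} days; each sub-interval is propagated
#' exactly by the matrix exponential of the augmented (affine) system.
#' Radon escape is routed to an exhaled-air sink, so the emanating/retained
#' split is a model output. Chain members with half-life below the model's
#' equilibrium cutoff are reported in secular equilibrium with
#' in-compartment Rn-222.
#'
#' @param model a \linkS4class{CompartmentModel}.
#' @param schedule an \linkS4class{IntakeSchedule}; must lie within
#'   \code{[birth_date, t_end]}.
#' @param chain a \linkS4class{DecayChain}; the first member is the ingested
#'   nuclide.
#' @param birth_date worker's birth date (ages index the coefficients).
#' @param t_end end of the solution (Date, or days since birth).
#' @param max_step_d maximum sub-interval length in days (default 30, the
#'   age-stepping resolution).
#' @return a \linkS4class{TimeActivityDistribution}.
#' @export
solveBiokinetics <- function(model, schedule, chain, birth_date, t_end,
                             max_step_d = 30) {
  birth_date <- .asDate(birth_date)
  tEnd <- if (inherits(t_end, "Date") || is.character(t_end)) {
    daysBetween(birth_date, .asDate(t_end))
  } else as.numeric(t_end)
  if (max_step_d <= 0) stop("max_step_d must be positive")
  p <- schedule@periods
  states <- c(model@compartments, model@sinks)
  nc <- length(states)
  nucAll <- chain@nuclides
  tracked <- .trackedMask(chain, model@equilibriumCutoffHours)
  if (!tracked[1]) stop("the ingested nuclide must be tracked (half-life above the equilibrium cutoff)")
  trNames <- nucAll$name[tracked]
  trLambda <- nucAll$lambda_per_d[tracked]
  nt <- length(trNames)
  n <- nt * nc
  emptyTad <- function(times) {
    nz <- length(times)
    arr <- array(0, dim = c(nz, nc, nrow(nucAll)),
                 dimnames = list(NULL, states, nucAll$name))
    new("TimeActivityDistribution", timesDays = times, birthDate = birth_date,
        states = states, nuclides = nucAll$name, activities = arr, atoms = arr,
        model = model, schedule = schedule, chain = chain)
  }
  if (nrow(p) == 0) return(emptyTad(c(0, tEnd)))
  tStartD <- daysBetween(birth_date, p$start[1])
  if (tStartD < 0) stop("schedule begins before birth")
  if (daysBetween(birth_date, p$end[nrow(p)]) > tEnd + 1e-9) {
    stop("schedule extends beyond t_end")
  }
  # sub-interval edges: period boundaries, then <= max_step_d steps
  edges <- sort(unique(c(
    unlist(lapply(seq_len(nrow(p)), function(i) {
      a <- daysBetween(birth_date, p$start[i]); b <- daysBetween(birth_date, p$end[i])
      seq(a, b, length.out = max(2, ceiling((b - a) / max_step_d) + 1))
    })),
    {
      a <- daysBetween(birth_date, p$end[nrow(p)])
      if (tEnd > a) seq(a, tEnd, length.out = max(2, ceiling((tEnd - a) / max_step_d) + 1)) else numeric()
    }
  )))
  lamFirst <- trLambda[1]
  if (lamFirst <= 0) stop("the ingested nuclide must be radioactive")
  maxAge <- max(model@referenceAges)
  rnIdx <- which(trNames == "Rn-222")
  propCache <- new.env(parent = emptyenv())
  adultK <- NULL
  atoms <- matrix(0, length(edges), n)
  N <- numeric(n)
  for (i in seq_len(length(edges) - 1)) {
    ta <- edges[i]; tb <- edges[i + 1]; h <- tb - ta
    ageMid <- (ta + tb) / 2 / DAYS_PER_YEAR
    dateMid <- birth_date + (ta + tb) / 2
    rate <- .scheduleRateAt(schedule, dateMid)
    adult <- ageMid >= maxAge
    key <- paste(signif(h, 12), signif(rate, 12),
                 if (adult) "adult" else signif(ageMid, 10), sep = "|")
    P <- propCache[[key]]
    if (is.null(P)) {
      if (adult) {
        if (is.null(adultK)) adultK <- interpolateParameters(model, maxAge)$matrix
        radK <- adultK
      } else {
        radK <- interpolateParameters(model, ageMid)$matrix
      }
      if (any(!is.finite(radK))) stop("non-finite transfer coefficients")
      A <- matrix(0, n, n)
      for (k in seq_len(nt)) {
        Kk <- .nuclideMatrix(model, trNames[k], k == 1, radK)
        rows <- ((k - 1) * nc + 1):(k * nc)
        A[rows, rows] <- .generatorBlock(Kk, trLambda[k])
        if (k > 1) {
          prev <- ((k - 2) * nc + 1):((k - 1) * nc)
          A[cbind(rows, prev)] <- A[cbind(rows, prev)] + trLambda[k - 1]
        }
      }
      b <- numeric(n)
      b[1] <- rate / lamFirst  # atoms/d of the ingested nuclide into the alimentary pool
      M <- rbind(cbind(A, b), 0)
      P <- as.matrix(Matrix::expm(Matrix::Matrix(M * h, sparse = FALSE)))
      propCache[[key]] <- P
    }
    y <- P %*% c(N, 1)
    N <- pmax(y[seq_len(n)], 0)
    atoms[i + 1, ] <- N
  }
  times <- edges
  nAll <- nrow(nucAll)
  atomArr <- array(0, dim = c(length(times), nc, nAll),
                   dimnames = list(NULL, states, nucAll$name))
  actArr <- atomArr
  for (k in seq_len(nt)) {
    cols <- ((k - 1) * nc + 1):(k * nc)
    kAll <- which(nucAll$name == trNames[k])
    atomArr[, , kAll] <- atoms[, cols]
    actArr[, , kAll] <- atoms[, cols] * trLambda[k]
  }
  # equilibrium members: activity equal to that of the nearest tracked
  # ancestor (Rn-222 for the radium series)
  for (kAll in which(!tracked)) {
    anc <- max(which(tracked[seq_len(kAll)]))
    lamK <- nucAll$lambda_per_d[kAll]
    actArr[, , kAll] <- actArr[, , anc]
    atomArr[, , kAll] <- actArr[, , kAll] / lamK
  }
  if (tStartD > min(times)) {
    # grid starts at the first intake; activities are zero there by construction
  }
  new("TimeActivityDistribution", timesDays = times, birthDate = birth_date,
      states = states, nuclides = nucAll$name, activities = actArr,
      atoms = atomArr, model = model, schedule = schedule, chain = chain)
}

#' @describeIn radrecon-generics the [time, state, nuclide] activity array of
#'   a TimeActivityDistribution (optionally sliced by nuclide).
#' @param nuclide optional nuclide name to slice.
#' @export
setMethod("activities", "TimeActivityDistribution", function(object, nuclide = NULL, ...) {
  if (is.null(nuclide)) return(object@activities)
  object@activities[, , nuclide]
})

#' Solution time grid
#' @param tad a \linkS4class{TimeActivityDistribution}.
#' @return numeric vector, days since birth.
#' @export
timesDays <- function(tad) tad@timesDays

setMethod("show", "TimeActivityDistribution", function(object) {
  cat("TimeActivityDistribution:", length(object@timesDays), "time points,",
      length(object@states), "states,", length(object@nuclides), "nuclides\n")
  cat("  grid:", format(min(object@timesDays)), "..",
      format(max(object@timesDays)), "days since birth (",
      format(object@birthDate), ")\n")
})

.tToDays <- function(tad, t) {
  if (inherits(t, "Date") || is.character(t)) {
    daysBetween(tad@birthDate, .asDate(t))
  } else as.numeric(t)
}

# Interpolate one [time] vector from the solution grid; zero before the grid
# (pre-intake), error beyond its end.
.gridInterp <- function(tad, y, td) {
  tg <- tad@timesDays
  if (any(td > max(tg) + 1e-9)) stop("t outside the solution grid")
  if (any(td < 0)) stop("t before birth")
  out <- numeric(length(td))
  inside <- td >= min(tg)
  if (any(inside)) out[inside] <- approx(tg, y, xout = td[inside], rule = 2)$y
  out
}

#' @rdname bodyBurden
#' @export
setMethod("bodyBurden", "TimeActivityDistribution", function(tad, t) {
  td <- .tToDays(tad, t)
  first <- tad@nuclides[1]
  body <- tad@model@compartments
  y <- rowSums(tad@activities[, body, first, drop = FALSE][, , 1, drop = FALSE])
  .gridInterp(tad, y, td)
})

#' @rdname emanatingFraction
#' @export
setMethod("emanatingFraction", signature("TimeActivityDistribution", "DecayChain"),
  function(tad, chain, t) {
  td <- .tToDays(tad, t)
  body <- tad@model@compartments
  if (!"Rn-222" %in% tad@nuclides) stop("chain does not track Rn-222")
  esc <- tad@model@radonEscape
  escV <- setNames(numeric(length(body)), body)
  escV[intersect(names(esc), body)] <- esc[intersect(names(esc), body)]
  exhale <- as.vector(tad@atoms[, body, "Rn-222"] %*% escV)
  produce <- rowSums(tad@activities[, body, tad@nuclides[1], drop = FALSE][, , 1, drop = FALSE])
  ex <- .gridInterp(tad, exhale, td)
  pr <- .gridInterp(tad, produce, td)
  if (any(pr <= 0)) stop("zero Rn-222 production rate at the requested time")
  pmin(pmax(ex / pr, 0), 1)
})
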