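#' Construct a linear decay chain
#'
#' Low-level constructor for an arbitrary linear parent-to-progeny chain
#' (used for toy chains in validation as well as the bundled Ra-226 series;
#' use \code{\link{loadChain}} for the bundled series file).
#'
#' @param name character vector of nuclide names, in decay order.
#' @param half_life_d half-lives in days (\code{Inf} for a stable terminus).
#' @param mode decay modes: \code{"alpha"}, \code{"beta"} or \code{"stable"}.
#' @param alias optional historical aliases (e.g. "Radium C").
#' @param gammaLines optional data.frame with columns \code{nuclide},
#'   \code{energy_keV}, \code{yield}.
#' @return a \linkS4class{DecayChain}.
#' @examples
#' toy <- decayChain(c("A", "B", "C"), c(10, 2, Inf),
#'                   c("alpha", "beta", "stable"))
#' chainActivities(toy, c(1, 0, 0), 5)
#' @export
decayChain <- function(name, half_life_d, mode,
                       alias = rep(NA_character_, length(name)),
                       gammaLines = NULL) {
  stopifnot(length(name) == length(half_life_d), length(name) == length(mode))
  mode <- match.arg(mode, c("alpha", "beta", "stable"), several.ok = TRUE)
  lambda <- ifelse(mode == "stable", 0, log(2) / half_life_d)
  nuc <- data.frame(name = as.character(name), alias = as.character(alias),
                    half_life_d = ifelse(mode == "stable", Inf, half_life_d),
                    lambda_per_d = lambda, mode = mode,
                    stringsAsFactors = FALSE)
  if (is.null(gammaLines)) {
    gammaLines <- data.frame(nuclide = character(), energy_keV = numeric(),
                             yield = numeric(), stringsAsFactors = FALSE)
  }
  new("DecayChain", nuclides = nuc, gammaLines = gammaLines)
}

#' Load a decay chain from a delimited table
#'
#' Reads the tab-delimited chain schema: columns \code{name}, \code{alias},
#' \code{half_life_value}, \code{half_life_unit} (y/d/min/s/us), \code{mode}
#' (alpha/beta/stable), then repeated \code{gamma_keV_i} / \code{gamma_yield_i}
#' pairs. Rows are in decay order; an optional \code{parent} column, if
#' present, is checked against the row order and any branching is rejected.
#' The first row must be Ra-226 unless the table is a single terminal row.
#'
#' @param path path to the chain file; default is the bundled Ra-226 series.
#' @return a validated \linkS4class{DecayChain}.
#' @examples
#' chain <- loadChain()
#' nuclides(chain)$name
#' @export
loadChain <- function(path = system.file("extdata", "ra226_chain.tsv",
                                         package = "radrecon")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  required <- c("name", "half_life_value", "half_life_unit", "mode")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("chain table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$name)) {
    stop("duplicate nuclide name in chain table: ", tab$name[duplicated(tab$name)][1])
  }
  if ("parent" %in% names(tab) && nrow(tab) > 1) {
    expected <- c(NA, tab$name[-nrow(tab)])
    bad <- which(!is.na(tab$parent) & tab$parent != expected)
    if (length(bad)) {
      stop("non-linear chain: row ", bad[1], " (", tab$name[bad[1]],
           ") claims parent '", tab$parent[bad[1]], "' but chain order implies '",
           expected[bad[1]], "'")
    }
  }
  if (nrow(tab) > 1 && tab$name[1] != "Ra-226") {
    stop("chain table must start at Ra-226 (got ", tab$name[1], ")")
  }
  hl <- mapply(function(v, u, m) {
    if (m == "stable") return(Inf)
    if (is.na(v) || !nzchar(u)) stop("missing half-life for non-stable nuclide")
    halfLifeToDays(as.numeric(v), u)
  }, tab$half_life_value, tab$half_life_unit, tab$mode)
  ekeys <- grep("^gamma_keV_", names(tab), value = TRUE)
  gl <- do.call(rbind, lapply(ekeys, function(ek) {
    yk <- sub("keV", "yield", ek)
    keep <- !is.na(tab[[ek]])
    data.frame(nuclide = tab$name[keep], energy_keV = tab[[ek]][keep],
               yield = tab[[yk]][keep], stringsAsFactors = FALSE)
  }))
  alias <- if ("alias" %in% names(tab)) tab$alias else rep(NA_character_, nrow(tab))
  alias[!nzchar(trimws(ifelse(is.na(alias), "", alias)))] <- NA_character_
  decayChain(tab$name, hl, tab$mode, alias = alias, gammaLines = gl)
}

#' Resolve a historical nuclide alias
#'
#' Maps classical names ("Radium A".."Radium G") to modern nuclide names;
#' unknown aliases fail loudly.
#'
#' @param chain a \linkS4class{DecayChain}.
#' @param alias historical name to resolve (modern names resolve to themselves).
#' @return the modern nuclide name.
#' @export
resolveAlias <- function(chain, alias) {
  nuc <- chain@nuclides
  if (alias %in% nuc$name) return(alias)
  hit <- which(!is.na(nuc$alias) & nuc$alias == alias)
  if (length(hit) != 1) stop("unknown nuclide alias: '", alias, "'")
  nuc$name[hit]
}

# Perturb near-degenerate decay constants so the Bateman closed form stays
# defined; pairs within 1e-12 relative are separated by a 1e-9 relative nudge.
.adjustLambdas <- function(lambda) {
  for (pass in 1:10) {
    clash <- FALSE
    for (i in seq_along(lambda)) {
      for (j in seq_along(lambda)) {
        if (j <= i) next
        scale <- max(abs(lambda[i]), abs(lambda[j]))
        if (scale == 0) next  # two stable members cannot occur in a valid chain
        if (abs(lambda[i] - lambda[j]) <= 1e-12 * scale) {
          lambda[j] <- if (lambda[j] == 0) 1e-9 * scale else lambda[j] * (1 + 1e-9)
          clash <- TRUE
        }
      }
    }
    if (!clash) break
  }
  lambda
}

# Bateman closed form for atom numbers in a linear chain.
# lambda: decay constants (1/d, 0 allowed for the stable terminus);
# N0: initial atom numbers; t: scalar time (days). Returns atoms at t.
.batemanAtoms <- function(lambda, N0, t) {
  lambda <- .adjustLambdas(lambda)
  n <- length(lambda)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(i)) {
      if (N0[k] == 0) next
      prodlam <- if (k <= i - 1) prod(lambda[k:(i - 1)]) else 1
      if (prodlam == 0) next  # a stable intermediate blocks transport (not valid chains)
      s <- 0
      for (m in k:i) {
        denom <- prod(lambda[setdiff(k:i, m)] - lambda[m])
        s <- s + exp(-lambda[m] * t) / denom
      }
      acc <- acc + N0[k] * prodlam * s
    }
    out[i] <- acc
  }
  out
}

#' Atom numbers along a decay chain at time t
#'
#' Bateman closed-form solution for a linear chain, in atom numbers.
#' Degenerate (near-equal) decay constants are handled by an epsilon
#' perturbation at a documented 1e-12 relative threshold.
#'
#' @param chain a \linkS4class{DecayChain}.
#' @param initialAtoms atom numbers per chain member at t = 0.
#' @param t time in days (scalar, non-negative).
#' @return atom numbers per chain member at time \code{t}.
#' @export
chainAtoms <- function(chain, initialAtoms, t) {
  nuc <- chain@nuclides
  stopifnot(length(initialAtoms) == nrow(nuc))
  if (any(initialAtoms < 0)) stop("initial atom numbers must be non-negative")
  if (t < 0) stop("t must be non-negative")
  setNames(.batemanAtoms(nuc$lambda_per_d, initialAtoms, t), nuc$name)
}

#' Activities along a decay chain at time t
#'
#' Activities of every chain member at time \code{t} from the Bateman linear
#' chain closed form. A stable terminus must carry (and returns) zero
#' activity.
#'
#' @param chain a \linkS4class{DecayChain}.
#' @param initialActivities activities (Bq) per chain member at t = 0.
#' @param t time in days (scalar, non-negative).
#' @return activities (Bq) per chain member at time \code{t}.
#' @examples
#' chain <- loadChain()
#' a0 <- setNames(numeric(10), nuclides(chain)$name)
#' a0["Ra-226"] <- 1
#' chainActivities(chain, a0, 30)  # Rn-222 near secular equilibrium
#' @export
chainActivities <- function(chain, initialActivities, t) {
  nuc <- chain@nuclides
  stopifnot(length(initialActivities) == nrow(nuc))
  if (any(initialActivities < 0)) stop("activities must be non-negative")
  if (t < 0) stop("t must be non-negative")
  lam <- nuc$lambda_per_d
  stable <- lam == 0
  if (any(stable & initialActivities > 0)) {
    stop("a stable nuclide cannot carry activity; use chainAtoms for atom inventories")
  }
  N0 <- ifelse(stable, 0, initialActivities / ifelse(stable, 1, lam))
  N <- .batemanAtoms(lam, N0, t)
  setNames(ifelse(stable, 0, N * lam), nuc$name)
}

#' Photon emission rates from a set of chain activities
#'
#' Per-line emission rate = activity times gamma yield; lines at identical
#' energies are merged. Lines with zero rate are dropped.
#'
#' @param activities named activities (Bq) aligned with the chain order.
#' @param chain a \linkS4class{DecayChain}.
#' @return data.frame \code{energy_keV}, \code{photons_per_s}, sorted by energy.
#' @examples
#' chain <- loadChain()
#' a <- setNames(numeric(10), nuclides(chain)$name)
#' a["Bi-214"] <- 1
#' photonEmissionRate(a, chain)  # 0.4544 photons/s at 609.3 keV
#' @export
photonEmissionRate <- function(activities, chain) {
  nuc <- chain@nuclides
  stopifnot(length(activities) == nrow(nuc))
  gl <- chain@gammaLines
  if (nrow(gl) == 0) {
    return(data.frame(energy_keV = numeric(), photons_per_s = numeric()))
  }
  act <- setNames(as.numeric(activities), nuc$name)
  rate <- act[gl$nuclide] * gl$yield
  agg <- tapply(rate, gl$energy_keV, sum)
  out <- data.frame(energy_keV = as.numeric(names(agg)),
                    photons_per_s = as.numeric(agg))
  out <- out[out$photons_per_s > 0, , drop = FALSE]
  out[order(out$energy_keV), , drop = FALSE]
}

#' @rdname radrecon-generics
#' @export
setMethod("nuclides", "DecayChain", function(object, ...) object@nuclides)

#' @rdname radrecon-generics
#' @export
setMethod("gammaLines", "DecayChain", function(object, ...) object@gammaLines)

setMethod("show", "DecayChain", function(object) {
  nuc <- object@nuclides
  cat("DecayChain with", nrow(nuc), "nuclides:",
      paste(nuc$name, collapse = " -> "), "\n")
  cat(" ", nrow(object@gammaLines), "gamma line(s) tabulated\n")
})
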