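# Shared fixtures: toy chains, harness compartment models, and independent
# numerical oracles (deSolve fine-step integration) used to cross-check the
# closed-form Bateman solution and the matrix-exponential propagation.

# A random linear 3-member chain with moderate decay rates (1/d), kept in a
# range where no member decays below the ODE oracle's attainable accuracy
# over the test horizon.
randomToyChain <- function() {
  lam <- sort(runif(3, 0.05, 1), decreasing = TRUE)
  decayChain(c("X1", "X2", "X3"), log(2) / lam, c("alpha", "beta", "alpha"))
}

# Independent ODE oracle for a linear chain: integrates dN/dt directly with
# deSolve at tight tolerance and returns atom numbers at time t.
odeChainAtoms <- function(chain, N0, t) {
  lam <- nuclides(chain)$lambda_per_d
  rhs <- function(tt, N, p) {
    dN <- -lam * N
    if (length(N) > 1) dN[-1] <- dN[-1] + lam[-length(lam)] * N[-length(N)]
    list(dN)
  }
  out <- deSolve::ode(y = N0, times = c(0, t), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-13, atol = 1e-15 * max(N0, 1))
  unname(out[nrow(out), -1])
}

# Single effectively-stable nuclide ("decay switched off"): half-life 1e9 y.
noDecayChain <- function() decayChain("X1", 1e9 * 365.25, "alpha")

# Minimal harness model: alimentary -> (blood | excreta) split by fA, with a
# single caller-specified loss rate from blood to excreta (0 = absorbing
# blood). Used for mass-balance and steady-state oracles.
harnessModel <- function(fA15 = 0.3, fA25 = 0.2, bloodLoss = 0) {
  tr <- if (bloodLoss > 0) {
    data.frame(from = "blood", to = "excreta", age = c(15, 25),
               rate = bloodLoss, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), age = numeric(),
               rate = numeric(), stringsAsFactors = FALSE)
  }
  new("CompartmentModel", name = "harness",
      compartments = c("alimentary", "blood"), sinks = c("excreta", "exhaled"),
      referenceAges = c(15, 25),
      fA = c("15" = fA15, "25" = fA25), alimentaryTransit = 2.0,
      transfers = tr, radonEscape = c(blood = 0), progenyMode = "independent_kinetics",
      equilibriumCutoffHours = 1.0)
}

# Independent fine-step integration of the full biokinetic system for the
# default model: same piecewise-constant coefficient protocol as the solver,
# but propagated by adaptive ODE integration instead of matrix exponentials.
# Returns atoms [state x tracked nuclide] at the end of the grid.
odeBiokinetics <- function(model, schedule, chain, birth_date, t_end,
                           max_step_d = 30) {
  tad <- solveBiokinetics(model, schedule, chain, birth_date, t_end,
                          max_step_d = max_step_d)
  edges <- timesDays(tad)
  states <- c(model@compartments, model@sinks)
  nc <- length(states)
  nucAll <- nuclides(chain)
  tracked <- nucAll$half_life_d > model@equilibriumCutoffHours / 24 |
    nucAll$mode == "stable"
  trN <- nucAll$name[tracked]
  trL <- nucAll$lambda_per_d[tracked]
  nt <- length(trN)
  maxAge <- max(model@referenceAges)
  N <- numeric(nt * nc)
  birth <- as.Date(birth_date)
  for (i in seq_len(length(edges) - 1)) {
    ta <- edges[i]; tb <- edges[i + 1]
    ageMid <- (ta + tb) / 2 / 365.25
    dateMid <- birth + (ta + tb) / 2
    rate <- radrecon:::.scheduleRateAt(schedule, dateMid)
    radK <- interpolateParameters(model, min(ageMid, maxAge))$matrix
    A <- matrix(0, nt * nc, nt * nc)
    for (k in seq_len(nt)) {
      Kk <- matrix(0, nc, nc, dimnames = list(states, states))
      if (k == 1) {
        Kk <- radK
      } else if (trN[k] == "Rn-222" && model@progenyMode == "independent_kinetics") {
        esc <- model@radonEscape
        for (cc in intersect(names(esc), model@compartments)) {
          Kk[cc, "exhaled"] <- esc[[cc]]
        }
      } else if (model@progenyMode == "shared_kinetics") {
        Kk <- radK
      }
      rows <- ((k - 1) * nc + 1):(k * nc)
      A[rows, rows] <- t(Kk) - diag(rowSums(Kk), nc) - diag(trL[k], nc)
      if (k > 1) {
        prev <- ((k - 2) * nc + 1):((k - 1) * nc)
        A[cbind(rows, prev)] <- A[cbind(rows, prev)] + trL[k - 1]
      }
    }
    b <- numeric(nt * nc)
    b[1] <- rate / trL[1]
    rhs <- function(tt, y, p) list(A %*% y + b)
    out <- deSolve::ode(y = N, times = c(0, tb - ta), func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-10)
    N <- pmax(out[nrow(out), -1], 0)
  }
  matrix(N, nc, nt, dimnames = list(states, trN))
}

# Write a measurement table to a temp CSV and return the path.
writeMeasCSV <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, na = "")
  tmp
}

# Cached case-study objects shared across test files (computed once).
caseUnitTad <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- readRunConfig()
      cache <<- radrecon:::.unitModelFromConfig(cfg)
    }
    cache
  }
})
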