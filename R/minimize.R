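#' @include energy-model.R
NULL

#' Deterministic bounded energy minimization
#'
#' Conjugate-gradient (Polak-Ribiere with restarts) with a backtracking
#' Armijo line search.  Only energy-decreasing steps are accepted, so the
#' energy trace is non-increasing; the run is fully deterministic given
#' identical inputs.
#'
#' @param system a [MolecularSystem-class] with coordinates set.
#' @param params a [ParameterSet-class].
#' @param model an [EnergyModel-class] (biases, flagged atoms, toggles).
#' @param steps maximum number of accepted steps (>= 1).
#' @param gtol gradient infinity-norm convergence tolerance
#'   (kcal/mol/A, default 1e-4).
#' @param ff optional precompiled terms from [compileForceField()].
#' @return A [MinimizationResult-class]; its `system` carries the minimized
#'   coordinates.
#' @export
minimizeSystem <- function(system, params, model = EnergyModel(),
                           steps = 500L, gtol = 1e-4, ff = NULL) {
  if (steps < 1) stop("steps must be >= 1")
  if (is.null(ff)) ff <- compileForceField(system, params)
  x <- coords(system)
  ev <- tryCatch(
    computeEnergyForces(system, params, model, xyz = x, ff = ff),
    error = function(e) {
      if (!length(model@flagged) && grepl("non-finite", conditionMessage(e)))
        stop("non-finite energy at entry with no flagged atoms; ",
             "run a soft-core (flagged) stage first [", conditionMessage(e), "]",
             call. = FALSE)
      stop(e)
    })
  e <- ev$energy
  g <- -ev$forces                       # gradient
  dir <- -g
  trace <- e
  nTaken <- 0L
  reason <- "max-steps"
  alpha <- 0.1
  gPrev <- g

  for (it in seq_len(steps)) {
    gmax <- max(abs(g))
    if (gmax <= gtol) { reason <- "gradient-converged"; break }
    slope <- sum(dir * g)
    if (slope >= 0) {                   # bad direction: restart steepest
      dir <- -g
      slope <- sum(dir * g)
    }
    dmax <- max(abs(dir))
    a <- min(alpha, 0.3 / dmax)         # cap displacement at 0.3 A/step
    accepted <- FALSE
    for (ls in 1:40) {
      xNew <- x + a * dir
      evNew <- tryCatch(
        computeEnergyForces(system, params, model, xyz = xNew, ff = ff),
        error = function(e) NULL)
      if (!is.null(evNew) && is.finite(evNew$energy) &&
          evNew$energy <= e + 1e-4 * a * slope) {
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) { reason <- "stalled"; break }
    x <- xNew
    e <- evNew$energy
    gPrev <- g
    g <- -evNew$forces
    trace <- c(trace, e)
    nTaken <- nTaken + 1L
    alpha <- min(a * 2, 1)              # adapt initial trial step
    ## Polak-Ribiere+ with periodic restart
    if (it %% 25 == 0) {
      dir <- -g
    } else {
      beta <- max(0, sum(g * (g - gPrev)) / max(sum(gPrev * gPrev), 1e-30))
      dir <- -g + beta * dir
    }
  }

  coords(system) <- x
  new("MinimizationResult", system = system, energyTrace = trace,
      steps = nTaken, reason = reason)
}
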