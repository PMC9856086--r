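#' @include AllClasses.R energy-model.R topology-graph.R pierce-oracle.R
NULL

#' Construct an empty BiasState
#' @return A [BiasState-class] with no records.
#' @export
BiasState <- function() {
  new("BiasState", records = list(), prevLongest = integer(0),
      flagged = integer(0))
}

.bondKey <- function(bond) paste(sort(bond), collapse = "-")

#' Perpendicular displacement targets for a long bond
#'
#' Two points in the plane through the bond midpoint normal to the bond
#' vector, each exactly `distance` from the midpoint and opposite one
#' another, so the two bond atoms are pulled apart sideways -- the lateral
#' shear that frees a threaded bond.  The in-plane direction is the only
#' stochastic element of the workflow and is drawn from R's RNG (seed it for
#' reproducible runs).
#'
#' @param bond integer pair of atom indices.
#' @param coordinates natoms x 3 matrix (A).
#' @param distance target distance from the midpoint (A, default 10).
#' @return list with `targetA`, `targetB` (3-vectors) and `midpoint`.
#' @export
perpendicularTarget <- function(bond, coordinates, distance = 10) {
  p <- coordinates[bond[1], ]
  q <- coordinates[bond[2], ]
  v <- q - p
  L <- sqrt(sum(v^2))
  if (L < 1e-6) stop("zero-length bond: perpendicular direction undefined")
  v <- v / L
  mid <- (p + q) / 2
  ## orthonormal basis of the plane normal to v
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .cross3(v, ref)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(v, e1)
  theta <- stats::runif(1, 0, 2 * pi)
  u <- cos(theta) * e1 + sin(theta) * e2
  list(targetA = mid + distance * u, targetB = mid - distance * u,
       midpoint = mid)
}

#' Build the per-iteration biases around the target long bonds
#'
#' For each target bond: two point restraints pulling its atoms toward
#' opposite perpendicular targets; a one-sided separation bias between the
#' bond pair and the nearby ring neighborhood (depth-2 bonded expansion of
#' ring atoms found within `nearbyRadius` of the bond midpoint, minus the
#' bond pair); and a repulsive density hill at the midpoint.  The alchemical
#' flagged set is the bond atoms plus every atom within `nearbyRadius` of a
#' midpoint.  Records carry the current force constants; bonds already
#' recorded keep their (possibly escalated) constants.
#'
#' @param system a [MolecularSystem-class] with coordinates set.
#' @param targetBonds integer matrix, one row per target bond.
#' @param graph igraph bond graph of the system.
#' @param state the current [BiasState-class].
#' @param model an [EnergyModel-class] to receive the bias terms.
#' @param rings list of rings from [enumerateSmallRings()]; recomputed when
#'   `NULL`.
#' @param pointK,sepK,sepTarget,hillHeight,hillRadius,perpDistance,nearbyRadius
#'   bias magnitudes (see [RunConfig-class] for defaults and units).
#' @return list with `model` (biases attached, flagged set installed) and
#'   `state` (updated records and flagged set).
#' @export
buildBiases <- function(system, targetBonds, graph, state, model,
                        rings = NULL,
                        pointK = 10, sepK = 10, sepTarget = 10,
                        hillHeight = 20, hillRadius = 4,
                        perpDistance = 10, nearbyRadius = 4) {
  stopifnot(nrow(targetBonds) >= 1)
  if (is.null(rings)) rings <- enumerateSmallRings(graph)
  xyz <- coords(system)
  flagged <- integer(0)
  keep <- character(0)
  for (r in seq_len(nrow(targetBonds))) {
    bond <- c(targetBonds[r, 1], targetBonds[r, 2])
    key <- .bondKey(bond)
    keep <- c(keep, key)
    rec <- state@records[[key]]
    if (is.null(rec))
      rec <- list(bond = bond, pointK = pointK, sepK = sepK,
                  hillHeight = hillHeight, count = 1L)
    state@records[[key]] <- rec

    tg <- perpendicularTarget(bond, xyz, distance = perpDistance)
    ## both atoms share one lateral target: the bond is sheared sideways out
    ## of the ring face rather than elongated symmetrically in place
    model <- addPointRestraint(model, bond[1], tg$targetA, rec$pointK)
    model <- addPointRestraint(model, bond[2], tg$targetA, rec$pointK)

    near <- atomsWithin(system, tg$midpoint, nearbyRadius)
    ringAtoms <- unique(unlist(rings[vapply(rings, function(rg)
      any(rg %in% near), TRUE)]))
    if (length(ringAtoms)) {
      hood <- bondedNeighborhood(graph, ringAtoms, 2L)
      groupB <- setdiff(hood, bond)
      if (length(groupB))
        model <- addSeparationBias(model, bond, groupB,
                                   target = sepTarget, k = rec$sepK)
    }
    model <- addDensityHill(model, tg$midpoint, radius = hillRadius,
                            height = rec$hillHeight, exempt = bond)
    flagged <- union(flagged, union(bond, near))
  }
  ## drop records for bonds no longer targeted
  state@records <- state@records[names(state@records) %in% keep]
  state@flagged <- sort(as.integer(flagged))
  model@flagged <- state@flagged
  validObject(state)
  list(model = model, state = state)
}

#' Escalate bias force constants for a persistent longest bond
#'
#' If the current longest bond equals the previous iteration's, every force
#' constant in its record (point pulls, separation bias, hill height) is
#' doubled and its consecutive-longest counter incremented.  Records of
#' bonds that are no longer targeted are dropped by [buildBiases()]; the
#' counter keys on bond identity, so a bond that re-emerges as longest after
#' an unperturbed round resumes its escalated constants.
#'
#' @param state a [BiasState-class].
#' @param currentLongest integer pair: this iteration's longest bond.
#' @return The updated state (with `prevLongest` set to `currentLongest`).
#' @export
escalateBiases <- function(state, currentLongest) {
  key <- .bondKey(currentLongest)
  if (length(state@prevLongest) &&
      .bondKey(state@prevLongest) == key &&
      !is.null(state@records[[key]])) {
    rec <- state@records[[key]]
    rec$pointK <- rec$pointK * 2
    rec$sepK <- rec$sepK * 2
    rec$hillHeight <- rec$hillHeight * 2
    rec$count <- rec$count + 1L
    state@records[[key]] <- rec
  }
  state@prevLongest <- as.integer(currentLongest)
  state
}

#' Remove all bias terms from a model
#'
#' Point restraints, separation biases and hills are removed and the
#' alchemical flagged set emptied; chirality restraints are retained (they
#' certify the final structure too).  Idempotent.
#'
#' @param model an [EnergyModel-class].
#' @param state a [BiasState-class].
#' @return list with the cleared `model` and `state`.
#' @export
clearBiases <- function(model, state) {
  model@pointRestraints <- model@pointRestraints[0, , drop = FALSE]
  model@sepBiases <- list()
  model@hills <- list()
  model@flagged <- integer(0)
  state@flagged <- integer(0)
  list(model = model, state = state)
}
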