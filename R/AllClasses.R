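#' @import methods
NULL

#' MolecularSystem: atoms, bonded topology and coordinates
#'
#' In-memory representation of a CHARMM-style molecular system: one row of
#' atom metadata per atom, bonded topology as index tuples, and Cartesian
#' coordinates in Angstrom.  Atom indices are 1-based everywhere in R;
#' file formats keep their native serials.
#'
#' @slot atoms data.frame with columns `name`, `resname`, `resid`, `segid`,
#'   `type` (CHARMM atom type string), `charge` (e), `mass` (amu).
#' @slot bonds integer matrix, one row per bond (2 columns).
#' @slot angles integer matrix (3 columns).
#' @slot dihedrals integer matrix (4 columns).
#' @slot impropers integer matrix (4 columns).
#' @slot coords numeric matrix natoms x 3 in Angstrom, or 0 x 3 when unset.
#'
#' @export
setClass("MolecularSystem",
  representation(
    atoms     = "data.frame",
    bonds     = "matrix",
    angles    = "matrix",
    dihedrals = "matrix",
    impropers = "matrix",
    coords    = "matrix"
  )
)

.emptyTuple <- function(k) matrix(integer(0), ncol = k)

.validMolecularSystem <- function(object) {
  msg <- character(0)
  n <- nrow(object@atoms)
  if (n < 1L) msg <- c(msg, "system must contain at least one atom")
  need <- c("name", "resname", "resid", "segid", "type", "charge", "mass")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    msg <- c(msg, paste0("atoms table missing column(s): ",
                         paste(miss, collapse = ", ")))
  chk <- function(m, k, what) {
    out <- character(0)
    if (ncol(m) != k)
      out <- c(out, sprintf("%s must have %d columns", what, k))
    else if (nrow(m) && (min(m) < 1L || max(m) > n))
      out <- c(out, sprintf("%s reference atom indices outside 1..%d", what, n))
    out
  }
  msg <- c(msg, chk(object@bonds, 2L, "bonds"),
                chk(object@angles, 3L, "angles"),
                chk(object@dihedrals, 4L, "dihedrals"),
                chk(object@impropers, 4L, "impropers"))
  if (nrow(object@bonds)) {
    key <- paste(pmin(object@bonds[, 1], object@bonds[, 2]),
                 pmax(object@bonds[, 1], object@bonds[, 2]))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate bonds (unordered pairs must be unique)")
    if (any(object@bonds[, 1] == object@bonds[, 2]))
      msg <- c(msg, "self-bond (both indices equal)")
  }
  if (ncol(object@coords) != 3L) {
    msg <- c(msg, "coords must have 3 columns")
  } else if (nrow(object@coords)) {
    if (nrow(object@coords) != n)
      msg <- c(msg, "coords row count must equal atom count (or 0 when unset)")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coords must be finite")
  }
  if (length(msg)) msg else TRUE
}
setValidity("MolecularSystem", .validMolecularSystem)

#' Construct a MolecularSystem
#'
#' @param atoms data.frame of atom metadata (see [MolecularSystem-class]).
#' @param bonds,angles,dihedrals,impropers integer matrices of atom-index
#'   tuples (2, 3, 4, 4 columns); may have zero rows.
#' @param coords numeric natoms x 3 matrix in Angstrom, or `NULL` if unset.
#' @return A validated [MolecularSystem-class] object.
#' @export
MolecularSystem <- function(atoms, bonds = .emptyTuple(2), angles = .emptyTuple(3),
                            dihedrals = .emptyTuple(4), impropers = .emptyTuple(4),
                            coords = NULL) {
  toMat <- function(x, k) {
    m <- matrix(as.integer(x), ncol = k)
    dimnames(m) <- NULL
    m
  }
  if (is.null(coords)) coords <- matrix(numeric(0), ncol = 3)
  coords <- matrix(as.numeric(coords), ncol = 3)
  atoms$resid <- as.integer(atoms$resid)
  for (col in c("name", "resname", "segid", "type"))
    atoms[[col]] <- as.character(atoms[[col]])
  atoms$charge <- as.numeric(atoms$charge)
  atoms$mass <- as.numeric(atoms$mass)
  rownames(atoms) <- NULL
  new("MolecularSystem", atoms = atoms,
      bonds = toMat(bonds, 2), angles = toMat(angles, 3),
      dihedrals = toMat(dihedrals, 4), impropers = toMat(impropers, 4),
      coords = coords)
}

#' ParameterSet: CHARMM force-field parameter tables
#'
#' Bond, angle, dihedral, improper and nonbonded parameter tables keyed by
#' atom-type tuples.  Lookups are invariant under tuple reversal; dihedral
#' lookups fall back to wildcard (`X`) outer types.
#'
#' @slot bonds data.frame `t1,t2,k,b0` (kcal/mol/A^2, A).
#' @slot angles data.frame `t1,t2,t3,k,theta0` (kcal/mol/rad^2, degrees).
#' @slot dihedrals data.frame `t1..t4,k,n,delta` (kcal/mol, multiplicity,
#'   degrees).
#' @slot impropers data.frame `t1..t4,k,phi0` (kcal/mol/rad^2, degrees).
#' @slot nonbonded data.frame `type,eps,rmin2` (kcal/mol, A).
#' @export
setClass("ParameterSet",
  representation(
    bonds     = "data.frame",
    angles    = "data.frame",
    dihedrals = "data.frame",
    impropers = "data.frame",
    nonbonded = "data.frame"
  )
)

.validParameterSet <- function(object) {
  msg <- character(0)
  if (nrow(object@bonds) && any(object@bonds$b0 <= 0))
    msg <- c(msg, "all equilibrium bond lengths b0 must be > 0")
  if (nrow(object@nonbonded) && anyDuplicated(object@nonbonded$type))
    msg <- c(msg, "duplicate nonbonded type entries")
  if (length(msg)) msg else TRUE
}
setValidity("ParameterSet", .validParameterSet)

#' RunConfig: workflow run configuration
#'
#' Input paths plus every tunable of the repair loop, with the defaults the
#' workflow uses when a key is absent from the configuration file.
#'
#' @slot structure path to the PSF topology.
#' @slot coordinates path to the PDB coordinates.
#' @slot parameters character vector of CHARMM parameter/stream file paths.
#' @slot cutoff convergence threshold on bond deviation (A, default 0.4).
#' @slot window worst-bond selection window (A, default 0.1).
#' @slot maxStages stage cap for the loop (default 100).
#' @slot stepsPerStage minimizer steps per stage (default 500).
#' @slot dielectric relative dielectric for Coulomb terms (default 80).
#' @slot nbCutoff nonbonded cutoff (A, default 12).
#' @slot switchOn switching-function onset (A, default 10).
#' @slot chirality generate and keep chirality restraints (default TRUE).
#' @slot writeIntermediates write per-stage coordinate snapshots.
#' @slot seed integer random seed for the perpendicular-target direction.
#' @slot pointK perpendicular point-restraint force constant
#'   (kcal/mol/A^2, default 10).
#' @slot sepK separation-bias force constant (kcal/mol/A^2, default 10).
#' @slot sepTarget separation-bias target distance (A, default 10).
#' @slot hillHeight repulsive density-hill height (kcal/mol, default 20).
#' @slot hillRadius density-hill radius (A, default 4).
#' @slot chiralityK chirality improper force constant
#'   (kcal/mol/rad^2, default 50).
#' @slot softcoreDelta soft-core shift (A, default 2.5).
#' @slot perpDistance perpendicular-target distance from the bond midpoint
#'   (A, default 10).
#' @slot nearbyRadius radius defining "nearby atoms" around a long-bond
#'   midpoint (A, default 4).
#' @slot legacyAbsoluteCutoff use the historic fixed 1.65 A long-bond rule
#'   instead of the parameter-aware deviation cutoff (default FALSE).
#' @slot label run label used to derive output file names.
#' @slot outdir output directory.
#' @export
setClass("RunConfig",
  representation(
    structure = "character", coordinates = "character",
    parameters = "character",
    cutoff = "numeric", window = "numeric",
    maxStages = "integer", stepsPerStage = "integer",
    dielectric = "numeric", nbCutoff = "numeric", switchOn = "numeric",
    chirality = "logical", writeIntermediates = "logical",
    seed = "integer",
    pointK = "numeric", sepK = "numeric", sepTarget = "numeric",
    hillHeight = "numeric", hillRadius = "numeric",
    chiralityK = "numeric", softcoreDelta = "numeric",
    perpDistance = "numeric", nearbyRadius = "numeric",
    legacyAbsoluteCutoff = "logical",
    label = "character", outdir = "character"
  )
)

.validRunConfig <- function(object) {
  msg <- character(0)
  if (object@cutoff <= 0) msg <- c(msg, "cutoff must be > 0")
  if (object@window < 0) msg <- c(msg, "window must be >= 0")
  if (object@maxStages < 1L) msg <- c(msg, "maxStages must be >= 1")
  if (object@stepsPerStage < 1L) msg <- c(msg, "stepsPerStage must be >= 1")
  if (object@dielectric < 1) msg <- c(msg, "dielectric must be >= 1")
  if (object@nbCutoff <= object@switchOn)
    msg <- c(msg, "nbCutoff must exceed switchOn")
  if (length(msg)) msg else TRUE
}
setValidity("RunConfig", .validRunConfig)

#' StretchReport: per-bond deviation from equilibrium length
#'
#' @slot table data.frame with one row per bond: `ai`, `aj` (atom indices),
#'   `ti`, `tj` (atom types), `length` (A), `b0` (A), `deviation`
#'   (length - b0, A; negative for compressed bonds).
#' @slot natoms number of atoms in the measured system.
#' @slot cutoff flagging cutoff used (A); `NA` before flagging.
#' @slot window target-selection window used (A); `NA` before selection.
#' @slot flagged integer row indices with deviation >= cutoff.
#' @slot targets integer row indices of target bonds (within `window` of the
#'   maximum deviation, when the maximum is flagged).
#' @export
setClass("StretchReport",
  representation(
    table = "data.frame", natoms = "integer",
    cutoff = "numeric", window = "numeric",
    flagged = "integer", targets = "integer"
  )
)

.validStretchReport <- function(object) {
  msg <- character(0)
  tb <- object@table
  need <- c("ai", "aj", "ti", "tj", "length", "b0", "deviation")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "report table missing required columns")
  else if (nrow(tb) && max(abs(tb$deviation - (tb$length - tb$b0))) > 1e-9)
    msg <- c(msg, "deviation must equal length - b0")
  if (length(object@flagged) && nrow(tb) &&
      !all(object@flagged %in% seq_len(nrow(tb))))
    msg <- c(msg, "flagged rows out of range")
  if (length(object@targets) && !all(object@targets %in% object@flagged))
    msg <- c(msg, "target bonds must be a subset of flagged bonds")
  if (length(msg)) msg else TRUE
}
setValidity("StretchReport", .validStretchReport)

#' EnergyModel: classical energy terms plus repair biases
#'
#' Describes which energy terms are active, the nonbonded treatment
#' (dielectric, cutoff/switching, soft-core shift for alchemically flagged
#' atoms) and all extra restraint terms: harmonic point pulls, one-sided
#' center-of-mass separation biases, repulsive Gaussian density hills and
#' chirality improper restraints.
#'
#' @slot terms named logical vector: `bonds`, `angles`, `dihedrals`,
#'   `impropers`, `lj`, `coulomb`.
#' @slot dielectric relative dielectric constant.
#' @slot nbCutoff nonbonded cutoff (A).
#' @slot switchOn switching onset (A).
#' @slot softcoreDelta soft-core shift delta (A) for flagged pairs.
#' @slot flagged integer indices of alchemically flagged atoms.
#' @slot pointRestraints data.frame `id, atom, x, y, z, k`.
#' @slot sepBiases list of `list(id, groupA, groupB, target, k)`.
#' @slot hills list of `list(id, center, radius, height, exempt)`.
#' @slot chiralRestraints data.frame `a, b, c, d, k, phi0` (phi0 in radians).
#' @slot nextId integer id counter for removable restraints.
#' @export
setClass("EnergyModel",
  representation(
    terms = "logical", dielectric = "numeric",
    nbCutoff = "numeric", switchOn = "numeric", softcoreDelta = "numeric",
    flagged = "integer",
    pointRestraints = "data.frame",
    sepBiases = "list", hills = "list",
    chiralRestraints = "data.frame",
    nextId = "integer"
  )
)

.validEnergyModel <- function(object) {
  msg <- character(0)
  need <- c("bonds", "angles", "dihedrals", "impropers", "lj", "coulomb")
  if (!all(need %in% names(object@terms)))
    msg <- c(msg, "terms must name bonds/angles/dihedrals/impropers/lj/coulomb")
  if (object@softcoreDelta < 0) msg <- c(msg, "softcoreDelta must be >= 0")
  if (nrow(object@pointRestraints) && any(object@pointRestraints$k <= 0))
    msg <- c(msg, "point restraint force constants must be > 0")
  if (length(msg)) msg else TRUE
}
setValidity("EnergyModel", .validEnergyModel)

#' MinimizationResult: outcome of one bounded minimization
#'
#' @slot system the input [MolecularSystem-class] with minimized coordinates.
#' @slot energyTrace energy (kcal/mol) after each accepted step, element 1
#'   being the starting energy.
#' @slot steps number of accepted steps taken.
#' @slot reason one of `"max-steps"`, `"gradient-converged"`, `"stalled"`.
#' @export
setClass("MinimizationResult",
  representation(system = "MolecularSystem", energyTrace = "numeric",
                 steps = "integer", reason = "character")
)

#' BiasState: per-target-bond bias bookkeeping
#'
#' Tracks, for every currently targeted long bond, the force constants of
#' its biases and how many consecutive workflow iterations it has remained
#' the longest bond (force constants double on each repeat).
#'
#' @slot records named list keyed `"i-j"`; each element is
#'   `list(bond, pointK, sepK, hillHeight, count)`.
#' @slot prevLongest integer(2) atom pair of the previous iteration's
#'   longest bond, or integer(0).
#' @slot flagged integer indices of the currently flagged (soft-core) atoms.
#' @export
setClass("BiasState",
  representation(records = "list", prevLongest = "integer",
                 flagged = "integer")
)

.validBiasState <- function(object) {
  msg <- character(0)
  for (rec in object@records) {
    if (rec$pointK <= 0 || rec$sepK <= 0 || rec$hillHeight <= 0)
      msg <- c(msg, "bias force constants must be strictly positive")
    if (rec$count < 1L) msg <- c(msg, "record counter must be >= 1")
    if (!all(rec$bond %in% object@flagged) && length(object@flagged))
      msg <- c(msg, "flagged set must contain both atoms of every target bond")
  }
  if (length(msg)) unique(msg) else TRUE
}
setValidity("BiasState", .validBiasState)

#' WorkflowState: progress of the iterative repair loop
#'
#' @slot stage stages completed so far.
#' @slot prevPerturbed whether the last minimization carried bias terms
#'   (soft-core / pulls / hills).
#' @slot trace data.frame `stage, ai, aj, deviation, perturbed, branch`
#'   (stage 0 is the unminimized input).
#' @slot bias the current [BiasState-class].
#' @slot converged whether the loop terminated via the unperturbed check.
#' @slot status `"converged"`, `"stage-cap"` or `"running"`.
#' @slot intermediates list of per-stage coordinate matrices (optional).
#' @export
setClass("WorkflowState",
  representation(stage = "integer", prevPerturbed = "logical",
                 trace = "data.frame", bias = "BiasState",
                 converged = "logical", status = "character",
                 intermediates = "list")
)

#' FixtureBundle: a generated test system plus its manifest
#'
#' @slot system [MolecularSystem-class] as built.
#' @slot params [ParameterSet-class] resolving every lookup in the system.
#' @slot manifest list with `piercings` (intended piercing count),
#'   `chiralCenters` (detected stereocenter count) and `notes`.
#' @export
setClass("FixtureBundle",
  representation(system = "MolecularSystem", params = "ParameterSet",
                 manifest = "list")
)
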