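#' @include AllClasses.R charmm-prm.R
#' @useDynLib ringfree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct an EnergyModel
#'
#' @param dielectric relative dielectric (default 80, emulating an aqueous
#'   environment for unsolvated runs).
#' @param nbCutoff nonbonded cutoff (A, default 12).
#' @param switchOn switching onset (A, default 10).
#' @param softcoreDelta soft-core shift (A, default 2.5); pairs with at least
#'   one flagged atom interact at the effective distance
#'   `sqrt(r^2 + delta^2)`, so their energy stays finite down to r = 0.
#' @param terms named logical vector toggling bonds, angles, dihedrals,
#'   impropers, lj, coulomb (all on by default).
#' @param flagged integer indices of alchemically flagged (softened) atoms.
#' @return An [EnergyModel-class].
#' @export
EnergyModel <- function(dielectric = 80, nbCutoff = 12, switchOn = 10,
                        softcoreDelta = 2.5,
                        terms = c(bonds = TRUE, angles = TRUE,
                                  dihedrals = TRUE, impropers = TRUE,
                                  lj = TRUE, coulomb = TRUE),
                        flagged = integer(0)) {
  new("EnergyModel", terms = terms, dielectric = dielectric,
      nbCutoff = nbCutoff, switchOn = switchOn,
      softcoreDelta = softcoreDelta, flagged = as.integer(flagged),
      pointRestraints = data.frame(id = integer(0), atom = integer(0),
                                   x = numeric(0), y = numeric(0),
                                   z = numeric(0), k = numeric(0)),
      sepBiases = list(), hills = list(),
      chiralRestraints = data.frame(a = integer(0), b = integer(0),
                                    c = integer(0), d = integer(0),
                                    k = numeric(0), phi0 = numeric(0)),
      nextId = 1L)
}

#' Add a harmonic point restraint
#'
#' Adds `1/2 k |r_atom - target|^2` to the energy; removable by id.
#'
#' @param model an [EnergyModel-class].
#' @param atom atom index.
#' @param target numeric 3-vector (A).
#' @param k force constant (kcal/mol/A^2, > 0).
#' @return The updated model; the id assigned is in `attr(, "id")`.
#' @export
addPointRestraint <- function(model, atom, target, k) {
  stopifnot(k > 0, length(target) == 3)
  id <- model@nextId
  model@pointRestraints <- rbind(model@pointRestraints,
    data.frame(id = id, atom = as.integer(atom), x = target[1],
               y = target[2], z = target[3], k = k))
  model@nextId <- id + 1L
  attr(model, "id") <- id
  model
}

#' Add a one-sided center-of-mass separation bias
#'
#' Harmonic `1/2 k (d - target)^2` on the mass-weighted center separation
#' `d`, active only while `d < target` ("up to" the target -- no pull
#' beyond it).
#'
#' @param model an [EnergyModel-class].
#' @param groupA,groupB disjoint, non-empty integer atom index sets.
#' @param target target separation (A, default 10).
#' @param k force constant (kcal/mol/A^2, > 0).
#' @return The updated model; assigned id in `attr(, "id")`.
#' @export
addSeparationBias <- function(model, groupA, groupB, target = 10, k) {
  stopifnot(k > 0, length(groupA) > 0, length(groupB) > 0)
  if (length(intersect(groupA, groupB)))
    stop("separation bias groups must be disjoint")
  id <- model@nextId
  model@sepBiases <- c(model@sepBiases,
    list(list(id = id, groupA = as.integer(groupA),
              groupB = as.integer(groupB), target = target, k = k)))
  model@nextId <- id + 1L
  attr(model, "id") <- id
  model
}

#' Add a repulsive Gaussian density hill
#'
#' Adds `height * exp(-|r - center|^2 / (2 (radius/2)^2))` per non-exempt
#' atom: a smooth repulsive density that pushes surrounding atoms out of the
#' tangled region.
#'
#' @param model an [EnergyModel-class].
#' @param center numeric 3-vector (A).
#' @param radius hill radius (A, > 0); the Gaussian sigma is `radius/2`.
#' @param height peak height (kcal/mol, > 0).
#' @param exempt integer atom indices that do not feel the hill.
#' @return The updated model; assigned id in `attr(, "id")`.
#' @export
addDensityHill <- function(model, center, radius, height, exempt = integer(0)) {
  stopifnot(radius > 0, height > 0, length(center) == 3)
  id <- model@nextId
  model@hills <- c(model@hills,
    list(list(id = id, center = as.numeric(center), radius = radius,
              height = height, exempt = as.integer(exempt))))
  model@nextId <- id + 1L
  attr(model, "id") <- id
  model
}

#' Remove a restraint or bias by id
#'
#' @param model an [EnergyModel-class].
#' @param id id returned at addition time.
#' @return The updated model.
#' @export
removeBias <- function(model, id) {
  model@pointRestraints <-
    model@pointRestraints[model@pointRestraints$id != id, , drop = FALSE]
  model@sepBiases <- Filter(function(b) b$id != id, model@sepBiases)
  model@hills <- Filter(function(h) h$id != id, model@hills)
  model
}

#' Set the chirality restraints of a model
#'
#' @param model an [EnergyModel-class].
#' @param restraints data.frame from [generateChiralityRestraints()].
#' @return The updated model.
#' @export
setChiralRestraints <- function(model, restraints) {
  model@chiralRestraints <- restraints
  model
}

#' Precompile force-field terms for a system
#'
#' Resolves every bonded term and per-atom nonbonded parameter once, so the
#' minimizer does not repeat table lookups at every energy evaluation.
#' Dihedral entries are expanded per multiplicity term; 1-2 and 1-3 pairs
#' are collected as nonbonded exclusions (1-4 pairs interact at full
#' strength).
#'
#' @param system a [MolecularSystem-class].
#' @param params a [ParameterSet-class] total over the system.
#' @return An opaque list consumed by [computeEnergyForces()] and
#'   [minimizeSystem()].
#' @export
compileForceField <- function(system, params) {
  ty <- system@atoms$type
  b <- system@bonds
  bk <- numeric(nrow(b)); bb0 <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    p <- bondParam(params, ty[b[i, 1]], ty[b[i, 2]])
    bk[i] <- p$k; bb0[i] <- p$b0
  }
  a <- system@angles
  ak <- numeric(nrow(a)); ath0 <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    p <- angleParam(params, ty[a[i, 1]], ty[a[i, 2]], ty[a[i, 3]])
    ak[i] <- p$k; ath0[i] <- p$theta0 * pi / 180
  }
  d <- system@dihedrals
  dIdx <- list(); dk <- numeric(0); dn <- integer(0); dd <- numeric(0)
  for (i in seq_len(nrow(d))) {
    p <- dihedralParam(params, ty[d[i, 1]], ty[d[i, 2]], ty[d[i, 3]], ty[d[i, 4]])
    for (t in seq_len(nrow(p))) {
      dIdx[[length(dIdx) + 1L]] <- d[i, ]
      dk <- c(dk, p$k[t]); dn <- c(dn, p$n[t]); dd <- c(dd, p$delta[t] * pi / 180)
    }
  }
  dmat <- if (length(dIdx)) do.call(rbind, dIdx) else .emptyTuple(4)
  im <- system@impropers
  ik <- numeric(nrow(im)); iphi0 <- numeric(nrow(im))
  for (i in seq_len(nrow(im))) {
    p <- improperParam(params, ty[im[i, 1]], ty[im[i, 2]], ty[im[i, 3]], ty[im[i, 4]])
    ik[i] <- p$k; iphi0[i] <- p$phi0 * pi / 180
  }
  nb <- lapply(unique(ty), function(t) nonbondedParam(params, t))
  names(nb) <- unique(ty)
  eps <- vapply(ty, function(t) nb[[t]]$eps, 0)
  rmin2 <- vapply(ty, function(t) nb[[t]]$rmin2, 0)

  ## 1-2 and 1-3 exclusions from the bond adjacency
  n <- natoms(system)
  adj <- vector("list", n)
  for (i in seq_len(nrow(b))) {
    adj[[b[i, 1]]] <- c(adj[[b[i, 1]]], b[i, 2])
    adj[[b[i, 2]]] <- c(adj[[b[i, 2]]], b[i, 1])
  }
  exc <- list(b)
  for (j in seq_len(n)) {
    nbrs <- adj[[j]]
    if (length(nbrs) >= 2) {
      prs <- t(utils::combn(sort(nbrs), 2))
      exc[[length(exc) + 1L]] <- prs
    }
  }
  exc <- do.call(rbind, exc)
  exc <- unique(cbind(pmin(exc[, 1], exc[, 2]), pmax(exc[, 1], exc[, 2])))

  list(bonds = b, bondK = bk, bondB0 = bb0,
       angles = a, angK = ak, angTh0 = ath0,
       dihedrals = dmat, dihK = dk, dihN = dn, dihDelta = dd,
       impropers = im, impK = ik, impPhi0 = iphi0,
       eps = unname(eps), rmin2 = unname(rmin2),
       charge = system@atoms$charge, mass = system@atoms$mass,
       excl = exc, natoms = n)
}

#' Energy and analytic forces of a system under a model
#'
#' Bonded terms (harmonic bonds and angles, cosine dihedrals, harmonic
#' impropers), switched Lennard-Jones and Coulomb with soft-core treatment of
#' flagged pairs, and every restraint attached to the model.  Forces are the
#' exact negative gradient of the implemented energy.
#'
#' @param system a [MolecularSystem-class] with coordinates set.
#' @param params a [ParameterSet-class].
#' @param model an [EnergyModel-class]; its `flagged` slot names the
#'   soft-core atoms.
#' @param xyz optional coordinate matrix overriding the system's.
#' @param ff optional precompiled terms from [compileForceField()].
#' @return list with `energy` (kcal/mol), `forces` (natoms x 3,
#'   kcal/mol/A) and `terms` (named per-term energies).
#' @export
computeEnergyForces <- function(system, params, model = EnergyModel(),
                                xyz = NULL, ff = NULL) {
  if (is.null(ff)) ff <- compileForceField(system, params)
  if (is.null(xyz)) xyz <- coords(system)
  if (!nrow(xyz)) stop("system has no coordinates")
  pr <- model@pointRestraints
  sb <- model@sepBiases
  hl <- model@hills
  cr <- model@chiralRestraints
  .lbeEnergyForces(xyz,
    ff$bonds, ff$bondK, ff$bondB0,
    ff$angles, ff$angK, ff$angTh0,
    ff$dihedrals, ff$dihK, as.integer(ff$dihN), ff$dihDelta,
    ff$impropers, ff$impK, ff$impPhi0,
    ff$eps, ff$rmin2, ff$charge,
    ff$excl, model@flagged,
    model@dielectric, model@nbCutoff, model@switchOn, model@softcoreDelta,
    unname(model@terms[c("bonds", "angles", "dihedrals", "impropers",
                         "lj", "coulomb")]),
    as.integer(pr$atom), cbind(pr$x, pr$y, pr$z), pr$k,
    lapply(sb, `[[`, "groupA"), lapply(sb, `[[`, "groupB"),
    vapply(sb, `[[`, 0, "target"), vapply(sb, `[[`, 0, "k"),
    ff$mass,
    if (length(hl)) do.call(rbind, lapply(hl, `[[`, "center"))
      else matrix(numeric(0), ncol = 3),
    vapply(hl, `[[`, 0, "radius"), vapply(hl, `[[`, 0, "height"),
    lapply(hl, `[[`, "exempt"),
    cbind(cr$a, cr$b, cr$c, cr$d), cr$k, cr$phi0)
}
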