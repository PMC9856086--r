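#' @include AllClasses.R charmm-prm.R charmm-psf.R pdb-io.R pierce-oracle.R run-config.R
NULL

## Minimal self-contained CHARMM-format parameter text used by all shipped
## fixtures: aromatic and aliphatic carbon, ether/ring/hydroxyl oxygen,
## amide-like nitrogen, carbonyl pair, hydrogens, and one deliberately bulky
## LJ type.  Values are chemically reasonable and fixed.
.minimalParamText <- function() c(
  "* minimal fixture parameters",
  "",
  "BONDS",
  "CA   CA   305.000  1.3750",
  "CA   HA   340.000  1.0800",
  "CA   CT   230.000  1.4900",
  "CT   CT   222.500  1.5280",
  "CT   HT   309.000  1.1110",
  "CT   OS   360.000  1.4150",
  "CT   OE   360.000  1.4150",
  "CT   OH1  428.000  1.4200",
  "OH1  HO   545.000  0.9600",
  "CT   NT   320.000  1.4300",
  "NT   HT   440.000  1.0000",
  "CT   C    250.000  1.4900",
  "C    OC   620.000  1.2300",
  "C    NT   370.000  1.3450",
  "CT   XL   200.000  1.8000",
  "",
  "ANGLES",
  "CA   CA   CA    40.00  120.00",
  "CA   CA   HA    30.00  120.00",
  "CA   CA   CT    45.80  122.30",
  "CA   CT   HT    49.30  107.50",
  "CA   CT   CT    51.80  107.50",
  "CT   CT   CT    58.35  113.60",
  "CT   CT   HT    34.60  110.10",
  "HT   CT   HT    35.50  108.40",
  "CT   CT   OS    45.00  111.50",
  "CT   CT   OE    45.00  111.50",
  "CT   OS   CT    95.00  109.70",
  "CT   OE   CT    95.00  109.70",
  "OS   CT   HT    60.00  109.50",
  "OE   CT   HT    60.00  109.50",
  "OS   CT   OE    90.00  111.50",
  "NT   CT   OS    80.00  109.50",
  "CT   CT   OH1   75.70  110.10",
  "OH1  CT   HT    45.90  108.90",
  "CT   OH1  HO    57.50  106.00",
  "OS   CT   OH1   90.00  111.50",
  "CT   CT   NT    67.70  110.00",
  "CT   NT   HT    45.00  113.00",
  "HT   NT   HT    35.00  107.00",
  "NT   CT   HT    51.50  107.50",
  "CT   C    OC    80.00  121.00",
  "CT   C    NT    80.00  116.50",
  "OC   C    NT    80.00  122.50",
  "C    NT   CT    50.00  120.00",
  "C    NT   HT    34.00  123.00",
  "NT   CT   C     50.00  107.00",
  "C    CT   CT    52.00  108.00",
  "C    CT   HT    49.30  107.50",
  "CT   CT   XL    50.00  110.00",
  "CT   NT   CT    50.00  112.00",
  "NT   CT   XL    50.00  110.00",
  "OS   CT   XL    50.00  110.00",
  "CT   XL   CT    50.00  110.00",
  "HT   CT   XL    40.00  109.50",
  "",
  "DIHEDRALS",
  "X    CA   CA   X      3.1000  2   180.00",
  "X    CA   CT   X      0.0000  6     0.00",
  "X    CT   CT   X      0.1900  3     0.00",
  "X    CT   OS   X      0.3000  3     0.00",
  "X    CT   OE   X      0.3000  3     0.00",
  "X    CT   OH1  X      0.1400  3     0.00",
  "X    CT   NT   X      0.2000  3     0.00",
  "X    C    NT   X      2.5000  2   180.00",
  "X    CT   C    X      0.0500  6   180.00",
  "X    CT   XL   X      0.1000  3     0.00",
  "",
  "IMPROPER",
  "C    X    X    OC   100.0000  0     0.00",
  "",
  "NONBONDED",
  "CA    0.0  -0.0700  1.9924",
  "HA    0.0  -0.0300  1.3582",
  "CT    0.0  -0.0780  2.0400",
  "HT    0.0  -0.0240  1.3400",
  "OS    0.0  -0.1000  1.6500",
  "OE    0.0  -0.1000  1.6500",
  "OH1   0.0  -0.1921  1.7650",
  "HO    0.0  -0.0460  0.2245",
  "NT    0.0  -0.2000  1.8500",
  "C     0.0  -0.1100  2.0000",
  "OC    0.0  -0.1200  1.7000",
  "XL    0.0  -0.3000  2.7000",
  "",
  "END")

.typeCharge <- c(CA = -0.115, HA = 0.115, CT = -0.18, HT = 0.09,
                 OS = -0.40, OE = -0.40, OH1 = -0.65, HO = 0.42,
                 NT = -0.47, C = 0.51, OC = -0.51, XL = 0.0)
.typeMass <- c(CA = 12.011, HA = 1.008, CT = 12.011, HT = 1.008,
               OS = 15.999, OE = 15.999, OH1 = 15.999, HO = 1.008,
               NT = 14.007, C = 12.011, OC = 15.999, XL = 40.08)

#' The embedded minimal parameter set of the shipped fixtures
#'
#' The parameter text is written to a file and re-read through the real
#' CHARMM parameter parser, so every fixture exercises the same code path as
#' user-supplied parameter files.
#'
#' @param path optional path to keep the parameter file at (temporary file
#'   by default).
#' @return A [ParameterSet-class].
#' @export
embeddedMinimalParams <- function(path = NULL) {
  if (is.null(path)) path <- tempfile(fileext = ".prm")
  writeLines(.minimalParamText(), path)
  readParameters(path)
}

## angles = all bonded paths i-j-k; dihedrals = all bonded paths i-j-k-l
.autoBondedTerms <- function(bonds, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds[i, 1]]] <- c(adj[[bonds[i, 1]]], bonds[i, 2])
    adj[[bonds[i, 2]]] <- c(adj[[bonds[i, 2]]], bonds[i, 1])
  }
  angles <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      prs <- t(utils::combn(nb, 2))
      angles[[length(angles) + 1L]] <- cbind(prs[, 1], j, prs[, 2])
    }
  }
  angles <- if (length(angles)) do.call(rbind, angles) else .emptyTuple(3)
  dihedrals <- list()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i != l)
        dihedrals[[length(dihedrals) + 1L]] <- c(i, j, k, l)
    }
  }
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals)
    else .emptyTuple(4)
  if (nrow(dihedrals)) {
    key <- apply(dihedrals, 1, function(r) {
      s <- if (r[2] < r[3] || (r[2] == r[3] && r[1] <= r[4])) r else rev(r)
      paste(s, collapse = "-")
    })
    dihedrals <- dihedrals[!duplicated(key), , drop = FALSE]
  }
  list(angles = angles, dihedrals = dihedrals)
}

.mkAtoms <- function(name, type, resname, resid, segid) {
  data.frame(name = name, resname = resname, resid = as.integer(resid),
             segid = segid, type = type,
             charge = unname(.typeCharge[type]),
             mass = unname(.typeMass[type]), stringsAsFactors = FALSE)
}

## orthonormal in-plane basis for a given normal
.planeBasis <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .cross3(normal, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(normal, e1)
  list(e1 = e1, e2 = e2, n = normal)
}

## regular hexagon vertices; phase rotates vertex 1 within the plane; pucker
## alternates +/- along the normal (0 = planar aromatic, ~0.25 = chair)
.hexCoords <- function(center, normal, radius = 1.375, phase = 0, pucker = 0) {
  b <- .planeBasis(normal)
  t(vapply(0:5, function(k) {
    th <- phase + k * pi / 3
    center + radius * (cos(th) * b$e1 + sin(th) * b$e2) +
      pucker * (-1)^k * b$n
  }, numeric(3)))
}

#' Construct and validate a FixtureBundle
#'
#' The manifest is verified at build time: the declared piercing count must
#' equal what [findPiercings()] reports on the as-built coordinates, the
#' declared stereocenter count must equal what [detectChiralCenters()]
#' returns, and the parameter set must be total over the system.
#'
#' @param system a [MolecularSystem-class].
#' @param params a [ParameterSet-class].
#' @param piercings intended piercing count.
#' @param chiralCenters intended detected-stereocenter count.
#' @param notes free-text manifest notes.
#' @return A [FixtureBundle-class].
#' @export
FixtureBundle <- function(system, params, piercings, chiralCenters,
                          notes = "") {
  checkParamsTotal(system, params)
  ev <- findPiercings(system)
  if (nrow(ev) != piercings)
    stop(sprintf(
      "fixture self-check: %d piercing(s) found, manifest says %d [%s]",
      nrow(ev), piercings,
      paste(sprintf("bond %d-%d ring %d", ev$ai, ev$aj, ev$ringIndex),
            collapse = "; ")))
  nc <- nrow(detectChiralCenters(system))
  if (nc != chiralCenters)
    stop(sprintf(
      "fixture self-check: %d chiral center(s) found, manifest says %d",
      nc, chiralCenters))
  new("FixtureBundle", system = system, params = params,
      manifest = list(piercings = as.integer(piercings),
                      chiralCenters = as.integer(chiralCenters),
                      notes = notes))
}

#' Pierced benzene-ethane fixture
#'
#' An aromatic six-ring (6 C + 6 H) centered at the origin in the xy-plane
#' with a two-carbon unit threaded through it along z: the C-C bond midpoint
#' sits at the ring centroid and the C-C length starts well past its
#' equilibrium value.  The canonical single-piercing local minimum.
#'
#' @return A [FixtureBundle-class] (manifest: 1 piercing, 0 chiral centers).
#' @export
makePiercedBenzeneEthane <- function() {
  ringC <- .hexCoords(c(0, 0, 0), c(0, 0, 1), radius = 1.375)
  ringH <- .hexCoords(c(0, 0, 0), c(0, 0, 1), radius = 1.375 + 1.080)
  cc <- 2.2 / 2
  eth <- rbind(c(0, 0, -cc), c(0, 0, cc))
  hz <- 1.111 / 3                   # |cos(109.47 deg)| * bond
  hr <- 1.111 * sqrt(1 - 1 / 9)
  ethH <- rbind(
    t(vapply(c(0, 2, 4) * pi / 3, function(p)
      c(hr * cos(p), hr * sin(p), -cc - hz), numeric(3))),
    t(vapply(c(1, 3, 5) * pi / 3, function(p)
      c(hr * cos(p), hr * sin(p), cc + hz), numeric(3))))

  atoms <- rbind(
    .mkAtoms(paste0("C", 1:6), rep("CA", 6), "BNZ", 1L, "RING"),
    .mkAtoms(paste0("H", 1:6), rep("HA", 6), "BNZ", 1L, "RING"),
    .mkAtoms(c("C7", "C8"), rep("CT", 2), "ETH", 2L, "PRC"),
    .mkAtoms(paste0("H", 7:12), rep("HT", 6), "ETH", 2L, "PRC"))
  xyz <- rbind(ringC, ringH, eth, ethH)
  bonds <- rbind(
    cbind(1:6, c(2:6, 1)),
    cbind(1:6, 7:12),
    c(13, 14),
    cbind(13, 15:17), cbind(14, 18:20))
  tp <- .autoBondedTerms(bonds, nrow(atoms))
  system <- MolecularSystem(atoms, bonds, tp$angles, tp$dihedrals,
                            coords = xyz)
  FixtureBundle(system, embeddedMinimalParams(), piercings = 1L,
                chiralCenters = 0L,
                notes = "two-carbon unit threaded through an aromatic ring")
}

#' Toy polymer of six-ring units with engineered piercings
#'
#' A chain of aromatic six-ring units joined by two-carbon linkers.  The
#' first `nPiercings` rings are each threaded by the central C-C bond of the
#' linker two units further along the chain: units u and u+1 sit on opposite
#' sides of ring u-1's plane and the linker between them passes vertically
#' through that ring's face.  The threaded bond is at least five bonds away
#' from the ring it pierces, so it cannot swing out during plain
#' minimization: each piercing is a genuine local-minimum trap.  Remaining
#' linkers extend the chain in-plane.  Construction is deterministic in
#' `seed`, which only jitters coordinates by < 0.005 A to break exact
#' symmetry.
#'
#' @param nUnits number of ring units (>= 2).
#' @param nPiercings number of engineered piercings (0..nUnits - 2; larger
#'   requests are geometrically infeasible and raise an error).
#' @param seed integer seed for the symmetry-breaking jitter.
#' @return A [FixtureBundle-class].
#' @export
makeToyPolymer <- function(nUnits, nPiercings, seed = 1L) {
  if (nUnits < 2) stop("infeasible request: need at least 2 units")
  if (nPiercings < 0 || nPiercings > max(0L, nUnits - 2L))
    stop("infeasible request: nPiercings must be in 0..nUnits-2")

  atoms <- list(); xyz <- list(); bonds <- list()
  nAt <- 0L
  addAtoms <- function(a, x) {
    atoms[[length(atoms) + 1L]] <<- a
    xyz[[length(xyz) + 1L]] <<- x
    idx <- nAt + seq_len(nrow(a))
    nAt <<- nAt + nrow(a)
    idx
  }
  addBonds <- function(b) bonds[[length(bonds) + 1L]] <<- b
  zhat <- c(0, 0, 1)

  ## ring centers: the pierced cluster zig-zags in z with growing amplitude
  ## (units u and u+1 must straddle ring u-1's plane); the tail extends +x
  centers <- matrix(0, nUnits, 3)
  for (u in seq_len(nUnits)[-1]) {
    centers[u, ] <- if (nPiercings > 0 && u <= nPiercings + 2)
      c(2.4 * (u - 1), 0.9 * (u %% 2), (-1)^u * 1.6 * floor(u / 2))
    else
      centers[u - 1, ] + c(6.5, 0, 0)
  }

  ringIdx <- vector("list", nUnits)
  ringXyzs <- vector("list", nUnits)
  usedVertex <- vector("list", nUnits)
  for (u in seq_len(nUnits)) {
    rx <- .hexCoords(centers[u, ], zhat, radius = 1.375)
    ringIdx[[u]] <- addAtoms(
      .mkAtoms(paste0("C", 1:6), rep("CA", 6), "RNG", u, "POLY"), rx)
    ringXyzs[[u]] <- rx
    usedVertex[[u]] <- integer(0)
    addBonds(cbind(ringIdx[[u]], ringIdx[[u]][c(2:6, 1)]))
  }
  pickVertex <- function(u, point) {
    free <- setdiff(1:6, usedVertex[[u]])
    d2 <- rowSums((ringXyzs[[u]][free, , drop = FALSE] -
                   matrix(point, length(free), 3, byrow = TRUE))^2)
    v <- free[which.min(d2)]
    usedVertex[[u]] <<- c(usedVertex[[u]], v)
    v
  }
  addLinkerH <- function(lIdx, lXyz, sd, perp) {
    q <- .cross3(sd, perp); q <- q / sqrt(sum(q^2))
    for (k in 1:2) {
      hs <- addAtoms(
        .mkAtoms(paste0("HL", c(2 * k - 1, 2 * k)), rep("HT", 2), "LNK",
                 0L, "POLY"),
        rbind(lXyz[k, ] + 0.85 * q + 0.5 * perp,
              lXyz[k, ] - 0.85 * q + 0.5 * perp))
      addBonds(cbind(lIdx[k], hs))
    }
  }

  for (u in seq_len(nUnits - 1L)) {
    pierces <- nPiercings > 0 && u >= 2 && u <= nPiercings + 1
    if (pierces) {
      p <- u - 1L
      hi <- centers[p, ] + 0.77 * zhat
      lo <- centers[p, ] - 0.77 * zhat
      upFirst <- centers[u, 3] >= centers[p, 3]
      endU <- if (upFirst) hi else lo
      endU1 <- if (upFirst) lo else hi
      lIdx <- addAtoms(
        .mkAtoms(c("CL1", "CL2"), rep("CT", 2), "LNK", u, "POLY"),
        rbind(endU, endU1))
      vU <- pickVertex(u, endU)
      vU1 <- pickVertex(u + 1L, endU1)
      addBonds(rbind(c(ringIdx[[u]][vU], lIdx[1]),
                     c(lIdx[1], lIdx[2]),
                     c(lIdx[2], ringIdx[[u + 1L]][vU1])))
      ## hydrogens horizontal, nudged away from the pierced ring plane
      sgn <- if (upFirst) 1 else -1
      addLinkerH(lIdx, rbind(endU + c(0, 0, 0.2) * sgn,
                             endU1 - c(0, 0, 0.2) * sgn),
                 zhat, c(1, 0, 0))
    } else {
      ## the one plain link inside the pierced cluster is routed around the
      ## -y side, clear of the closely stacked ring faces
      inCluster <- nPiercings > 0 && u <= nPiercings + 1L
      vU <- pickVertex(u, if (inCluster) centers[u, ] + c(0, -4, 0)
                          else centers[u + 1L, ])
      aU <- ringXyzs[[u]][vU, ]
      vU1 <- pickVertex(u + 1L, if (inCluster) centers[u + 1L, ] + c(0, -4, 0)
                                else centers[u, ])
      aU1 <- ringXyzs[[u + 1L]][vU1, ]
      seg <- aU1 - aU
      L <- sqrt(sum(seg^2))
      sd <- seg / L
      perp0 <- .cross3(sd, zhat)
      if (sqrt(sum(perp0^2)) < 0.1) perp0 <- .cross3(sd, c(1, 0, 0))
      perp <- perp0 / sqrt(sum(perp0^2))
      if (inCluster) {
        if (perp[2] > 0) perp <- -perp
      } else {
        perp <- perp * (-1)^u
      }
      mid <- (aU + aU1) / 2
      h <- sqrt(max(0.09, 2.25 - (L / 2 - 0.77)^2))
      l1 <- mid - 0.77 * sd + h * perp
      l2 <- mid + 0.77 * sd + h * perp
      lIdx <- addAtoms(
        .mkAtoms(c("CL1", "CL2"), rep("CT", 2), "LNK", u, "POLY"),
        rbind(l1, l2))
      addBonds(rbind(c(ringIdx[[u]][vU], lIdx[1]),
                     c(lIdx[1], lIdx[2]),
                     c(lIdx[2], ringIdx[[u + 1L]][vU1])))
      addLinkerH(lIdx, rbind(l1, l2), sd, perp)
    }
  }

  ## aromatic hydrogens on every unused ring vertex
  for (u in seq_len(nUnits)) {
    free <- setdiff(1:6, usedVertex[[u]])
    hx <- t(apply(ringXyzs[[u]][free, , drop = FALSE], 1, function(v)
      centers[u, ] + (v - centers[u, ]) * (2.455 / 1.375)))
    hIdx <- addAtoms(
      .mkAtoms(paste0("H", free), rep("HA", length(free)), "RNG", u, "POLY"),
      hx)
    addBonds(cbind(ringIdx[[u]][free], hIdx))
  }

  atoms <- do.call(rbind, atoms)
  xyz <- do.call(rbind, xyz)
  bonds <- do.call(rbind, bonds)
  set.seed(seed)
  xyz <- xyz + matrix(stats::runif(length(xyz), -0.0025, 0.0025), ncol = 3)
  tp <- .autoBondedTerms(bonds, nrow(atoms))
  system <- MolecularSystem(atoms, bonds, tp$angles, tp$dihedrals,
                            coords = xyz)
  FixtureBundle(system, embeddedMinimalParams(),
                piercings = as.integer(nPiercings), chiralCenters = 0L,
                notes = sprintf("%d-unit polymer, %d engineered piercings",
                                nUnits, nPiercings))
}

## one pyranose-like ring: C1-C5 + ring O5, link O on C1 (in-plane,
## aimed at `toward`), OH on C2/C3, two H on C4/C5.
.addSugarRing <- function(addAtoms, addBonds, center, normal, resid,
                          toward) {
  b <- .planeBasis(normal)
  tw <- toward - center
  tw <- tw - sum(tw * b$n) * b$n      # in-plane projection
  phase <- if (sqrt(sum(tw^2)) > 1e-6)
    atan2(sum(tw * b$e2), sum(tw * b$e1)) else 0
  ringXyz <- .hexCoords(center, normal, radius = 1.45, phase = phase,
                        pucker = 0.25)
  ridx <- addAtoms(.mkAtoms(c("C1", "C2", "C3", "C4", "C5", "O5"),
                            c("CT", "CT", "CT", "CT", "CT", "OS"),
                            "PYR", resid, "GLY"), ringXyz)
  addBonds(cbind(ridx, ridx[c(2:6, 1)]))
  out <- function(k) {
    d <- ringXyz[k, ] - center
    d <- d - sum(d * b$n) * b$n
    d / sqrt(sum(d^2))
  }
  ## link O on C1: in the ring plane, pointing outward toward the attachment
  oLink <- addAtoms(.mkAtoms("O1", "OE", "PYR", resid, "GLY"),
                    matrix(ringXyz[1, ] + 1.35 * out(1), 1))
  h1 <- addAtoms(.mkAtoms("H1", "HT", "PYR", resid, "GLY"),
                 matrix(ringXyz[1, ] + 0.35 * out(1) - 1.0 * b$n, 1))
  addBonds(rbind(c(ridx[1], oLink), c(ridx[1], h1)))
  for (k in 2:3) {
    s <- if (k == 2) 1 else -1
    oh <- addAtoms(.mkAtoms(paste0("O", k), "OH1", "PYR", resid, "GLY"),
                   matrix(ringXyz[k, ] + 1.0 * out(k) + s * 1.0 * b$n, 1))
    ho <- addAtoms(.mkAtoms(paste0("HO", k), "HO", "PYR", resid, "GLY"),
                   matrix(ringXyz[k, ] + 1.55 * out(k) + s * 1.45 * b$n, 1))
    hk <- addAtoms(.mkAtoms(paste0("H", k), "HT", "PYR", resid, "GLY"),
                   matrix(ringXyz[k, ] + 0.35 * out(k) - s * 1.0 * b$n, 1))
    addBonds(rbind(c(ridx[k], oh), c(oh, ho), c(ridx[k], hk)))
  }
  for (k in 4:5) {
    hs <- addAtoms(.mkAtoms(paste0("H", k, c("A", "B")), rep("HT", 2),
                            "PYR", resid, "GLY"),
      rbind(ringXyz[k, ] + 0.35 * out(k) + 1.0 * b$n,
            ringXyz[k, ] + 0.35 * out(k) - 1.0 * b$n))
    addBonds(cbind(ridx[k], hs))
  }
  list(ring = ridx, oLink = oLink)
}

#' Glyco-peptide toy fixture
#'
#' A three-residue peptide-like backbone carrying two hexose-like puckered
#' six-rings attached through ether linkages to side-chain carbons.  The
#' second ring is built around the CA-CB bond of the middle residue, so one
#' backbone-adjacent bond pierces a sugar ring.  Each ring contributes three
#' detectable stereocenters (C1, C2, C3) and each alpha-carbon one more, for
#' nine in total.
#'
#' @param seed integer seed for the symmetry-breaking coordinate jitter
#'   (< 0.005 A).
#' @return A [FixtureBundle-class] (manifest: 1 piercing, 9 chiral centers).
#' @export
makeGlycoPeptideToy <- function(seed = 1L) {
  atoms <- list(); xyz <- list(); bonds <- list()
  nAt <- 0L
  addAtoms <- function(a, x) {
    atoms[[length(atoms) + 1L]] <<- a
    xyz[[length(xyz) + 1L]] <<- x
    idx <- nAt + seq_len(nrow(a))
    nAt <<- nAt + nrow(a)
    idx
  }
  addBonds <- function(b) bonds[[length(bonds) + 1L]] <<- b

  prevC <- NA_integer_
  caXyz <- matrix(0, 3, 3); cbXyz <- matrix(0, 3, 3)
  caIdx <- integer(3); cbIdx <- integer(3)
  for (res in 1:3) {
    x0 <- (res - 1) * 3.6
    ni <- addAtoms(.mkAtoms("N", "NT", "RES", res, "PEP"),
                   matrix(c(x0, 0.0, 0.0), 1))
    hn <- addAtoms(.mkAtoms("HN", "HT", "RES", res, "PEP"),
                   matrix(c(x0 - 0.35, -0.9, 0.2), 1))
    ca <- addAtoms(.mkAtoms("CA", "CT", "RES", res, "PEP"),
                   matrix(c(x0 + 1.2, 0.8, 0.0), 1))
    ha <- addAtoms(.mkAtoms("HA", "HT", "RES", res, "PEP"),
                   matrix(c(x0 + 1.1, 1.45, -0.9), 1))
    cb <- addAtoms(.mkAtoms("CB", "CT", "RES", res, "PEP"),
                   matrix(c(x0 + 1.25, 1.65, 1.3), 1))
    co <- addAtoms(.mkAtoms("C", "C", "RES", res, "PEP"),
                   matrix(c(x0 + 2.5, 0.0, 0.0), 1))
    oc <- addAtoms(.mkAtoms("O", "OC", "RES", res, "PEP"),
                   matrix(c(x0 + 2.6, -1.23, 0.0), 1))
    addBonds(rbind(c(ni, hn), c(ni, ca), c(ca, ha), c(ca, cb), c(ca, co),
                   c(co, oc)))
    if (res > 1) addBonds(matrix(c(prevC, ni), 1))
    hb <- addAtoms(.mkAtoms(c("HB1", "HB2"), c("HT", "HT"), "RES", res,
                            "PEP"),
                   rbind(c(x0 + 0.55, 2.35, 1.25), c(x0 + 2.0, 2.2, 1.5)))
    addBonds(cbind(cb, hb))
    prevC <- co
    caIdx[res] <- ca; cbIdx[res] <- cb
    caXyz[res, ] <- c(x0 + 1.2, 0.8, 0.0)
    cbXyz[res, ] <- c(x0 + 1.25, 1.65, 1.3)
  }

  ## sugar 1 on CB of residue 1: ring plane contains the direction back to
  ## the side chain, so the ether linkage approaches edge-on (no piercing)
  u <- c(0, 0.6, 0.8)
  s1center <- cbXyz[1, ] + 3.0 * u
  s1 <- .addSugarRing(addAtoms, addBonds, center = s1center,
                      normal = c(1, 0, 0), resid = 4L, toward = cbXyz[1, ])
  addBonds(matrix(c(cbIdx[1], s1$oLink), 1))

  ## sugar 2 built around the CA-CB bond of residue 2: centered at the bond
  ## midpoint with its plane normal along the bond, so the backbone-adjacent
  ## CA-CB bond threads its face; its ether linkage reaches CB of residue 3
  mid <- (caXyz[2, ] + cbXyz[2, ]) / 2
  nrm <- cbXyz[2, ] - caXyz[2, ]
  s2 <- .addSugarRing(addAtoms, addBonds, center = mid, normal = nrm,
                      resid = 5L, toward = cbXyz[3, ])
  addBonds(matrix(c(cbIdx[3], s2$oLink), 1))

  atoms <- do.call(rbind, atoms)
  xyz <- do.call(rbind, xyz)
  bonds <- do.call(rbind, bonds)
  set.seed(seed)
  xyz <- xyz + matrix(stats::runif(length(xyz), -0.0025, 0.0025), ncol = 3)
  tp <- .autoBondedTerms(bonds, nrow(atoms))
  system <- MolecularSystem(atoms, bonds, tp$angles, tp$dihedrals,
                            coords = xyz)
  FixtureBundle(system, embeddedMinimalParams(), piercings = 1L,
                chiralCenters = 9L,
                notes = "glycosylated tripeptide toy; middle CA-CB bond threads a hexose ring")
}

#' Deliberately strained chiral toy (adversarial)
#'
#' A stereocenter caged under a bulky apex atom: the apex is bonded through
#' three short bridges to all three heavy substituents of the center, and
#' the center's hydrogen starts inside the cage pointing at the apex.  The
#' steric press between apex and hydrogen cannot escape sideways (the
#' bridges close every lateral path), so minimization drives the hydrogen
#' down through the substituent plane and inverts the center -- silently,
#' with no long bond left behind.  The companion demonstration is
#' [makeGlycoPeptideToy()], whose nine stereocenters survive a full default
#' repair run with restraints on; this cage shows what the repair forces
#' can do to an unprotected center.
#'
#' @return A [FixtureBundle-class] (manifest: 0 piercings, 1 chiral center).
#' @export
makeStrainedChiralToy <- function() {
  atoms <- list(); xyz <- list(); bonds <- list()
  nAt <- 0L
  addAtoms <- function(a, x) {
    atoms[[length(atoms) + 1L]] <<- a
    xyz[[length(xyz) + 1L]] <<- x
    idx <- nAt + seq_len(nrow(a))
    nAt <<- nAt + nrow(a)
    idx
  }
  addBonds <- function(b) bonds[[length(bonds) + 1L]] <<- b

  c0 <- addAtoms(.mkAtoms("C0", "CT", "CEN", 1L, "CHI"),
                 matrix(c(0, 0, 0), 1))
  n1 <- addAtoms(.mkAtoms("N1", "NT", "CEN", 1L, "CHI"),
                 matrix(c(1.40, 0, 0.15), 1))
  o1 <- addAtoms(.mkAtoms("O1", "OS", "CEN", 1L, "CHI"),
                 matrix(c(-0.70, 1.21, 0.15), 1))
  c1 <- addAtoms(.mkAtoms("C1", "CT", "CEN", 1L, "CHI"),
                 matrix(c(-0.70, -1.21, 0.15), 1))
  h0 <- addAtoms(.mkAtoms("H0", "HT", "CEN", 1L, "CHI"),
                 matrix(c(0, 0, 1.05), 1))
  xl <- addAtoms(.mkAtoms("XL", "XL", "CEN", 1L, "CHI"),
                 matrix(c(0, 0, 2.2), 1))
  bridge <- function(sub, subXyz, nm) {
    radial <- c(subXyz[1], subXyz[2], 0)
    radial <- radial / sqrt(sum(radial^2))
    cb <- addAtoms(.mkAtoms(nm, "CT", "CEN", 1L, "CHI"),
                   matrix(c(subXyz[1] * 1.03, subXyz[2] * 1.03, 1.55), 1))
    cbXyz <- c(subXyz[1] * 1.03, subXyz[2] * 1.03, 1.55)
    tangent <- .cross3(c(0, 0, 1), radial)
    hdir1 <- radial * 0.9 + c(0, 0, 0.35) + 0.6 * tangent
    hdir2 <- radial * 0.9 + c(0, 0, 0.35) - 0.6 * tangent
    h <- addAtoms(.mkAtoms(paste0("H", nm, 1:2), rep("HT", 2), "CEN", 1L,
                           "CHI"),
      rbind(cbXyz + 1.09 * hdir1 / sqrt(sum(hdir1^2)),
            cbXyz + 1.09 * hdir2 / sqrt(sum(hdir2^2))))
    addBonds(rbind(c(sub, cb), c(cb, xl), c(cb, h[1]), c(cb, h[2])))
    cb
  }
  bridge(n1, c(1.40, 0, 0.15), "CB1")
  bridge(o1, c(-0.70, 1.21, 0.15), "CB3")
  bridge(c1, c(-0.70, -1.21, 0.15), "CB2")
  hn <- addAtoms(.mkAtoms("HN1", "HT", "CEN", 1L, "CHI"),
                 matrix(c(2.3, 0, -0.25), 1))
  h1 <- addAtoms(.mkAtoms(c("H1A", "H1B"), rep("HT", 2), "CEN", 1L, "CHI"),
                 rbind(c(-0.35, -2.1, -0.45), c(-1.7, -1.45, -0.25)))
  addBonds(rbind(c(c0, n1), c(c0, o1), c(c0, c1), c(c0, h0),
                 c(n1, hn), c(c1, h1[1]), c(c1, h1[2])))
  atoms <- do.call(rbind, atoms)
  xyz <- do.call(rbind, xyz)
  bonds <- do.call(rbind, bonds)
  tp <- .autoBondedTerms(bonds, nrow(atoms))
  system <- MolecularSystem(atoms, bonds, tp$angles, tp$dihedrals,
                            coords = xyz)
  FixtureBundle(system, embeddedMinimalParams(), piercings = 0L,
                chiralCenters = 1L,
                notes = "caged stereocenter pressed by a bridged bulky apex")
}

#' Write a fixture to disk as PSF + PDB + PRM + run config
#'
#' @param bundle a [FixtureBundle-class].
#' @param dir output directory (created if absent).
#' @param name base name for the four files.
#' @return named character vector of the paths written, invisibly.
#' @export
writeFixture <- function(bundle, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  psf <- file.path(dir, paste0(name, ".psf"))
  pdb <- file.path(dir, paste0(name, ".pdb"))
  prm <- file.path(dir, paste0(name, ".prm"))
  cfg <- file.path(dir, paste0(name, ".yaml"))
  writePSF(bundle@system, psf)
  writePDB(bundle@system, pdb)
  writeLines(.minimalParamText(), prm)
  yaml::write_yaml(list(structure = paste0(name, ".psf"),
                        coordinates = paste0(name, ".pdb"),
                        parameters = list(paste0(name, ".prm")),
                        label = name), cfg)
  invisible(c(psf = psf, pdb = pdb, prm = prm, config = cfg))
}
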