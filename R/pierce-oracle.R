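#' @include AllClasses.R topology-graph.R
NULL

#' Segment-triangle intersection test
#'
#' Closed test: a segment touching the triangle's edge or vertices, or an
#' endpoint lying in the triangle's plane inside it, counts as intersecting.
#' Inclusive boundaries make a fan of triangles sharing edges watertight.
#'
#' @param p0,p1 segment endpoints (numeric 3-vectors, A).
#' @param t0,t1,t2 triangle vertices (numeric 3-vectors, A).
#' @param tol boundary tolerance.
#' @return list with `hit` (logical) and `point` (3-vector, or NULL).
#' @export
segmentTriangleIntersect <- function(p0, p1, t0, t1, t2, tol = 1e-9) {
  e1 <- t1 - t0
  e2 <- t2 - t0
  nrm <- .cross3(e1, e2)
  area2 <- sqrt(sum(nrm^2))
  if (area2 / 2 <= 1e-8) stop("degenerate triangle (area <= 1e-8 A^2)")

  d <- p1 - p0
  denom <- sum(nrm * d)
  w0 <- sum(nrm * (t0 - p0))
  if (abs(denom) < tol * area2) {
    ## segment (nearly) parallel to the plane; only a hit if it lies in the
    ## plane and an endpoint projects inside -- treat via endpoint checks
    for (p in list(p0, p1)) {
      if (abs(sum(nrm * (p - t0))) <= tol * area2 &&
          .inTriangle(p, t0, e1, e2, nrm, tol)) {
        return(list(hit = TRUE, point = p))
      }
    }
    return(list(hit = FALSE, point = NULL))
  }
  s <- w0 / denom
  if (s < -tol || s > 1 + tol) return(list(hit = FALSE, point = NULL))
  pt <- p0 + s * d
  if (.inTriangle(pt, t0, e1, e2, nrm, tol))
    list(hit = TRUE, point = pt)
  else
    list(hit = FALSE, point = NULL)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## barycentric point-in-triangle with inclusive boundaries
.inTriangle <- function(p, t0, e1, e2, nrm, tol) {
  w <- p - t0
  d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
  dw1 <- sum(w * e1); dw2 <- sum(w * e2)
  det <- d11 * d22 - d12 * d12
  if (det <= 0) return(FALSE)
  u <- (d22 * dw1 - d12 * dw2) / det
  v <- (d11 * dw2 - d12 * dw1) / det
  u >= -tol && v >= -tol && (u + v) <= 1 + tol
}

#' Find bonds piercing small rings
#'
#' Each ring is fan-triangulated about its centroid (watertight for planar
#' aromatics and puckered hexose chairs alike) and every bond that shares no
#' atom with the ring is tested against the fan.  One event is reported per
#' (bond, ring) pair, in deterministic order.
#'
#' @param system a [MolecularSystem-class] with coordinates set.
#' @param rings list of integer atom cycles (see [enumerateSmallRings()]);
#'   computed from the bond graph when `NULL`.
#' @return data.frame with one row per event: `ai, aj` (piercing bond),
#'   `ring` (list column of member vectors), `px, py, pz` (intersection, A).
#' @export
findPiercings <- function(system, rings = NULL) {
  if (is.null(rings))
    rings <- enumerateSmallRings(buildGraph(system))
  xyz <- coords(system)
  b <- system@bonds
  out <- list()
  for (ri in seq_along(rings)) {
    ring <- rings[[ri]]
    rxyz <- xyz[ring, , drop = FALSE]
    centroid <- colMeans(rxyz)
    k <- length(ring)
    ## candidate bonds: skip those sharing an atom with the ring, and prune
    ## by distance to the ring centroid (a hit must pass within the ring
    ## radius of the fan)
    share <- (b[, 1] %in% ring) | (b[, 2] %in% ring)
    rad <- max(sqrt(rowSums((rxyz - matrix(centroid, k, 3, byrow = TRUE))^2)))
    for (bi in which(!share)) {
      p0 <- xyz[b[bi, 1], ]
      p1 <- xyz[b[bi, 2], ]
      if (.segPointDist2(p0, p1, centroid) > (rad + 1e-6)^2) next
      for (e in seq_len(k)) {
        v0 <- rxyz[e, ]
        v1 <- rxyz[(e %% k) + 1L, ]
        hit <- segmentTriangleIntersect(p0, p1, v0, v1, centroid)
        if (hit$hit) {
          out[[length(out) + 1L]] <- data.frame(
            ai = b[bi, 1], aj = b[bi, 2], ringIndex = ri,
            px = hit$point[1], py = hit$point[2], pz = hit$point[3])
          break
        }
      }
    }
  }
  if (!length(out)) {
    ev <- data.frame(ai = integer(0), aj = integer(0), ringIndex = integer(0),
                     px = numeric(0), py = numeric(0), pz = numeric(0))
  } else {
    ev <- do.call(rbind, out)
    ev <- ev[order(ev$ringIndex, ev$ai, ev$aj), , drop = FALSE]
    rownames(ev) <- NULL
  }
  attr(ev, "rings") <- rings
  ev
}

## squared distance from point q to segment p0-p1
.segPointDist2 <- function(p0, p1, q) {
  d <- p1 - p0
  L2 <- sum(d^2)
  t <- if (L2 > 0) max(0, min(1, sum((q - p0) * d) / L2)) else 0
  sum((p0 + t * d - q)^2)
}

#' Detect potential chiral centers
#'
#' A potential stereocenter is any atom with exactly four bonded neighbors
#' whose substituent branches are pairwise distinguishable at the first
#' shell: each branch is summarized by the substituent's atom type plus the
#' sorted types of its own neighbors (the center excluded).  Over-inclusion
#' is harmless (a restraint on a non-center does nothing); methane-like
#' centers with identical branches are excluded.  Substituent order is fixed
#' by ascending atom index, and each center's reference sign is computed from
#' the current coordinates.
#'
#' @param system a [MolecularSystem-class] with coordinates set.
#' @return data.frame with `center`, `s1..s4` (substituent indices) and
#'   `sign` (+1/-1).
#' @export
detectChiralCenters <- function(system) {
  g <- buildGraph(system)
  ty <- system@atoms$type
  adj <- lapply(seq_len(natoms(system)), function(v)
    sort(as.integer(igraph::neighbors(g, v))))
  out <- list()
  for (v in seq_len(natoms(system))) {
    nb <- adj[[v]]
    if (length(nb) != 4L) next
    sig <- vapply(nb, function(s) {
      shell <- sort(ty[setdiff(adj[[s]], v)])
      paste(ty[s], paste(shell, collapse = ","), sep = ":")
    }, "")
    if (anyDuplicated(sig)) next
    sgn <- chiralitySign(nb, coords(system))
    out[[length(out) + 1L]] <- data.frame(
      center = v, s1 = nb[1], s2 = nb[2], s3 = nb[3], s4 = nb[4], sign = sgn)
  }
  if (!length(out))
    return(data.frame(center = integer(0), s1 = integer(0), s2 = integer(0),
                      s3 = integer(0), s4 = integer(0), sign = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chirality sign of an ordered substituent tetrahedron
#'
#' Sign of det[r2-r1, r3-r1, r4-r1] over the four ordered substituents;
#' invariant under rigid rotation, flipped by mirror reflection.
#'
#' @param substituents integer vector of 4 atom indices, in order.
#' @param coordinates natoms x 3 coordinate matrix (A).
#' @return `+1` or `-1`.
#' @export
chiralitySign <- function(substituents, coordinates) {
  stopifnot(length(substituents) == 4)
  r <- coordinates[substituents, , drop = FALSE]
  m <- rbind(r[2, ] - r[1, ], r[3, ] - r[1, ], r[4, ] - r[1, ])
  vol <- det(m)
  if (abs(vol) < 1e-6)
    stop("substituents are coplanar within tolerance; center ",
         "is geometrically degenerate")
  sign(vol)
}

#' Generate chirality-preserving improper restraints
#'
#' One harmonic improper-dihedral restraint per center over the quadruple
#' (center, s1, s2, s3), targeting the improper angle measured in the input
#' structure, so the tool preserves rather than imposes stereochemistry.
#'
#' @param centers data.frame from [detectChiralCenters()].
#' @param coordinates natoms x 3 input coordinates (A).
#' @param k force constant (kcal/mol/rad^2, default 50).
#' @return data.frame `a, b, c, d, k, phi0` with `phi0` in radians.
#' @export
generateChiralityRestraints <- function(centers, coordinates, k = 50) {
  if (!nrow(centers))
    return(data.frame(a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), k = numeric(0), phi0 = numeric(0)))
  phi0 <- vapply(seq_len(nrow(centers)), function(i)
    dihedralAngle(coordinates[centers$center[i], ],
                  coordinates[centers$s1[i], ],
                  coordinates[centers$s2[i], ],
                  coordinates[centers$s3[i], ]), 0)
  data.frame(a = centers$center, b = centers$s1, c = centers$s2,
             d = centers$s3, k = k, phi0 = phi0)
}

#' Dihedral angle of four points
#'
#' Signed angle in radians, in (-pi, pi], of the quadruple a-b-c-d about the
#' b-c axis.
#'
#' @param a,b,c,d numeric 3-vectors (A).
#' @return angle in radians.
#' @export
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  s <- sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(s, sum(n1 * n2))
}

#' Write restraints to a plain-text extra-restraints file
#'
#' One improper per line: the four atom indices, the force constant
#' (kcal/mol/rad^2) and the target angle in degrees.
#'
#' @param restraints data.frame from [generateChiralityRestraints()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRestraintsFile <- function(restraints, path) {
  lines <- sprintf("improper %d %d %d %d %.4f %.4f",
                   restraints$a, restraints$b, restraints$c, restraints$d,
                   restraints$k, restraints$phi0 * 180 / pi)
  writeLines(lines, path)
  invisible(path)
}
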