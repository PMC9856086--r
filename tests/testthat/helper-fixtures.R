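## Shared fixtures are built once per session and cached; all are generated
## in code, nothing is read from disk.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.cache[[name]])) assign(name, builder(), envir = .cache)
  .cache[[name]]
}

benzeneEthane <- function() cached("bnz", makePiercedBenzeneEthane)
toyPolymer <- function() cached("poly53", function() makeToyPolymer(5, 3, seed = 7))
cleanPolymer <- function() cached("poly0", function() makeToyPolymer(3, 0, seed = 1))
glycoToy <- function() cached("glyco", function() makeGlycoPeptideToy(seed = 1))
strainedToy <- function() cached("cage", makeStrainedChiralToy)
minimalParams <- function() cached("prm", embeddedMinimalParams)

testConfig <- function(...) RunConfig(outdir = tempdir(), ...)

## a bare system from explicit pieces, for micro-tests
miniSystem <- function(types, xyz, bonds = matrix(integer(0), ncol = 2),
                       charges = 0, masses = 12) {
  n <- length(types)
  atoms <- data.frame(name = paste0("A", seq_len(n)), resname = "TOY",
                      resid = 1L, segid = "T", type = types,
                      charge = rep_len(charges, n),
                      mass = rep_len(masses, n), stringsAsFactors = FALSE)
  tuples <- if (nrow(bonds)) ringfree:::.autoBondedTerms(bonds, n)
            else list(angles = matrix(integer(0), ncol = 3),
                      dihedrals = matrix(integer(0), ncol = 4))
  MolecularSystem(atoms, bonds, tuples$angles, tuples$dihedrals, coords = xyz)
}

## write a tiny parameter file and parse it
miniParams <- function(lines) {
  path <- tempfile(fileext = ".prm")
  writeLines(lines, path)
  readParameters(path)
}

## maximum relative force error against central differences, with a 1
## kcal/mol/A floor so near-zero components do not dominate the ratio
gradMaxRelErr <- function(system, params, model, nProbe = 40, h = 1e-6,
                          ff = NULL, seed = 1) {
  if (is.null(ff)) ff <- compileForceField(system, params)
  ev <- computeEnergyForces(system, params, model, ff = ff)
  x0 <- coords(system)
  set.seed(seed)
  worst <- 0
  for (t in seq_len(nProbe)) {
    i <- sample(nrow(x0), 1)
    d <- sample(3, 1)
    xp <- x0; xp[i, d] <- xp[i, d] + h
    xm <- x0; xm[i, d] <- xm[i, d] - h
    num <- (computeEnergyForces(system, params, model, xyz = xp, ff = ff)$energy -
            computeEnergyForces(system, params, model, xyz = xm, ff = ff)$energy) / (2 * h)
    ana <- -ev$forces[i, d]
    worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1))
  }
  worst
}

## chirality signs of a set of detected centers at given coordinates
signsAt <- function(centers, xyz) {
  vapply(seq_len(nrow(centers)), function(i)
    chiralitySign(unlist(centers[i, c("s1", "s2", "s3", "s4")]), xyz), 0)
}

## independent segment/triangle oracle: solve the 3x3 linear system for the
## plane crossing and check barycentric coordinates
segTriOracle <- function(p0, p1, t0, t1, t2, tol = 1e-9) {
  A <- cbind(t1 - t0, t2 - t0, -(p1 - p0))
  if (abs(det(A)) < 1e-12) {
    ## parallel: report a hit only if an endpoint lies in the triangle plane
    nrm <- ringfree:::.cross3(t1 - t0, t2 - t0)
    for (p in list(p0, p1)) {
      if (abs(sum(nrm * (p - t0))) <= tol * sqrt(sum(nrm^2))) {
        uv <- tryCatch(qr.solve(cbind(t1 - t0, t2 - t0), p - t0),
                       error = function(e) c(-1, -1))
        if (uv[1] >= -tol && uv[2] >= -tol && sum(uv) <= 1 + tol)
          return(TRUE)
      }
    }
    return(FALSE)
  }
  x <- solve(A, p0 - t0)
  x[1] >= -tol && x[2] >= -tol && (x[1] + x[2]) <= 1 + tol &&
    x[3] >= -tol && x[3] <= 1 + tol
}

## independent small-ring oracle: all chordless simple cycles of size <=
## maxSize, found through igraph simple paths between bonded vertex pairs
ringOracle <- function(bonds, n, maxSize = 7) {
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  adj <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(g, v)))
  seen <- character(0)
  out <- list()
  for (e in seq_len(nrow(bonds))) {
    u <- bonds[e, 1]; v <- bonds[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    paths <- igraph::all_simple_paths(g2, from = u, to = v,
                                      cutoff = maxSize - 1)
    for (p in paths) {
      cyc <- as.integer(p)
      if (length(cyc) < 3 || length(cyc) > maxSize) next
      if (!ringfree:::.isChordless(cyc, adj)) next
      key <- paste(sort(cyc), collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- sort(cyc)
      }
    }
  }
  out[order(vapply(out, function(x) paste(sprintf("%06d", x), collapse = ""),
                   ""))]
}
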