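#' @include AllClasses.R
NULL

#' Build the bonded-topology graph of a system
#'
#' @param system a [MolecularSystem-class] with at least one bond.
#' @return An undirected igraph graph whose vertices are the atom indices and
#'   whose edge set equals the system's bond set.
#' @export
buildGraph <- function(system) {
  igraph::graph_from_edgelist(system@bonds, directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < natoms(system))
       igraph::add_vertices(g, natoms(system) - igraph::vcount(g)) else g)()
}

#' Enumerate the small rings of a bond graph
#'
#' Returns every chordless simple cycle of size 3..`maxSize` — the minimal
#' faces a bond can thread.  Larger macrocycles (which are not piercing
#' artifacts) and cycles shortcut by a chord (e.g. the 10-membered perimeter
#' of two fused six-rings) are excluded.  Ordering is deterministic: rings
#' are sorted by their smallest member index, then lexicographically; each
#' ring is rotated to start at its smallest atom with the smaller neighbor
#' second.
#'
#' @param graph an igraph graph from [buildGraph()].
#' @param maxSize largest ring size considered "small" (default 7).
#' @return list of integer vectors, each an ordered atom cycle.
#' @export
enumerateSmallRings <- function(graph, maxSize = 7L) {
  n <- igraph::vcount(graph)
  adj <- lapply(seq_len(n), function(v)
    sort(as.integer(igraph::neighbors(graph, v))))
  found <- new.env(hash = TRUE)
  rings <- list()

  ## bounded DFS from each start vertex; only extend with vertices larger
  ## than the start so each cycle is generated from its smallest member
  dfs <- function(start, path) {
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (nxt == start && length(path) >= 3L) {
        if (.isChordless(path, adj)) {
          key <- paste(sort(path), collapse = ",")
          if (is.null(found[[key]])) {
            found[[key]] <- TRUE
            rings[[length(rings) + 1L]] <<- path
          }
        }
      } else if (nxt > start && !(nxt %in% path) && length(path) < maxSize) {
        dfs(start, c(path, nxt))
      }
    }
  }
  for (v in seq_len(n)) if (length(adj[[v]]) >= 2L) dfs(v, v)

  rings <- lapply(rings, .canonicalRing)
  if (!length(rings)) return(list())
  ord <- order(vapply(rings, `[[`, 0L, 1L),
               vapply(rings, function(r) paste(sprintf("%06d", r), collapse = ""), ""))
  rings[ord]
}

## a cycle is chordless when no non-consecutive members are bonded
.isChordless <- function(cyc, adj) {
  k <- length(cyc)
  for (i in seq_len(k - 2L)) {
    js <- if (i == 1L) seq(i + 2L, k - 1L) else seq(i + 2L, k)
    for (j in js) if (cyc[j] %in% adj[[cyc[i]]]) return(FALSE)
  }
  TRUE
}

## rotate to start at the smallest atom, smaller neighbor second
.canonicalRing <- function(cyc) {
  k <- length(cyc)
  i <- which.min(cyc)
  cyc <- cyc[((seq_len(k) + i - 2L) %% k) + 1L]
  if (cyc[2L] > cyc[k]) cyc <- c(cyc[1L], rev(cyc[-1L]))
  as.integer(cyc)
}

#' Atoms within a radius of a point
#'
#' Closed-ball selection with no periodic imaging.
#'
#' @param system a [MolecularSystem-class] with coordinates set.
#' @param center numeric 3-vector (A).
#' @param radius positive radius (A).
#' @return sorted integer vector of atom indices.
#' @export
atomsWithin <- function(system, center, radius) {
  stopifnot(radius > 0, length(center) == 3)
  xyz <- coords(system)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
        (xyz[, 3] - center[3])^2
  which(d2 <= radius^2)
}

#' Bonded neighborhood of a seed set
#'
#' All atoms within `depth` bond hops of any seed, seeds included;
#' `depth = 0` returns the seeds unchanged.
#'
#' @param graph an igraph graph from [buildGraph()].
#' @param seeds integer atom indices.
#' @param depth non-negative hop count.
#' @return sorted integer vector of atom indices.
#' @export
bondedNeighborhood <- function(graph, seeds, depth) {
  stopifnot(depth >= 0)
  seeds <- as.integer(seeds)
  if (length(seeds) && (min(seeds) < 1L || max(seeds) > igraph::vcount(graph)))
    stop("seed atom index out of range")
  if (!length(seeds)) return(integer(0))
  hood <- igraph::ego(graph, order = depth, nodes = seeds)
  sort(unique(as.integer(unlist(hood))))
}
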