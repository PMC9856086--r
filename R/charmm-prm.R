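#' @include AllClasses.R
NULL

.stripComment <- function(x) sub("\\s*[!*].*$", "", x)

.sectionStarts <- c(
  BONDS = "BONDS", ANGLES = "ANGLES", THETAS = "ANGLES",
  DIHEDRALS = "DIHEDRALS", PHI = "DIHEDRALS",
  IMPROPER = "IMPROPER", IMPROPERS = "IMPROPER", IMPHI = "IMPROPER",
  NONBONDED = "NONBONDED", CMAP = "SKIP", HBOND = "SKIP",
  NBFIX = "SKIP", ATOMS = "SKIP", MASS = NA, END = NA, RETURN = NA
)

#' Read CHARMM parameter / stream files into a ParameterSet
#'
#' Understands the BONDS, ANGLES, DIHEDRALS, IMPROPER and NONBONDED blocks of
#' CHARMM PRM files and the `read param card` payload of stream (STR) files.
#' RTF content (MASS/RESI records) and CMAP/NBFIX/HBOND blocks are tolerated
#' and skipped.  When several files define the same type tuple, the last file
#' wins (all multiplicities of a dihedral key are replaced together).
#'
#' @param paths character vector of parameter file paths, applied in order.
#' @return A [ParameterSet-class].
#' @export
readParameters <- function(paths) {
  stopifnot(length(paths) >= 1)
  bonds <- list(); angles <- list(); dihedrals <- list()
  impropers <- list(); nonbonded <- list()
  sawBonds <- FALSE

  for (path in paths) {
    if (!file.exists(path)) stop("parameter file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    section <- "NONE"
    fileDihKeys <- character(0)   # dihedral keys replaced by this file
    for (li in seq_along(lines)) {
      raw <- .stripComment(lines[li])
      txt <- trimws(raw)
      if (!nzchar(txt)) next
      toks <- strsplit(txt, "\\s+")[[1]]
      head1 <- toupper(toks[1])
      if (head1 %in% c("READ", "RESI", "PRES", "GROUP", "BOND", "DOUBLE",
                       "ANGLE", "DIHE", "IMPR", "DONOR", "ACCEPTOR", "IC",
                       "PATCH", "DELETE", "AUTO", "DEFA", "DECL")) {
        ## RTF-side records; BOND/ANGLE inside RESI are topology, not params
        if (head1 %in% c("RESI", "PRES")) section <- "SKIP"
        next
      }
      if (head1 %in% names(.sectionStarts)) {
        sec <- .sectionStarts[[head1]]
        if (!is.na(sec)) section <- sec
        next
      }
      if (grepl("^[0-9.-]", toks[1]) && section == "NONE") next
      num <- function(i, what) {
        v <- suppressWarnings(as.numeric(toks[i]))
        if (anyNA(v))
          stop(sprintf("malformed numeric field in %s block, %s line %d",
                       what, path, li))
        v
      }
      if (section == "BONDS" && length(toks) >= 4) {
        v <- num(3:4, "BONDS")
        bonds[[.pairKey(toks[1], toks[2])]] <-
          data.frame(t1 = toks[1], t2 = toks[2], k = v[1], b0 = v[2],
                     stringsAsFactors = FALSE)
        sawBonds <- TRUE
      } else if (section == "ANGLES" && length(toks) >= 5) {
        v <- num(4:5, "ANGLES")
        angles[[.tripleKey(toks[1:3])]] <-
          data.frame(t1 = toks[1], t2 = toks[2], t3 = toks[3],
                     k = v[1], theta0 = v[2], stringsAsFactors = FALSE)
      } else if (section == "DIHEDRALS" && length(toks) >= 7) {
        v <- num(5:7, "DIHEDRALS")
        key <- .quadKey(toks[1:4])
        if (!(key %in% fileDihKeys)) {   # a later file replaces all terms
          dihedrals[[key]] <- NULL
          fileDihKeys <- c(fileDihKeys, key)
        }
        dihedrals[[key]] <- rbind(dihedrals[[key]],
          data.frame(t1 = toks[1], t2 = toks[2], t3 = toks[3], t4 = toks[4],
                     k = v[1], n = as.integer(v[2]), delta = v[3],
                     stringsAsFactors = FALSE))
      } else if (section == "IMPROPER" && length(toks) >= 7) {
        v <- num(5:7, "IMPROPER")
        impropers[[.quadKey(toks[1:4])]] <-
          data.frame(t1 = toks[1], t2 = toks[2], t3 = toks[3], t4 = toks[4],
                     k = v[1], phi0 = v[3], stringsAsFactors = FALSE)
      } else if (section == "NONBONDED" && length(toks) >= 4) {
        if (head1 %in% c("CUTNB", "NBXMOD", "E14FAC", "WMIN", "CTOFNB",
                         "CTONNB", "EPS", "VDW", "VSWITCH", "SHIFT"))
          next
        v <- num(2:4, "NONBONDED")
        nonbonded[[toupper(toks[1])]] <-
          data.frame(type = toks[1], eps = abs(v[2]), rmin2 = v[3],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!sawBonds)
    stop("no BONDS block found in any parameter file")
  bindRows <- function(lst, proto) {
    if (!length(lst)) return(proto)
    out <- do.call(rbind, unname(lst))
    rownames(out) <- NULL
    out
  }
  new("ParameterSet",
      bonds = bindRows(bonds, data.frame(t1 = character(0), t2 = character(0),
                                         k = numeric(0), b0 = numeric(0))),
      angles = bindRows(angles, data.frame(t1 = character(0), t2 = character(0),
                                           t3 = character(0), k = numeric(0),
                                           theta0 = numeric(0))),
      dihedrals = bindRows(dihedrals,
        data.frame(t1 = character(0), t2 = character(0), t3 = character(0),
                   t4 = character(0), k = numeric(0), n = integer(0),
                   delta = numeric(0))),
      impropers = bindRows(impropers,
        data.frame(t1 = character(0), t2 = character(0), t3 = character(0),
                   t4 = character(0), k = numeric(0), phi0 = numeric(0))),
      nonbonded = bindRows(nonbonded,
        data.frame(type = character(0), eps = numeric(0), rmin2 = numeric(0))))
}

.pairKey <- function(a, b) paste(sort(toupper(c(a, b))), collapse = "|")

.tripleKey <- function(t) {
  t <- toupper(t)
  r <- rev(t)
  paste(if (paste(t, collapse = "|") <= paste(r, collapse = "|")) t else r,
        collapse = "|")
}

.quadKey <- function(t) {
  t <- toupper(t)
  r <- rev(t)
  paste(if (paste(t, collapse = "|") <= paste(r, collapse = "|")) t else r,
        collapse = "|")
}

#' Bond parameter lookup
#'
#' Lookup is invariant under reversal of the type pair.
#'
#' @param params a [ParameterSet-class].
#' @param t1,t2 CHARMM atom type strings.
#' @return list with `k` (kcal/mol/A^2) and `b0` (A).
#' @export
bondParam <- function(params, t1, t2) {
  tb <- params@bonds
  hit <- which(.pairKey(t1, t2) == mapply(.pairKey, tb$t1, tb$t2))
  if (!length(hit))
    stop(sprintf("no bond parameter for type pair (%s, %s)", t1, t2))
  list(k = tb$k[hit[1]], b0 = tb$b0[hit[1]])
}

#' Angle parameter lookup (reversal-invariant)
#' @inheritParams bondParam
#' @param t3 third atom type.
#' @return list with `k` (kcal/mol/rad^2) and `theta0` (degrees).
#' @export
angleParam <- function(params, t1, t2, t3) {
  tb <- params@angles
  key <- .tripleKey(c(t1, t2, t3))
  hit <- which(key == mapply(function(a, b, c) .tripleKey(c(a, b, c)),
                             tb$t1, tb$t2, tb$t3))
  if (!length(hit))
    stop(sprintf("no angle parameter for type triple (%s, %s, %s)",
                 t1, t2, t3))
  list(k = tb$k[hit[1]], theta0 = tb$theta0[hit[1]])
}

#' Dihedral parameter lookup with wildcard fallback
#'
#' Tries the exact quadruple (either direction) first, then the CHARMM
#' wildcard form `X t2 t3 X`.  A dihedral key may carry several terms
#' (multiplicities); all are returned.
#'
#' @inheritParams angleParam
#' @param t4 fourth atom type.
#' @return data.frame with columns `k`, `n`, `delta` (one row per term).
#' @export
dihedralParam <- function(params, t1, t2, t3, t4) {
  tb <- params@dihedrals
  keys <- mapply(function(a, b, c, d) .quadKey(c(a, b, c, d)),
                 tb$t1, tb$t2, tb$t3, tb$t4)
  hit <- which(.quadKey(c(t1, t2, t3, t4)) == keys)
  if (!length(hit))
    hit <- which(.quadKey(c("X", t2, t3, "X")) == keys)
  if (!length(hit))
    stop(sprintf("no dihedral parameter for (%s, %s, %s, %s)",
                 t1, t2, t3, t4))
  tb[hit, c("k", "n", "delta"), drop = FALSE]
}

#' Improper parameter lookup with wildcard fallback
#'
#' Tries the exact quadruple, then `t1 X X t4`.
#'
#' @inheritParams dihedralParam
#' @return list with `k` (kcal/mol/rad^2) and `phi0` (degrees).
#' @export
improperParam <- function(params, t1, t2, t3, t4) {
  tb <- params@impropers
  keys <- mapply(function(a, b, c, d) .quadKey(c(a, b, c, d)),
                 tb$t1, tb$t2, tb$t3, tb$t4)
  hit <- which(.quadKey(c(t1, t2, t3, t4)) == keys)
  if (!length(hit))
    hit <- which(.quadKey(c(t1, "X", "X", t4)) == keys)
  if (!length(hit))
    stop(sprintf("no improper parameter for (%s, %s, %s, %s)",
                 t1, t2, t3, t4))
  list(k = tb$k[hit[1]], phi0 = tb$phi0[hit[1]])
}

#' Nonbonded parameter lookup
#' @inheritParams bondParam
#' @param type CHARMM atom type string.
#' @return list with `eps` (kcal/mol, positive well depth) and `rmin2`
#'   (r_min/2, A).
#' @export
nonbondedParam <- function(params, type) {
  tb <- params@nonbonded
  hit <- which(toupper(type) == toupper(tb$type))
  if (!length(hit))
    stop(sprintf("no nonbonded parameter for atom type %s", type))
  list(eps = tb$eps[hit[1]], rmin2 = tb$rmin2[hit[1]])
}

#' Verify that a ParameterSet is total over a system
#'
#' Checks that every atom type resolves to a nonbonded entry and every bond,
#' angle, dihedral and improper tuple resolves to a parameter entry.
#'
#' @param system a [MolecularSystem-class].
#' @param params a [ParameterSet-class].
#' @return `TRUE`, invisibly; otherwise a typed error naming the first
#'   unresolvable tuple.
#' @export
checkParamsTotal <- function(system, params) {
  ty <- system@atoms$type
  for (t in unique(ty)) nonbondedParam(params, t)
  b <- system@bonds
  for (i in seq_len(nrow(b))) bondParam(params, ty[b[i, 1]], ty[b[i, 2]])
  a <- system@angles
  for (i in seq_len(nrow(a)))
    angleParam(params, ty[a[i, 1]], ty[a[i, 2]], ty[a[i, 3]])
  d <- system@dihedrals
  for (i in seq_len(nrow(d)))
    dihedralParam(params, ty[d[i, 1]], ty[d[i, 2]], ty[d[i, 3]], ty[d[i, 4]])
  im <- system@impropers
  for (i in seq_len(nrow(im)))
    improperParam(params, ty[im[i, 1]], ty[im[i, 2]], ty[im[i, 3]], ty[im[i, 4]])
  invisible(TRUE)
}
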