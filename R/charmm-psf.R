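#' @include AllClasses.R
NULL

## PSF is whitespace-parseable in both the standard and EXT dialects; the
## dialect only changes column widths, which matters for writing, not reading.

.psfSections <- c("NATOM", "NBOND", "NTHETA", "NPHI", "NIMPHI")

#' Read a CHARMM/X-PLOR PSF topology file
#'
#' Parses both the standard and EXT column dialects (auto-detected from the
#' header flags).  X-PLOR alphabetic atom-type names are kept verbatim as the
#' type string.  Coordinates are left unset; read them with
#' [readPDBCoords()].
#'
#' @param path path to the PSF file.
#' @return A [MolecularSystem-class] with coordinates unset.
#' @export
readPSF <- function(path) {
  if (!file.exists(path)) stop("PSF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^PSF", lines[1]))
    stop("not a PSF file (missing PSF header): ", path)

  secAt <- grep("^\\s*\\d+\\s+![A-Z]", lines)
  secName <- sub("^\\s*\\d+\\s+!([A-Z]+).*", "\\1", lines[secAt])
  secCount <- as.integer(sub("^\\s*(\\d+)\\s+!.*", "\\1", lines[secAt]))

  missing <- setdiff(.psfSections, secName)
  if (length(missing))
    stop("PSF missing section(s): ", paste(missing, collapse = ", "))

  sectionBody <- function(name) {
    k <- match(name, secName)
    from <- secAt[k] + 1L
    to <- if (k < length(secAt)) secAt[k + 1L] - 1L else length(lines)
    list(count = secCount[k], lines = lines[seq(from, length.out = max(0, to - from + 1L))],
         offset = secAt[k])
  }

  ## atoms
  at <- sectionBody("NATOM")
  n <- at$count
  body <- at$lines[nzchar(trimws(at$lines))]
  if (length(body) < n)
    stop(sprintf("PSF NATOM declares %d atoms but only %d atom lines found",
                 n, length(body)))
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(toks, length, 0L) < 8L)
  if (length(bad))
    stop(sprintf("unparseable PSF atom line %d", at$offset + bad[1]))
  getf <- function(i) vapply(toks, `[[`, "", i)
  charge <- suppressWarnings(as.numeric(getf(7)))
  mass <- suppressWarnings(as.numeric(getf(8)))
  if (anyNA(charge) || anyNA(mass))
    stop(sprintf("unparseable numeric field on PSF atom line %d",
                 at$offset + which(is.na(charge) | is.na(mass))[1]))
  resid <- suppressWarnings(as.integer(sub("[A-Za-z]+$", "", getf(3))))
  if (anyNA(resid))
    stop(sprintf("unparseable residue id on PSF atom line %d",
                 at$offset + which(is.na(resid))[1]))
  atoms <- data.frame(
    name = getf(5), resname = getf(4), resid = resid, segid = getf(2),
    type = getf(6), charge = charge, mass = mass,
    stringsAsFactors = FALSE)

  readTuples <- function(name, width) {
    sec <- sectionBody(name)
    want <- sec$count * width
    body <- sec$lines[nzchar(trimws(sec$lines))]
    vals <- integer(0)
    for (i in seq_along(body)) {
      v <- suppressWarnings(as.integer(strsplit(trimws(body[i]), "\\s+")[[1]]))
      if (anyNA(v))
        stop(sprintf("unparseable PSF index line %d in %s",
                     sec$offset + i, name))
      vals <- c(vals, v)
      if (length(vals) >= want) break
    }
    if (length(vals) < want)
      stop(sprintf("PSF %s declares %d entries but lists %d indices (%d needed)",
                   name, sec$count, length(vals), want))
    vals <- vals[seq_len(want)]
    matrix(vals, ncol = width, byrow = TRUE)
  }

  bonds <- readTuples("NBOND", 2L)
  angles <- readTuples("NTHETA", 3L)
  dihedrals <- readTuples("NPHI", 4L)
  impropers <- readTuples("NIMPHI", 4L)

  MolecularSystem(atoms, bonds, angles, dihedrals, impropers)
}

#' Write a CHARMM PSF topology file
#'
#' @param system a [MolecularSystem-class].
#' @param path output path.
#' @param ext write the EXT (wide-column) dialect.
#' @return `path`, invisibly.
#' @export
writePSF <- function(system, path, ext = FALSE) {
  a <- system@atoms
  n <- nrow(a)
  out <- c(if (ext) "PSF EXT" else "PSF", "",
           sprintf("%8d !NTITLE", 1L),
           " REMARKS written by ringfree", "")
  atomFmt <- if (ext)
    "%10d %-8s %-8d %-8s %-8s %-6s %10.6f %13.4f %11d"
  else
    "%8d %-4s %-4d %-4s %-4s %-4s %10.6f %13.4f %11d"
  cntFmt <- if (ext) "%10d !%s" else "%8d !%s"
  out <- c(out, sprintf(cntFmt, n, "NATOM"),
           sprintf(atomFmt, seq_len(n), a$segid, a$resid, a$resname,
                   a$name, a$type, a$charge, a$mass, 0L), "")
  idxFmt <- if (ext) "%10d" else "%8d"
  tupleLines <- function(m, perLine) {
    v <- as.integer(t(m))
    if (!length(v)) return(character(0))
    grp <- ceiling(seq_along(v) / (perLine * ncol(m)))
    unname(vapply(split(v, grp),
                  function(x) paste(sprintf(idxFmt, x), collapse = ""), ""))
  }
  out <- c(out,
    sprintf(cntFmt, nrow(system@bonds), "NBOND: bonds"),
    tupleLines(system@bonds, 4L), "",
    sprintf(cntFmt, nrow(system@angles), "NTHETA: angles"),
    tupleLines(system@angles, 3L), "",
    sprintf(cntFmt, nrow(system@dihedrals), "NPHI: dihedrals"),
    tupleLines(system@dihedrals, 2L), "",
    sprintf(cntFmt, nrow(system@impropers), "NIMPHI: impropers"),
    tupleLines(system@impropers, 2L), "")
  writeLines(out, path)
  invisible(path)
}
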