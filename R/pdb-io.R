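#' @include AllClasses.R
NULL

#' Read coordinates from a PDB file into a system
#'
#' Takes x/y/z from the fixed columns of ATOM/HETMATM records, in file order.
#' Occupancy and temperature-factor columns may be absent (they default to 0
#' and are not stored).  The record count must equal the system's atom count.
#'
#' @param path PDB file path.
#' @param system a [MolecularSystem-class] (typically from [readPSF()]).
#' @return The system with coordinates populated (A).
#' @export
readPDBCoords <- function(path, system) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  n <- natoms(system)
  if (length(rec) != n)
    stop(sprintf("PDB atom count (%d) does not match system atom count (%d)",
                 length(rec), n))
  num <- function(l, from, to) {
    s <- trimws(substr(l, from, to))
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop("unparseable coordinate field in PDB record: ",
           rec[which(is.na(v))[1]])
    v
  }
  xyz <- cbind(num(rec, 31, 38), num(rec, 39, 46), num(rec, 47, 54))
  coords(system) <- xyz
  system
}

#' Write a system to a PDB file
#'
#' Emits standard fixed-column ATOM records with 1-based serials, followed by
#' TER and END.
#'
#' @param system a [MolecularSystem-class] with coordinates set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(system, path) {
  xyz <- coords(system)
  if (!nrow(xyz)) stop("system has no coordinates to write")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (any(abs(xyz) > 9999.999))
    stop("coordinate overflows PDB fixed columns (|x| > 9999.999 A); ",
         "recenter the system or use a wider output format")
  a <- system@atoms
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  name4 <- sprintf("%-4s", substr(name4, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
    seq_len(nrow(a)) %% 100000L, name4, substr(a$resname, 1, 4), " ",
    a$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
    substr(a$segid, 1, 4))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Write the converged structure under a run-label-derived name
#'
#' @param system converged [MolecularSystem-class].
#' @param outdir output directory (created if absent).
#' @param label run label; the file is named `<label>-opt.pdb`.
#' @return The path written, invisibly.
#' @export
writeFinalCoords <- function(system, outdir, label = "lbe") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  path <- file.path(outdir, paste0(label, "-opt.pdb"))
  writePDB(system, path)
  invisible(path)
}
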