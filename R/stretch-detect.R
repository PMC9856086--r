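#' @include AllClasses.R
NULL

#' Measure every bond's deviation from its equilibrium length
#'
#' The symptom metric of ring penetration: each bond's Euclidean length is
#' compared against the force-field equilibrium length b0 for its atom-type
#' pair.  Deviation is signed (compressed bonds are negative); flagging is
#' done separately by [flagStretches()] / [selectTargetBonds()] and only ever
#' considers positive deviations.
#'
#' @param system a [MolecularSystem-class] with coordinates set.
#' @param params a [ParameterSet-class] resolving every bond type pair.
#' @return A [StretchReport-class] with flag sets unset.
#' @export
bondDeviations <- function(system, params) {
  b <- system@bonds
  if (!nrow(coords(system))) stop("system has no coordinates")
  ty <- system@atoms$type
  xyz <- coords(system)
  dvec <- xyz[b[, 1], , drop = FALSE] - xyz[b[, 2], , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  b0 <- vapply(seq_len(nrow(b)), function(i)
    bondParam(params, ty[b[i, 1]], ty[b[i, 2]])$b0, 0)
  tb <- data.frame(ai = b[, 1], aj = b[, 2],
                   ti = ty[b[, 1]], tj = ty[b[, 2]],
                   length = len, b0 = b0, deviation = len - b0,
                   stringsAsFactors = FALSE)
  new("StretchReport", table = tb, natoms = natoms(system),
      cutoff = NA_real_, window = NA_real_,
      flagged = integer(0), targets = integer(0))
}

#' The most stretched bond of a report
#'
#' Ties are broken by the smaller first atom index (then smaller second), so
#' repeated runs are reproducible.
#'
#' @param report a [StretchReport-class] with at least one bond.
#' @return list with `bond` (integer pair), `deviation` (A) and `row`.
#' @export
largestDeviation <- function(report) {
  tb <- report@table
  if (!nrow(tb)) stop("empty stretch report")
  mx <- max(tb$deviation)
  cand <- which(tb$deviation == mx)
  cand <- cand[order(tb$ai[cand], tb$aj[cand])]
  row <- cand[1]
  list(bond = c(tb$ai[row], tb$aj[row]), deviation = mx, row = row)
}

#' Flag stretched bonds and select this iteration's targets
#'
#' A bond is flagged when its deviation meets the cutoff (by default the
#' parameter-aware 0.4 A rule; optionally the historic absolute 1.65 A
#' length rule).  Target bonds are the worst offenders: every flagged bond
#' whose deviation is within `window` of the maximum (closed at the
#' boundary, deviation >= max - window).
#'
#' @param report a [StretchReport-class].
#' @param cutoff deviation cutoff in A (default 0.4).
#' @param window worst-bond window in A (default 0.1).
#' @param legacyAbsoluteCutoff flag bonds by absolute length > 1.65 A instead
#'   of by deviation (off by default; kept for comparison with the historic
#'   rule, which misflags bonds to large elements).
#' @return The report with `cutoff`, `window`, `flagged` and `targets` set.
#' @export
flagStretches <- function(report, cutoff = 0.4, window = 0.1,
                          legacyAbsoluteCutoff = FALSE) {
  tb <- report@table
  flagged <- if (legacyAbsoluteCutoff)
    which(tb$length > 1.65)
  else
    which(tb$deviation >= cutoff)
  targets <- integer(0)
  if (length(flagged)) {
    mx <- max(tb$deviation[flagged])
    targets <- flagged[tb$deviation[flagged] >= mx - window]
    targets <- targets[order(tb$ai[targets], tb$aj[targets])]
  }
  initialize(report, cutoff = cutoff, window = window,
             flagged = as.integer(flagged), targets = as.integer(targets))
}

#' Select the target bonds of an iteration
#'
#' Convenience wrapper around [flagStretches()]: empty when the maximum
#' deviation is below the cutoff, otherwise all bonds within `window` of the
#' maximum.
#'
#' @inheritParams flagStretches
#' @return integer matrix with one row per target bond (columns ai, aj).
#' @export
selectTargetBonds <- function(report, cutoff = 0.4, window = 0.1) {
  rep2 <- flagStretches(report, cutoff = cutoff, window = window)
  tb <- rep2@table[rep2@targets, , drop = FALSE]
  cbind(ai = tb$ai, aj = tb$aj)
}

#' Per-atom accumulated deviation field
#'
#' For visualization: each atom receives the sum of the deviations of its
#' incident bonds that are stretched by at least `threshold`; atoms with no
#' such bond get 0.
#'
#' @param report a [StretchReport-class].
#' @param threshold minimum deviation contributing to the field (A).
#' @return numeric vector of length `natoms`.
#' @export
perAtomDeviationField <- function(report, threshold = 0.1) {
  field <- numeric(report@natoms)
  tb <- report@table[report@table$deviation >= threshold, , drop = FALSE]
  for (i in seq_len(nrow(tb))) {
    field[tb$ai[i]] <- field[tb$ai[i]] + tb$deviation[i]
    field[tb$aj[i]] <- field[tb$aj[i]] + tb$deviation[i]
  }
  field
}

#' Write the flagged-bond report to a plain-text file
#'
#' One line per flagged bond: atom indices, names, types, measured length,
#' b0 and deviation.
#'
#' @param report a flagged [StretchReport-class] (see [flagStretches()]).
#' @param system the measured [MolecularSystem-class] (for atom names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStretchReport <- function(report, system, path) {
  tb <- report@table[report@flagged, , drop = FALSE]
  nm <- system@atoms$name
  header <- "ai aj name_i name_j type_i type_j length_A b0_A deviation_A"
  lines <- sprintf("%d %d %s %s %s %s %.4f %.4f %.4f",
                   tb$ai, tb$aj, nm[tb$ai], nm[tb$aj], tb$ti, tb$tj,
                   tb$length, tb$b0, tb$deviation)
  writeLines(c(header, lines), path)
  invisible(path)
}
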