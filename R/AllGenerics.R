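#' @include AllClasses.R
NULL

#' Number of atoms in a system
#' @param x a [MolecularSystem-class]
#' @return integer atom count
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))

#' @rdname natoms
#' @export
setMethod("natoms", "MolecularSystem", function(x) nrow(x@atoms))

#' Atom metadata table
#' @param x a [MolecularSystem-class]
#' @return data.frame of per-atom metadata
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname atomData
#' @export
setMethod("atomData", "MolecularSystem", function(x) x@atoms)

#' Bond list
#' @param x a [MolecularSystem-class]
#' @return integer matrix, one row per bond
#' @export
setGeneric("bondList", function(x) standardGeneric("bondList"))

#' @rdname bondList
#' @export
setMethod("bondList", "MolecularSystem", function(x) x@bonds)

#' Coordinates accessor
#' @param x a [MolecularSystem-class]
#' @return numeric natoms x 3 matrix (A); zero rows when unset
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "MolecularSystem", function(x) x@coords)

#' @rdname coords
#' @param value replacement natoms x 3 coordinate matrix
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname coords
#' @export
setMethod("coords<-", "MolecularSystem", function(x, value) {
  x@coords <- matrix(as.numeric(value), ncol = 3)
  validObject(x)
  x
})

#' @export
setMethod("show", "MolecularSystem", function(object) {
  cat(sprintf(
    "MolecularSystem: %d atoms, %d bonds, %d angles, %d dihedrals, %d impropers; coordinates %s\n",
    natoms(object), nrow(object@bonds), nrow(object@angles),
    nrow(object@dihedrals), nrow(object@impropers),
    if (nrow(object@coords)) "set" else "unset"))
  invisible(object)
})

#' @export
setMethod("show", "ParameterSet", function(object) {
  cat(sprintf(
    "ParameterSet: %d bond, %d angle, %d dihedral, %d improper, %d nonbonded entries\n",
    nrow(object@bonds), nrow(object@angles), nrow(object@dihedrals),
    nrow(object@impropers), nrow(object@nonbonded)))
  invisible(object)
})

#' @export
setMethod("show", "StretchReport", function(object) {
  n <- nrow(object@table)
  mx <- if (n) max(object@table$deviation) else NA_real_
  cat(sprintf(
    "StretchReport: %d bonds, max deviation %.3f A, %d flagged, %d targeted\n",
    n, mx, length(object@flagged), length(object@targets)))
  invisible(object)
})

#' @export
setMethod("show", "EnergyModel", function(object) {
  on <- names(object@terms)[object@terms]
  cat(sprintf(
    paste0("EnergyModel: terms [%s]; dielectric %.1f; cutoff %.1f/%.1f A; ",
           "%d flagged atoms; %d point pulls, %d separation biases, ",
           "%d hills, %d chirality restraints\n"),
    paste(on, collapse = ","), object@dielectric, object@switchOn,
    object@nbCutoff, length(object@flagged), nrow(object@pointRestraints),
    length(object@sepBiases), length(object@hills),
    nrow(object@chiralRestraints)))
  invisible(object)
})

#' @export
setMethod("show", "WorkflowState", function(object) {
  cat(sprintf("WorkflowState: %d stage(s) completed, status %s\n",
              object@stage, object@status))
  invisible(object)
})

#' @export
setMethod("show", "FixtureBundle", function(object) {
  cat(sprintf(
    "FixtureBundle: %d atoms; manifest: %d piercing(s), %d chiral center(s)\n",
    natoms(object@system), object@manifest$piercings,
    object@manifest$chiralCenters))
  invisible(object)
})

#' @export
setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    paste0("RunConfig: structure=%s, coords=%s, %d parameter file(s); ",
           "cutoff %.2f A, window %.2f A, %d stages x %d steps, ",
           "dielectric %.0f, nb cutoff %.0f A, chirality %s\n"),
    object@structure, object@coordinates, length(object@parameters),
    object@cutoff, object@window, object@maxStages, object@stepsPerStage,
    object@dielectric, object@nbCutoff,
    if (object@chirality) "on" else "off"))
  invisible(object)
})
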