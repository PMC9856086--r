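#' @include bias-engine.R minimize.R stretch-detect.R pdb-io.R run-config.R
NULL

#' Branch decision of the repair loop
#'
#' The two gray diamonds of the workflow: a stretched bond at or above the
#' cutoff sends the loop down the biased branch; otherwise, if the previous
#' minimization carried perturbations, one certifying round without them is
#' run; only an unperturbed round below the cutoff terminates the loop.
#'
#' @param maxDeviation largest bond deviation of the stage (A).
#' @param cutoff convergence cutoff (A, > 0).
#' @param previousPerturbed whether the minimization just completed carried
#'   bias/soft-core terms.
#' @return `"BIASED_ROUND"`, `"UNPERTURBED_ROUND"` or `"DONE"`.
#' @export
decideBranch <- function(maxDeviation, cutoff, previousPerturbed) {
  stopifnot(cutoff > 0)
  if (maxDeviation >= cutoff) return("BIASED_ROUND")
  if (previousPerturbed) return("UNPERTURBED_ROUND")
  "DONE"
}

#' Run the iterative long-bond repair loop
#'
#' Per stage: a bounded minimization under the current model, a stretch
#' report, a trace entry and a branch decision.  The biased branch targets
#' the worst bonds (within `window` of the maximum deviation), escalates
#' force constants for a bond that stays longest across iterations, attaches
#' perpendicular pulls, a separation bias and a density hill, and softens the
#' nonbonded interactions of atoms near each target midpoint.  Convergence is
#' only ever certified by an unperturbed stage.  Chirality restraints are
#' generated once from the input structure and stay active throughout when
#' enabled.
#'
#' @param config a [RunConfig-class].
#' @param system,params optional in-memory inputs; when `NULL` they are read
#'   from the config paths.
#' @param writeOutputs write the final PDB, trace, long-bond report and log
#'   into `config@outdir` (default TRUE when inputs come from files).
#' @return list with `system` (final coordinates), `state`
#'   ([WorkflowState-class]) and `exitStatus` (0 converged, 1 stage cap).
#' @export
runLBE <- function(config, system = NULL, params = NULL,
                   writeOutputs = is.null(system)) {
  stopifnot(is(config, "RunConfig"))
  force(writeOutputs)       # must see `system` before it is reassigned
  if (is.null(system)) {
    system <- readPSF(config@structure)
    system <- readPDBCoords(config@coordinates, system)
  }
  if (is.null(params)) params <- readParameters(config@parameters)
  checkParamsTotal(system, params)

  graph <- buildGraph(system)
  rings <- enumerateSmallRings(graph)
  ff <- compileForceField(system, params)
  model <- EnergyModel(dielectric = config@dielectric,
                       nbCutoff = config@nbCutoff,
                       switchOn = config@switchOn,
                       softcoreDelta = config@softcoreDelta)
  if (config@chirality) {
    centers <- detectChiralCenters(system)
    model <- setChiralRestraints(
      model, generateChiralityRestraints(centers, coords(system),
                                         k = config@chiralityK))
  }
  set.seed(config@seed)
  state <- BiasState()
  log <- character(0)

  rep0 <- bondDeviations(system, params)
  ld0 <- largestDeviation(rep0)
  trace <- data.frame(stage = 0L, ai = ld0$bond[1], aj = ld0$bond[2],
                      deviation = ld0$deviation, perturbed = FALSE,
                      branch = "", stringsAsFactors = FALSE)

  perturbed <- FALSE   # does the model carry bias terms right now?
  stage <- 0L
  status <- "stage-cap"
  converged <- FALSE
  intermediates <- list()
  finalReport <- rep0

  while (stage < config@maxStages) {
    res <- minimizeSystem(system, params, model,
                          steps = config@stepsPerStage, ff = ff)
    system <- res@system
    stage <- stage + 1L
    rep <- bondDeviations(system, params)
    finalReport <- rep
    ld <- largestDeviation(rep)
    branch <- decideBranch(ld$deviation, config@cutoff, perturbed)
    trace <- rbind(trace, data.frame(
      stage = stage, ai = ld$bond[1], aj = ld$bond[2],
      deviation = ld$deviation, perturbed = perturbed, branch = branch,
      stringsAsFactors = FALSE))
    log <- c(log, sprintf(
      "stage %d: perturbed=%s longest=(%d,%d) deviation=%.4f branch=%s",
      stage, perturbed, ld$bond[1], ld$bond[2], ld$deviation, branch))
    if (config@writeIntermediates)
      intermediates[[stage]] <- coords(system)

    if (branch == "DONE") {
      status <- "converged"
      converged <- TRUE
      break
    } else if (branch == "UNPERTURBED_ROUND") {
      cl <- clearBiases(model, state)
      model <- cl$model
      state <- cl$state
      perturbed <- FALSE
    } else {
      targets <- selectTargetBonds(rep, cutoff = config@cutoff,
                                   window = config@window)
      state <- escalateBiases(state, ld$bond)
      cl <- clearBiases(model, state)
      bb <- buildBiases(system, targets, graph, cl$state, cl$model,
                        rings = rings,
                        pointK = config@pointK, sepK = config@sepK,
                        sepTarget = config@sepTarget,
                        hillHeight = config@hillHeight,
                        hillRadius = config@hillRadius,
                        perpDistance = config@perpDistance,
                        nearbyRadius = config@nearbyRadius)
      model <- bb$model
      state <- bb$state
      perturbed <- TRUE
      for (key in names(state@records)) {
        rec <- state@records[[key]]
        log <- c(log, sprintf(
          "  target %s: pointK=%.3g sepK=%.3g hill=%.3g count=%d",
          key, rec$pointK, rec$sepK, rec$hillHeight, rec$count))
      }
    }
  }

  wf <- new("WorkflowState", stage = stage, prevPerturbed = perturbed,
            trace = trace, bias = state, converged = converged,
            status = status, intermediates = intermediates)

  if (writeOutputs) {
    outdir <- config@outdir
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    writeFinalCoords(system, outdir, config@label)
    writeTrace(wf, file.path(outdir, paste0(config@label, "-trace.tsv")))
    flagged <- flagStretches(finalReport, cutoff = config@cutoff,
                             window = config@window,
                             legacyAbsoluteCutoff = config@legacyAbsoluteCutoff)
    writeStretchReport(flagged, system,
                       file.path(outdir, paste0(config@label, "-longbonds.txt")))
    writeLines(log, file.path(outdir, paste0(config@label, "-log.txt")))
    if (config@writeIntermediates) {
      for (s in seq_along(intermediates)) {
        snap <- system
        coords(snap) <- intermediates[[s]]
        writePDB(snap, file.path(outdir,
                 sprintf("%s-stage%03d.pdb", config@label, s)))
      }
    }
  }

  list(system = system, state = wf,
       exitStatus = if (converged) 0L else 1L)
}

#' Longest-bond trace of a run
#'
#' Stage 0 is the unminimized input structure; one row follows per completed
#' stage.
#'
#' @param state a [WorkflowState-class] from [runLBE()].
#' @return data.frame `stage, ai, aj, deviation, perturbed, branch`.
#' @export
longestBondTrace <- function(state) state@trace

#' Write / read the longest-bond trace as a delimited text file
#'
#' @param state a [WorkflowState-class].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
writeTrace <- function(state, path) {
  utils::write.table(state@trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @return `readTrace`: the trace data.frame.
#' @export
readTrace <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("integer", "integer", "integer",
                                   "numeric", "logical", "character"),
                    na.strings = NULL)
}

#' Detection-only report of a system
#'
#' Runs the three detectors without modifying coordinates: the stretch
#' report, the geometric piercing events and the chiral-center inventory.
#'
#' @param config a [RunConfig-class].
#' @param system,params optional in-memory inputs (read from config paths
#'   when `NULL`).
#' @return list with `stretch` (flagged [StretchReport-class]), `piercings`
#'   (event data.frame) and `chiralCenters` (data.frame).
#' @export
detectArtifacts <- function(config, system = NULL, params = NULL) {
  if (is.null(system)) {
    system <- readPSF(config@structure)
    system <- readPDBCoords(config@coordinates, system)
  }
  if (is.null(params)) params <- readParameters(config@parameters)
  rep <- flagStretches(bondDeviations(system, params),
                       cutoff = config@cutoff, window = config@window,
                       legacyAbsoluteCutoff = config@legacyAbsoluteCutoff)
  list(stretch = rep, piercings = findPiercings(system),
       chiralCenters = detectChiralCenters(system))
}
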