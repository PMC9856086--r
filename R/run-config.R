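#' @include AllClasses.R
NULL

.configDefaults <- function() list(
  cutoff = 0.4, window = 0.1, maxstages = 100L, stepsperstage = 500L,
  dielectric = 80, nbcutoff = 12, switchon = 10,
  chirality = TRUE, writeintermediates = FALSE, seed = 1L,
  pointk = 10, sepk = 10, septarget = 10, hillheight = 20, hillradius = 4,
  chiralityk = 50, softcoredelta = 2.5, perpdistance = 10, nearbyradius = 4,
  legacyabsolutecutoff = FALSE, label = "lbe", outdir = "."
)

#' Construct a RunConfig programmatically
#'
#' All loop parameters take the same defaults as an empty configuration
#' file; input paths may be left blank when the system and parameters are
#' passed to [runLBE()] in memory.
#'
#' @param structure,coordinates PSF / PDB paths (may be blank for in-memory
#'   runs).
#' @param parameters character vector of parameter file paths.
#' @param ... any [RunConfig-class] slot by name (e.g. `cutoff`, `seed`,
#'   `maxStages`, `chirality`).
#' @return A validated [RunConfig-class].
#' @export
RunConfig <- function(structure = "", coordinates = "",
                      parameters = character(0), ...) {
  d <- .configDefaults()
  over <- list(...)
  slotNames <- c(cutoff = "cutoff", window = "window",
                 maxStages = "maxstages", stepsPerStage = "stepsperstage",
                 dielectric = "dielectric", nbCutoff = "nbcutoff",
                 switchOn = "switchon", chirality = "chirality",
                 writeIntermediates = "writeintermediates", seed = "seed",
                 pointK = "pointk", sepK = "sepk", sepTarget = "septarget",
                 hillHeight = "hillheight", hillRadius = "hillradius",
                 chiralityK = "chiralityk", softcoreDelta = "softcoredelta",
                 perpDistance = "perpdistance", nearbyRadius = "nearbyradius",
                 legacyAbsoluteCutoff = "legacyabsolutecutoff",
                 label = "label", outdir = "outdir")
  bad <- setdiff(names(over), names(slotNames))
  if (length(bad)) stop("unknown RunConfig argument(s): ",
                        paste(bad, collapse = ", "))
  val <- function(nm) {
    if (nm %in% names(over)) over[[nm]] else d[[slotNames[[nm]]]]
  }
  new("RunConfig",
      structure = structure, coordinates = coordinates,
      parameters = parameters,
      cutoff = as.numeric(val("cutoff")), window = as.numeric(val("window")),
      maxStages = as.integer(val("maxStages")),
      stepsPerStage = as.integer(val("stepsPerStage")),
      dielectric = as.numeric(val("dielectric")),
      nbCutoff = as.numeric(val("nbCutoff")),
      switchOn = as.numeric(val("switchOn")),
      chirality = as.logical(val("chirality")),
      writeIntermediates = as.logical(val("writeIntermediates")),
      seed = as.integer(val("seed")),
      pointK = as.numeric(val("pointK")), sepK = as.numeric(val("sepK")),
      sepTarget = as.numeric(val("sepTarget")),
      hillHeight = as.numeric(val("hillHeight")),
      hillRadius = as.numeric(val("hillRadius")),
      chiralityK = as.numeric(val("chiralityK")),
      softcoreDelta = as.numeric(val("softcoreDelta")),
      perpDistance = as.numeric(val("perpDistance")),
      nearbyRadius = as.numeric(val("nearbyRadius")),
      legacyAbsoluteCutoff = as.logical(val("legacyAbsoluteCutoff")),
      label = as.character(val("label")),
      outdir = as.character(val("outdir")))
}

#' Parse a run-configuration file
#'
#' The configuration is a flat key-value YAML document.  `structure`,
#' `coordinates` and `parameters` are required; every other key falls back to
#' the documented default ([RunConfig-class]).  Keys are case-insensitive;
#' unknown keys raise a warning, not an error.  Paths are resolved relative
#' to the configuration file's directory.
#'
#' @param path configuration file path.
#' @return A validated [RunConfig-class].
#' @export
parseRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a flat key-value document")
  names(raw) <- tolower(names(raw))
  defaults <- .configDefaults()
  known <- c("structure", "coordinates", "parameters", names(defaults))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  missing <- setdiff(c("structure", "coordinates", "parameters"), names(raw))
  if (length(missing))
    stop("config missing required key(s): ", paste(missing, collapse = ", "))

  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    p <- as.character(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  get <- function(key) if (key %in% names(raw)) raw[[key]] else defaults[[key]]
  new("RunConfig",
      structure = resolve(raw$structure),
      coordinates = resolve(raw$coordinates),
      parameters = resolve(unlist(raw$parameters)),
      cutoff = as.numeric(get("cutoff")),
      window = as.numeric(get("window")),
      maxStages = as.integer(get("maxstages")),
      stepsPerStage = as.integer(get("stepsperstage")),
      dielectric = as.numeric(get("dielectric")),
      nbCutoff = as.numeric(get("nbcutoff")),
      switchOn = as.numeric(get("switchon")),
      chirality = as.logical(get("chirality")),
      writeIntermediates = as.logical(get("writeintermediates")),
      seed = as.integer(get("seed")),
      pointK = as.numeric(get("pointk")),
      sepK = as.numeric(get("sepk")),
      sepTarget = as.numeric(get("septarget")),
      hillHeight = as.numeric(get("hillheight")),
      hillRadius = as.numeric(get("hillradius")),
      chiralityK = as.numeric(get("chiralityk")),
      softcoreDelta = as.numeric(get("softcoredelta")),
      perpDistance = as.numeric(get("perpdistance")),
      nearbyRadius = as.numeric(get("nearbyradius")),
      legacyAbsoluteCutoff = as.logical(get("legacyabsolutecutoff")),
      label = as.character(get("label")),
      outdir = if ("outdir" %in% names(raw)) resolve(raw$outdir) else base)
}

#' Serialize a RunConfig back to a YAML file
#'
#' Re-parsing the written file yields an equivalent configuration
#' (idempotence), with paths already absolute.
#'
#' @param config a [RunConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  x <- list(
    structure = config@structure, coordinates = config@coordinates,
    parameters = as.list(config@parameters),
    cutoff = config@cutoff, window = config@window,
    maxstages = config@maxStages, stepsperstage = config@stepsPerStage,
    dielectric = config@dielectric, nbcutoff = config@nbCutoff,
    switchon = config@switchOn, chirality = config@chirality,
    writeintermediates = config@writeIntermediates, seed = config@seed,
    pointk = config@pointK, sepk = config@sepK, septarget = config@sepTarget,
    hillheight = config@hillHeight, hillradius = config@hillRadius,
    chiralityk = config@chiralityK, softcoredelta = config@softcoreDelta,
    perpdistance = config@perpDistance, nearbyradius = config@nearbyRadius,
    legacyabsolutecutoff = config@legacyAbsoluteCutoff,
    label = config@label, outdir = config@outdir)
  yaml::write_yaml(x, path)
  invisible(path)
}
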