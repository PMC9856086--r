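test_that("PSF writer/reader round-trips both column dialects", {
  sys <- benzeneEthane()@system
  std <- tempfile(fileext = ".psf")
  ext <- tempfile(fileext = ".psf")
  writePSF(sys, std)
  writePSF(sys, ext, ext = TRUE)
  expect_match(readLines(ext, n = 1), "EXT")

  for (path in c(std, ext)) {
    got <- readPSF(path)
    expect_equal(natoms(got), 20L)
    expect_equal(bondList(got), bondList(sys))
    expect_equal(got@angles, sys@angles)
    expect_equal(got@dihedrals, sys@dihedrals)
    expect_equal(atomData(got)$type, atomData(sys)$type)
    expect_equal(atomData(got)$charge, atomData(sys)$charge,
                 tolerance = 1e-6)
    expect_equal(nrow(coords(got)), 0L)   # coordinates unset
  }
})

test_that("malformed PSF inputs raise parse errors", {
  sys <- benzeneEthane()@system
  path <- tempfile(fileext = ".psf")
  writePSF(sys, path)
  lines <- readLines(path)

  ## declared bond count one higher than the listed pairs
  i <- grep("!NBOND", lines)
  n0 <- as.integer(sub("^\\s*(\\d+)\\s+!NBOND.*", "\\1", lines[i]))
  bad <- lines
  bad[i] <- sub(as.character(n0), as.character(n0 + 1L), bad[i])
  f1 <- tempfile(); writeLines(bad, f1)
  expect_error(readPSF(f1), "NBOND")

  ## a section removed entirely
  drop <- lines[!grepl("NIMPHI", lines)]
  f2 <- tempfile(); writeLines(drop, f2)
  expect_error(readPSF(f2), "NIMPHI")

  ## unparseable numeric field on an atom line
  garbled <- lines
  i <- grep("C1", garbled)[1]
  garbled[i] <- sub("12\\.0110", "twelve", garbled[i])
  f3 <- tempfile(); writeLines(garbled, f3)
  expect_error(readPSF(f3), "line")

  expect_error(readPSF(tempfile()), "not found")
})

test_that("parameter files parse with symmetry, override and comments", {
  p <- miniParams(c("* test", "BONDS",
                    "CA CA 305.000 1.3750 ! aromatic",
                    "CT OT 400.0 1.42",
                    "NONBONDED", "CA 0.0 -0.07 1.99", "CT 0.0 -0.08 2.04",
                    "OT 0.0 -0.1 1.7"))
  expect_equal(bondParam(p, "CA", "CA")$b0, 1.375)
  expect_equal(bondParam(p, "OT", "CT"), bondParam(p, "CT", "OT"))
  expect_error(bondParam(p, "CA", "ZZ"), "ZZ")

  ## a later file overrides an earlier entry for the same key
  f1 <- tempfile(); writeLines(c("BONDS", "CT CT 222.5 1.528"), f1)
  f2 <- tempfile(); writeLines(c("BONDS", "CT CT 222.5 1.60"), f2)
  p2 <- readParameters(c(f1, f2))
  expect_equal(bondParam(p2, "CT", "CT")$b0, 1.60)

  ## no BONDS block anywhere -> error
  f3 <- tempfile(); writeLines(c("NONBONDED", "CA 0.0 -0.07 1.99"), f3)
  expect_error(readParameters(f3), "BONDS")

  ## malformed numeric field
  f4 <- tempfile(); writeLines(c("BONDS", "CT CT eek 1.5"), f4)
  expect_error(readParameters(f4), "malformed")
})

test_that("dihedral lookups fall back to wildcards and keep multiplicities", {
  p <- miniParams(c("BONDS", "CT CT 222.5 1.528",
                    "DIHEDRALS",
                    "X  CT CT X  0.19 3 0.0",
                    "CA CT CT CA 0.10 2 180.0",
                    "CA CT CT CA 0.05 3 0.0"))
  exact <- dihedralParam(p, "CA", "CT", "CT", "CA")
  expect_equal(nrow(exact), 2L)        # both multiplicity terms
  wild <- dihedralParam(p, "HA", "CT", "CT", "HA")
  expect_equal(wild$k, 0.19)
  expect_equal(wild$n, 3L)
  expect_error(dihedralParam(p, "HA", "OS", "OS", "HA"), "dihedral")
})

test_that("PDB coordinates round-trip at column precision", {
  sys <- benzeneEthane()@system
  path <- tempfile(fileext = ".pdb")
  writePDB(sys, path)
  blank <- sys
  blank@coords <- matrix(numeric(0), ncol = 3)
  got <- readPDBCoords(path, blank)
  expect_equal(coords(got), coords(sys), tolerance = 1e-3)
})

test_that("PDB contract errors: count mismatch, overflow, sparse columns", {
  sys <- benzeneEthane()@system
  path <- tempfile(fileext = ".pdb")
  writePDB(sys, path)

  lines <- readLines(path)
  short <- lines[-grep("^ATOM", lines)[1]]
  f <- tempfile(); writeLines(short, f)
  expect_error(readPDBCoords(f, sys), "does not match")

  far <- sys
  xyz <- coords(far); xyz[1, 1] <- 123456
  far@coords <- xyz
  expect_error(writePDB(far, tempfile()), "overflow")

  ## records truncated after the z column still parse; occ/beta default
  trimmed <- lines
  atomRows <- grep("^ATOM", trimmed)
  trimmed[atomRows] <- substr(trimmed[atomRows], 1, 54)
  f2 <- tempfile(); writeLines(trimmed, f2)
  got <- readPDBCoords(f2, sys)
  expect_equal(coords(got), coords(sys), tolerance = 1e-3)
})

test_that("run config defaults, overrides and error contracts", {
  dir <- tempfile(); dir.create(dir)
  writeLines("x", file.path(dir, "s.psf"))
  cfg <- file.path(dir, "run.yaml")

  yaml::write_yaml(list(structure = "s.psf", coordinates = "c.pdb",
                        parameters = list("p.prm")), cfg)
  rc <- parseRunConfig(cfg)
  expect_equal(rc@cutoff, 0.4)
  expect_equal(rc@window, 0.1)
  expect_equal(rc@maxStages, 100L)
  expect_equal(rc@stepsPerStage, 500L)
  expect_equal(rc@dielectric, 80)
  expect_equal(rc@nbCutoff, 12)
  expect_true(rc@chirality)
  expect_match(rc@structure, dir, fixed = TRUE)  # resolved relative to file

  yaml::write_yaml(list(structure = "s.psf", coordinates = "c.pdb",
                        parameters = list("p.prm"), cutoff = 0.2), cfg)
  expect_equal(parseRunConfig(cfg)@cutoff, 0.2)

  yaml::write_yaml(list(structure = "s.psf", coordinates = "c.pdb"), cfg)
  expect_error(parseRunConfig(cfg), "parameters")

  yaml::write_yaml(list(structure = "s.psf", coordinates = "c.pdb",
                        parameters = list("p.prm"), pizzazz = 9), cfg)
  expect_warning(parseRunConfig(cfg), "pizzazz")
})

test_that("run config serialization is idempotent", {
  dir <- tempfile(); dir.create(dir)
  cfg <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(structure = "s.psf", coordinates = "c.pdb",
                        parameters = list("p.prm"), cutoff = 0.3,
                        seed = 11L), cfg)
  rc1 <- parseRunConfig(cfg)
  cfg2 <- file.path(dir, "run2.yaml")
  writeRunConfig(rc1, cfg2)
  rc2 <- parseRunConfig(cfg2)
  for (sl in slotNames("RunConfig"))
    expect_equal(slot(rc2, sl), slot(rc1, sl), info = sl)
})
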