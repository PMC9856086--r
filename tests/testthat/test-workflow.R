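test_that("the branch decision reproduces the loop's three outcomes", {
  expect_equal(decideBranch(0.6, 0.4, FALSE), "BIASED_ROUND")
  expect_equal(decideBranch(0.2, 0.4, TRUE), "UNPERTURBED_ROUND")
  expect_equal(decideBranch(0.2, 0.4, FALSE), "DONE")
  expect_equal(decideBranch(0.4, 0.4, TRUE), "BIASED_ROUND")  # closed cutoff
  expect_error(decideBranch(0.5, 0, FALSE))
})

test_that("a clean structure takes the minimum path: one unperturbed stage", {
  fx <- cleanPolymer()
  out <- runLBE(testConfig(label = "clean"), system = fx@system,
                params = fx@params)
  expect_equal(out$exitStatus, 0L)
  expect_equal(out$state@stage, 1L)
  expect_true(out$state@converged)
  tr <- longestBondTrace(out$state)
  expect_equal(nrow(tr), 2L)                     # row 0 plus one stage
  expect_equal(tr$branch[2], "DONE")
  expect_false(any(tr$perturbed))
  expect_length(out$state@bias@records, 0L)      # no biases ever built
})

test_that("the stage cap terminates the loop with a nonzero exit status", {
  fx <- benzeneEthane()
  out <- runLBE(testConfig(label = "capped", maxStages = 1L),
                system = fx@system, params = fx@params)
  expect_equal(out$exitStatus, 1L)
  expect_equal(out$state@status, "stage-cap")
  expect_equal(nrow(longestBondTrace(out$state)), 2L)
})

test_that("convergence is only certified by an unperturbed stage", {
  fx <- benzeneEthane()
  out <- runLBE(testConfig(label = "cert"), system = fx@system,
                params = fx@params)
  tr <- longestBondTrace(out$state)
  expect_true(out$state@converged)
  final <- tr[nrow(tr), ]
  expect_equal(final$branch, "DONE")
  expect_false(final$perturbed)
  expect_lt(final$deviation, 0.4)
  ## the run actually exercised the biased branch first
  expect_true("BIASED_ROUND" %in% tr$branch)
})

test_that("trace rows start at the unminimized input and round-trip", {
  fx <- benzeneEthane()
  out <- runLBE(testConfig(label = "tr"), system = fx@system,
                params = fx@params)
  tr <- longestBondTrace(out$state)
  expect_equal(tr$stage[1], 0L)
  rep0 <- bondDeviations(fx@system, fx@params)
  expect_equal(tr$deviation[1], largestDeviation(rep0)$deviation,
               tolerance = 1e-9)

  path <- tempfile(fileext = ".tsv")
  writeTrace(out$state, path)
  expect_equal(readTrace(path), tr)
})

test_that("runs are deterministic for a fixed seed", {
  fx <- benzeneEthane()
  o1 <- runLBE(testConfig(label = "d1", seed = 42L), system = fx@system,
               params = fx@params)
  o2 <- runLBE(testConfig(label = "d2", seed = 42L), system = fx@system,
               params = fx@params)
  expect_equal(longestBondTrace(o1$state), longestBondTrace(o2$state))
  expect_equal(coords(o1$system), coords(o2$system))
})

test_that("piercing counts never increase across a full run", {
  for (fx in list(benzeneEthane(), toyPolymer(), glycoToy())) {
    before <- nrow(findPiercings(fx@system))
    out <- runLBE(testConfig(label = "mono"), system = fx@system,
                  params = fx@params)
    expect_lte(nrow(findPiercings(out$system)), before)
  }
})

test_that("a file-driven run writes coordinates, trace, report and log", {
  dir <- tempfile(); dir.create(dir)
  writeFixture(benzeneEthane(), dir, "bnz")
  cfg <- parseRunConfig(file.path(dir, "bnz.yaml"))
  out <- runLBE(cfg)
  expect_equal(out$exitStatus, 0L)
  expect_true(file.exists(file.path(dir, "bnz-opt.pdb")))
  expect_true(file.exists(file.path(dir, "bnz-trace.tsv")))
  expect_true(file.exists(file.path(dir, "bnz-longbonds.txt")))
  expect_true(file.exists(file.path(dir, "bnz-log.txt")))

  ## the written coordinates are the converged structure
  final <- readPDBCoords(file.path(dir, "bnz-opt.pdb"),
                         readPSF(file.path(dir, "bnz.psf")))
  expect_equal(nrow(findPiercings(final)), 0L)
})

test_that("intermediate snapshots are written when requested", {
  fx <- benzeneEthane()
  dir <- tempfile(); dir.create(dir)
  writeFixture(fx, dir, "b")
  cfg <- parseRunConfig(file.path(dir, "b.yaml"))
  cfg@writeIntermediates <- TRUE
  out <- runLBE(cfg)
  snaps <- list.files(dir, pattern = "^b-stage[0-9]+\\.pdb$")
  expect_equal(length(snaps), out$state@stage)
})

test_that("detection-only reporting flags artifacts without moving atoms", {
  fx <- benzeneEthane()
  rep <- detectArtifacts(testConfig(), system = fx@system,
                         params = fx@params)
  expect_s4_class(rep$stretch, "StretchReport")
  expect_equal(nrow(rep$piercings), 1L)
  expect_equal(nrow(rep$chiralCenters), 0L)
  expect_gte(length(rep$stretch@flagged), 1L)
})
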