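## a report built directly, for pure selection-rule tests
syntheticReport <- function(devs, bonds = cbind(seq_along(devs),
                                                seq_along(devs) + 10L)) {
  b0 <- rep(1.5, length(devs))
  new("StretchReport",
      table = data.frame(ai = bonds[, 1], aj = bonds[, 2],
                         ti = rep("CT", length(devs)),
                         tj = rep("CT", length(devs)),
                         length = b0 + devs, b0 = b0, deviation = devs,
                         stringsAsFactors = FALSE),
      natoms = as.integer(max(bonds, 1L)), cutoff = NA_real_,
      window = NA_real_,
      flagged = integer(0), targets = integer(0))
}

test_that("bond deviations are length minus equilibrium length", {
  p <- miniParams(c("BONDS", "CT CT 222.5 1.53",
                    "NONBONDED", "CT 0.0 -0.078 2.04"))
  sys <- miniSystem(c("CT", "CT"), rbind(c(0, 0, 0), c(2.10, 0, 0)),
                    bonds = matrix(c(1L, 2L), 1))
  rep <- bondDeviations(sys, p)
  expect_equal(rep@table$deviation, 0.57)

  at_eq <- miniSystem(c("CT", "CT"), rbind(c(0, 0, 0), c(1.53, 0, 0)),
                      bonds = matrix(c(1L, 2L), 1))
  expect_equal(bondDeviations(at_eq, p)@table$deviation, 0)

  ## unresolvable type pair names the pair
  bad <- miniSystem(c("CT", "ZZ"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                    bonds = matrix(c(1L, 2L), 1))
  expect_error(bondDeviations(bad, p), "ZZ")
})

test_that("deviations match a brute-force scan on a fixture", {
  fx <- toyPolymer()
  rep <- bondDeviations(fx@system, fx@params)
  xyz <- coords(fx@system)
  ty <- atomData(fx@system)$type
  b <- bondList(fx@system)
  for (i in sample(nrow(b), 15)) {
    len <- sqrt(sum((xyz[b[i, 1], ] - xyz[b[i, 2], ])^2))
    b0 <- bondParam(fx@params, ty[b[i, 1]], ty[b[i, 2]])$b0
    expect_equal(rep@table$deviation[i], len - b0, tolerance = 1e-10)
  }
})

test_that("largest deviation picks the maximum with index tie-breaking", {
  r <- syntheticReport(c(-0.02, 0.57, 0.31))
  expect_equal(largestDeviation(r)$deviation, 0.57)
  expect_equal(largestDeviation(r)$bond, c(2L, 12L))

  allEq <- syntheticReport(c(0, 0))
  expect_equal(largestDeviation(allEq)$deviation, 0)   # not an error

  tie <- syntheticReport(c(0.50, 0.50), bonds = rbind(c(3L, 9L), c(1L, 4L)))
  expect_equal(largestDeviation(tie)$bond, c(1L, 4L))

  empty <- syntheticReport(numeric(0), bonds = matrix(integer(0), ncol = 2))
  expect_error(largestDeviation(empty), "empty")
})

test_that("target selection keeps the worst bonds within the window", {
  r <- syntheticReport(c(1.20, 1.15, 1.05, 0.60))
  tb <- selectTargetBonds(r, cutoff = 0.4, window = 0.1)
  expect_equal(tb[, "ai"], c(1L, 2L))   # 1.20 and 1.15 (closed boundary)

  below <- syntheticReport(c(0.35, 0.2))
  expect_equal(nrow(selectTargetBonds(below, cutoff = 0.4)), 0L)

  argmax <- selectTargetBonds(r, cutoff = 0.4, window = 0)
  expect_equal(unname(argmax[, "ai"]), 1L)

  ## monotone (non-shrinking) in window
  n1 <- nrow(selectTargetBonds(r, 0.4, 0.05))
  n2 <- nrow(selectTargetBonds(r, 0.4, 0.25))
  expect_true(n2 >= n1)
})

test_that("flagging respects the deviation cutoff and the legacy length rule", {
  ## near-equilibrium structure: nothing flagged (the minimum-path condition)
  clean <- cleanPolymer()
  res <- minimizeSystem(clean@system, clean@params, EnergyModel(),
                        steps = 500)
  rep <- flagStretches(bondDeviations(res@system, clean@params))
  expect_length(rep@flagged, 0L)

  ## a 1.70 A bond is fine by deviation (0.17) but long by the legacy rule
  p <- miniParams(c("BONDS", "CT CT 222.5 1.53",
                    "NONBONDED", "CT 0.0 -0.078 2.04"))
  sys <- miniSystem(c("CT", "CT"), rbind(c(0, 0, 0), c(1.70, 0, 0)),
                    bonds = matrix(c(1L, 2L), 1))
  rep2 <- bondDeviations(sys, p)
  expect_length(flagStretches(rep2)@flagged, 0L)
  expect_length(flagStretches(rep2, legacyAbsoluteCutoff = TRUE)@flagged, 1L)
})

test_that("per-atom deviation field accumulates stretched incident bonds", {
  r <- syntheticReport(c(0.5, 0.3), bonds = rbind(c(1L, 2L), c(1L, 3L)))
  f <- perAtomDeviationField(r)
  expect_equal(f[1], 0.8)
  expect_equal(f[2], 0.5)
  expect_equal(f[3], 0.3)

  small <- syntheticReport(c(0.05, 0.09), bonds = rbind(c(1L, 2L),
                                                        c(1L, 3L)))
  expect_true(all(perAtomDeviationField(small) == 0))

  ## brute-force accumulation on a fixture report
  fx <- benzeneEthane()
  rep <- bondDeviations(fx@system, fx@params)
  f2 <- perAtomDeviationField(rep, threshold = 0.1)
  want <- numeric(natoms(fx@system))
  tb <- rep@table
  for (i in seq_len(nrow(tb))) {
    if (tb$deviation[i] >= 0.1) {
      want[tb$ai[i]] <- want[tb$ai[i]] + tb$deviation[i]
      want[tb$aj[i]] <- want[tb$aj[i]] + tb$deviation[i]
    }
  }
  expect_equal(f2, want)
})

test_that("the flagged-bond report file lists one line per flagged bond", {
  fx <- benzeneEthane()
  rep <- flagStretches(bondDeviations(fx@system, fx@params))
  path <- tempfile(fileext = ".txt")
  writeStretchReport(rep, fx@system, path)
  lines <- readLines(path)
  expect_length(lines, length(rep@flagged) + 1L)   # header + rows
  expect_match(lines[1], "deviation")
})
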