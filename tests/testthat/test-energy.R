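nbOnly <- function(lj = TRUE, coulomb = FALSE, ...)
  EnergyModel(terms = c(bonds = FALSE, angles = FALSE, dihedrals = FALSE,
                        impropers = FALSE, lj = lj, coulomb = coulomb), ...)

twoAtoms <- function(r, types = c("CT", "CT"), charges = 0,
                     bonds = matrix(integer(0), ncol = 2))
  miniSystem(types, rbind(c(0, 0, 0), c(r, 0, 0)), bonds = bonds,
             charges = charges)

ctParams <- function() miniParams(c(
  "BONDS", "CT CT 300.0 1.5",
  "NONBONDED", "CT 0.0 -0.0780 2.0400"))

test_that("LJ energy at the pair minimum distance equals -epsilon", {
  p <- ctParams()
  sys <- twoAtoms(2 * 2.04)      # r = rmin_ij
  ev <- computeEnergyForces(sys, p, nbOnly())
  expect_equal(ev$energy, -0.078, tolerance = 1e-10)
  expect_equal(max(abs(ev$forces)), 0, tolerance = 1e-8)
})

test_that("soft-core keeps overlapping flagged pairs finite", {
  p <- ctParams()
  sys <- twoAtoms(0)
  m <- nbOnly(flagged = 1:2, softcoreDelta = 2.5)
  ev <- computeEnergyForces(sys, p, m)
  ## closed form at r_eff = delta
  q6 <- (2 * 2.04 / 2.5)^6
  expect_equal(ev$energy, 0.078 * (q6^2 - 2 * q6), tolerance = 1e-10)

  ## the same overlap without soft-core is a hard error naming the pair
  expect_error(computeEnergyForces(sys, p, nbOnly()), "worst")
})

test_that("soft-core converges to the standard potential as delta shrinks", {
  p <- ctParams()
  sys <- twoAtoms(3.6)   # a non-contact configuration
  plain <- computeEnergyForces(sys, p, nbOnly())$energy
  errs <- vapply(c(1.0, 0.1, 0.01), function(d)
    abs(computeEnergyForces(sys, p, nbOnly(flagged = 1:2,
                                           softcoreDelta = d))$energy -
        plain), 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("Coulomb term uses the dielectric and the switching window", {
  p <- ctParams()
  sys <- twoAtoms(5, charges = c(1, -1))
  e80 <- computeEnergyForces(sys, p, nbOnly(lj = FALSE, coulomb = TRUE,
                                            dielectric = 80))$energy
  expect_equal(e80, -332.0636 / (80 * 5), tolerance = 1e-9)
  e1 <- computeEnergyForces(sys, p, nbOnly(lj = FALSE, coulomb = TRUE,
                                           dielectric = 1))$energy
  expect_equal(e1, 80 * e80, tolerance = 1e-9)

  ## beyond the cutoff the interaction is exactly zero
  far <- twoAtoms(12.5, charges = c(1, -1))
  expect_equal(computeEnergyForces(far, p,
                 nbOnly(lj = FALSE, coulomb = TRUE))$energy, 0)
})

test_that("1-2 and 1-3 pairs are excluded from nonbonded terms", {
  p <- miniParams(c("BONDS", "CT CT 300.0 1.5",
                    "ANGLES", "CT CT CT 50.0 110.0",
                    "NONBONDED", "CT 0.0 -0.0780 2.0400"))
  ## three bonded atoms in a row, all within clashing distance
  sys <- miniSystem(rep("CT", 3),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0)),
                    bonds = rbind(c(1L, 2L), c(2L, 3L)))
  ev <- computeEnergyForces(sys, p, nbOnly())
  expect_equal(ev$terms[["lj"]], 0)   # both 1-2 and the 1-3 pair excluded
})

test_that("forces equal the negative numerical gradient for every term", {
  ## a strained many-term system plus every bias type
  fx <- strainedToy()
  model <- EnergyModel(flagged = c(1L, 5L, 6L))
  model <- addPointRestraint(model, 6, c(3, 1, 4), 7)
  model <- addSeparationBias(model, c(1, 5), c(7, 10, 13), target = 8, k = 4)
  model <- addDensityHill(model, c(0.2, -0.1, 1), radius = 3, height = 15,
                          exempt = c(5L))
  model <- setChiralRestraints(model,
    generateChiralityRestraints(detectChiralCenters(fx@system),
                                coords(fx@system)))
  expect_lt(gradMaxRelErr(fx@system, fx@params, model, nProbe = 60), 1e-4)

  ## and on a larger fixture with default terms
  g <- glycoToy()
  expect_lt(gradMaxRelErr(g@system, g@params, EnergyModel(), nProbe = 40),
            1e-4)
})

test_that("unbiased energy is invariant under rigid-body motion", {
  fx <- benzeneEthane()
  m <- EnergyModel(flagged = 1:4)
  e0 <- computeEnergyForces(fx@system, fx@params, m)$energy
  set.seed(9)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  moved <- coords(fx@system) %*% Q +
    matrix(c(3, -8, 2), natoms(fx@system), 3, byrow = TRUE)
  e1 <- computeEnergyForces(fx@system, fx@params, m, xyz = moved)$energy
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("minimization reaches the analytic minimum of a single bond", {
  p <- ctParams()
  sys <- twoAtoms(2.0, bonds = matrix(c(1L, 2L), 1))
  m <- nbOnly(lj = FALSE)       # bonded off too; turn bonds on
  m@terms["bonds"] <- TRUE
  res <- minimizeSystem(sys, p, m, steps = 500)
  d <- sqrt(sum((coords(res@system)[1, ] - coords(res@system)[2, ])^2))
  expect_equal(d, 1.5, tolerance = 1e-3)
  expect_true(all(diff(res@energyTrace) <= 1e-12))
  expect_error(minimizeSystem(sys, p, m, steps = 0), "steps")
})

test_that("minimization advises a soft-core stage on non-finite entry", {
  p <- ctParams()
  sys <- twoAtoms(0)
  expect_error(minimizeSystem(sys, p, nbOnly(), steps = 10), "soft-core")
})

test_that("point restraints pull a free atom onto the target", {
  p <- ctParams()
  sys <- miniSystem("CT", matrix(c(0, 0, 0), 1))
  m <- nbOnly(lj = FALSE)
  m <- addPointRestraint(m, 1, c(5, 0, 0), 10)
  res <- minimizeSystem(sys, p, m, steps = 500)
  expect_equal(coords(res@system)[1, ], c(5, 0, 0), tolerance = 1e-3)

  ## energy is 1/2 k |r - t|^2; doubling k doubles it
  e1 <- computeEnergyForces(sys, p, m)$energy
  expect_equal(e1, 0.5 * 10 * 25, tolerance = 1e-10)
  m2 <- nbOnly(lj = FALSE)
  m2 <- addPointRestraint(m2, 1, c(5, 0, 0), 20)
  expect_equal(computeEnergyForces(sys, p, m2)$energy, 2 * e1,
               tolerance = 1e-10)
})

test_that("the separation bias is one-sided with the documented magnitude", {
  p <- ctParams()
  mkm <- function(k) {
    m <- nbOnly(lj = FALSE)
    addSeparationBias(m, 1L, 2L, target = 10, k = k)
  }
  atBoundary <- twoAtoms(10)
  expect_equal(computeEnergyForces(atBoundary, p, mkm(10))$energy, 0)
  beyond <- twoAtoms(14)
  expect_equal(computeEnergyForces(beyond, p, mkm(10))$energy, 0)
  near <- twoAtoms(4)
  expect_equal(computeEnergyForces(near, p, mkm(10))$energy, 180,
               tolerance = 1e-10)   # 1/2 * 10 * (4-10)^2

  res <- minimizeSystem(near, p, mkm(10), steps = 500)
  d <- sqrt(sum((coords(res@system)[1, ] - coords(res@system)[2, ])^2))
  expect_equal(d, 10, tolerance = 1e-3)

  m <- nbOnly(lj = FALSE)
  expect_error(addSeparationBias(m, 1:2, 2:3, k = 5), "disjoint")
})

test_that("density hills have the documented peak, tail and exemptions", {
  p <- ctParams()
  sys <- twoAtoms(30)
  m <- nbOnly(lj = FALSE)
  m <- addDensityHill(m, c(0, 0, 0), radius = 4, height = 20)
  ev <- computeEnergyForces(sys, p, m)
  expect_equal(ev$terms[["hills"]], 20, tolerance = 1e-6)  # atom 1 at peak

  m2 <- nbOnly(lj = FALSE)
  m2 <- addDensityHill(m2, c(0, 0, 0), radius = 4, height = 20,
                       exempt = 1L)
  expect_lt(computeEnergyForces(sys, p, m2)$terms[["hills"]], 1e-6)
})

test_that("biases are removable by id", {
  p <- ctParams()
  sys <- twoAtoms(4)
  m <- nbOnly(lj = FALSE)
  m <- addPointRestraint(m, 1, c(9, 0, 0), 10)
  id <- attr(m, "id")
  m <- addDensityHill(m, c(0, 0, 0), radius = 4, height = 20)
  m <- removeBias(m, id)
  expect_equal(nrow(m@pointRestraints), 0L)
  expect_length(m@hills, 1L)
})
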