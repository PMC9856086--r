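test_that("segment-triangle test handles constructed cases", {
  hit <- segmentTriangleIntersect(c(0, 0, -1), c(0, 0, 1),
                                  c(2, 0, 0), c(-1, 1.5, 0), c(-1, -1.5, 0))
  expect_true(hit$hit)
  expect_equal(hit$point, c(0, 0, 0), tolerance = 1e-12)

  miss <- segmentTriangleIntersect(c(0, 0, 1.5), c(0, 0, 3),
                                   c(2, 0, 0), c(-1, 1.5, 0), c(-1, -1.5, 0))
  expect_false(miss$hit)

  expect_error(
    segmentTriangleIntersect(c(0, 0, -1), c(0, 0, 1),
                             c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    "degenerate")
})

test_that("segment-triangle test agrees with an independent oracle", {
  set.seed(101)
  n <- 10000
  mismatch <- 0
  for (k in seq_len(n)) {
    p0 <- runif(3, -2, 2); p1 <- runif(3, -2, 2)
    t0 <- runif(3, -2, 2); t1 <- runif(3, -2, 2); t2 <- runif(3, -2, 2)
    area <- sqrt(sum(ringfree:::.cross3(t1 - t0, t2 - t0)^2)) / 2
    if (area <= 1e-8) next
    got <- segmentTriangleIntersect(p0, p1, t0, t1, t2)$hit
    want <- segTriOracle(p0, p1, t0, t1, t2)
    if (got != want) mismatch <- mismatch + 1
  }
  expect_equal(mismatch, 0)
})

test_that("piercing detection finds engineered events and nothing else", {
  ev <- findPiercings(benzeneEthane()@system)
  expect_equal(nrow(ev), 1L)
  expect_equal(sort(c(ev$ai, ev$aj)), c(13L, 14L))   # the threaded C-C

  expect_equal(nrow(findPiercings(toyPolymer()@system)), 3L)
  expect_equal(nrow(findPiercings(makeToyPolymer(4, 2, seed = 3)@system)), 2L)
  expect_equal(nrow(findPiercings(cleanPolymer()@system)), 0L)
})

test_that("piercing detection is invariant under rigid-body motion", {
  sys <- benzeneEthane()@system
  theta <- 0.83
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3) %*%
       matrix(c(1, 0, 0, 0, cos(0.4), -sin(0.4), 0, sin(0.4), cos(0.4)),
              3, 3)
  moved <- sys
  coords(moved) <- coords(sys) %*% t(R) +
    matrix(c(11, -3, 7), natoms(sys), 3, byrow = TRUE)
  ev0 <- findPiercings(sys)
  ev1 <- findPiercings(moved)
  expect_equal(nrow(ev1), nrow(ev0))
  expect_equal(ev1$ai, ev0$ai)
  expect_equal(ev1$aj, ev0$aj)
})

test_that("potential stereocenters require four distinguishable branches", {
  ## methane-like center: four identical hydrogens, not a center
  xyz <- rbind(c(0, 0, 0),
               c(1.09, 0, 0), c(-0.36, 1.03, 0),
               c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89))
  met <- miniSystem(c("CT", "HT", "HT", "HT", "HT"), xyz,
                    bonds = cbind(1L, 2:5))
  expect_equal(nrow(detectChiralCenters(met)), 0L)

  centers <- detectChiralCenters(glycoToy()@system)
  expect_equal(nrow(centers), 9L)
  ## every center is genuinely four-coordinate
  g <- buildGraph(glycoToy()@system)
  expect_true(all(igraph::degree(g)[centers$center] == 4))
})

test_that("chirality signs follow the signed tetrahedron volume", {
  ## det[(0,1,0)-(1,0,0), (0,0,1)-(1,0,0), (-1,-1,-1)-(1,0,0)] = -4
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(-1, -1, -1))
  expect_equal(chiralitySign(2:5, xyz), -1)
  mirrored <- xyz; mirrored[, 1] <- -mirrored[, 1]
  expect_equal(chiralitySign(2:5, mirrored), 1)   # parity flips the sign

  ## invariant under rigid rotation
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  expect_equal(chiralitySign(2:5, xyz %*% Q), -1)

  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                c(0.5, 0.5, 0))
  expect_error(chiralitySign(2:5, flat), "degenerate")
})

test_that("mirror imaging flips every detected center's sign", {
  sys <- glycoToy()@system
  c0 <- detectChiralCenters(sys)
  mir <- sys
  xyz <- coords(sys); xyz[, 1] <- -xyz[, 1]
  coords(mir) <- xyz
  c1 <- detectChiralCenters(mir)
  expect_equal(c1$center, c0$center)
  expect_equal(c1$sign, -c0$sign)
})

test_that("chirality restraints target the input geometry, one per center", {
  sys <- glycoToy()@system
  centers <- detectChiralCenters(sys)
  r <- generateChiralityRestraints(centers, coords(sys), k = 50)
  expect_equal(nrow(r), nrow(centers))
  expect_true(all(r$k == 50))
  ## the restraint energy of the input structure is zero by construction
  m <- setChiralRestraints(EnergyModel(), r)
  ev <- computeEnergyForces(sys, glycoToy()@params, m)
  expect_lt(ev$terms[["chirality"]], 1e-10)

  expect_equal(nrow(generateChiralityRestraints(centers[0, ], coords(sys))),
               0L)

  path <- tempfile()
  writeRestraintsFile(r, path)
  expect_length(readLines(path), nrow(r))
})

test_that("restrained minimization preserves signs where unrestrained flips", {
  ## the strained glyco system keeps all nine centers under restraints
  fx <- glycoToy()
  centers <- detectChiralCenters(fx@system)
  m <- setChiralRestraints(EnergyModel(),
                           generateChiralityRestraints(centers,
                                                       coords(fx@system)))
  res <- minimizeSystem(fx@system, fx@params, m, steps = 500)
  expect_equal(signsAt(centers, coords(res@system)), centers$sign)

  ## the adversarial cage inverts its center without restraints
  cage <- strainedToy()
  cc <- detectChiralCenters(cage@system)
  res2 <- minimizeSystem(cage@system, cage@params, EnergyModel(),
                         steps = 2000)
  expect_equal(signsAt(cc, coords(res2@system)), -cc$sign)
})
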