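test_that("the default MO-RDF grid has 726 inclusive points", {
  g <- mordfGrid()
  expect_identical(nPoints(g), 726L)
  pts <- gridPoints(g)
  expect_equal(pts[1], 0.5)
  expect_equal(pts[726], 15.0)
  expect_equal(diff(pts)[1], 0.02)
})

test_that("atomic potential matches the double-loop oracle", {
  expect_equal(atomicPotential(6, matrix(0, 1, 3)), 0)
  expect_equal(atomicPotential(c(1, 1), rbind(c(0, 0, 0), c(1, 0, 0))),
               c(1, 1))
  set.seed(11)
  coords <- randomGeometry(4)
  Z <- c(6, 7, 8, 1)
  expect_lt(max(abs(atomicPotential(Z, coords) -
                      oraclePotential(Z, coords))), 1e-12)
  expect_error(atomicPotential(c(1, 1), rbind(c(0, 0, 0), c(1e-8, 0, 0))),
               "coincident atoms 1 and 2")
})

test_that("atomic potential is invariant under rotation and translation", {
  set.seed(12)
  coords <- randomGeometry(7)
  Z <- sample(c(1, 6, 7, 8), 7, replace = TRUE)
  ref <- atomicPotential(Z, coords)
  for (k in 1:5) {
    R <- randomRotation()
    t <- runif(3, -10, 10)
    moved <- sweep(coords %*% R, 2L, t, "+")
    expect_lt(max(abs(atomicPotential(Z, moved) - ref)), 1e-9)
  }
})

test_that("orbital populations normalize squared coefficients per atom", {
  expect_equal(orbitalPopulations(c(2, 0, 0), c(1, 2, 3)), c(1, 0, 0))
  expect_equal(orbitalPopulations(c(1, 1), c(1, 2)), c(0.5, 0.5))
  set.seed(13)
  cc <- rnorm(8)
  b2a <- sample(1:3, 8, replace = TRUE)
  expect_lt(max(abs(orbitalPopulations(cc, b2a, 3) -
                      oraclePopulations(cc, b2a, 3))), 1e-12)
  expect_equal(sum(orbitalPopulations(cc, b2a, 3)), 1)
  expect_error(orbitalPopulations(c(0, 0), c(1, 2)), "zero")
})

test_that("orbital populations are permutation-equivariant", {
  set.seed(14)
  cc <- rnorm(10)
  b2a <- sample(1:4, 10, replace = TRUE)
  p <- orbitalPopulations(cc, b2a, 4)
  perm <- sample(4)
  pNew <- orbitalPopulations(cc, perm[b2a], 4)
  # relabeling atom a -> perm[a] carries its population along
  expect_lt(max(abs(pNew[perm] - p)), 1e-12)
})

test_that("particle/hole densities follow the population oracle", {
  b2a <- c(1, 1, 2, 2, 3)
  hole <- c(1, 1, 0, 0, 0)
  part <- c(0, 0, 0, 0, 2)
  d <- particleHoleDensities(hole, part, b2a)
  expect_equal(d$n_hole, c(1, 0, 0))
  expect_equal(d$n_elec, c(0, 0, 1))
  same <- particleHoleDensities(hole, hole, b2a)
  expect_identical(same$n_hole, same$n_elec)
  set.seed(15)
  h <- rnorm(5); p <- rnorm(5)
  d2 <- particleHoleDensities(h, p, b2a)
  expect_lt(max(abs(d2$n_hole - oraclePopulations(h, b2a, 3))), 1e-12)
  expect_lt(abs(sum(d2$n_hole) - 1), 1e-12)
  expect_lt(abs(sum(d2$n_elec) - 1), 1e-12)
  # multi-pair mode weights by squared singular values
  dm <- particleHoleDensities(list(h, p), list(p, h), b2a,
                              singularValues = c(1, 0))
  expect_lt(max(abs(dm$n_hole - oraclePopulations(h, b2a, 3))), 1e-12)
})

test_that("MO-RDF matches closed-form and brute-force evaluation", {
  f0 <- moRdf(matrix(0, 1, 3), 1)
  expect_identical(f0, rep(0, 726))
  f2 <- moRdf(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1))
  expect_equal(length(f2), 726L)
  # peak of the normalized Gaussian at x = 0: 1 / (sigma sqrt(2 pi))
  expect_lt(abs(max(f2) - 1 / (0.05 * sqrt(2 * pi))), 1e-6)
  expect_equal(gridPoints(mordfGrid())[which.max(f2)], 2.0, tolerance = 0.02)
  expect_lt(abs(sum(f2) * 0.02 - 1), 1e-6)
  set.seed(16)
  coords <- randomGeometry(6)
  w <- runif(6)
  g <- mordfGrid()
  expect_lt(max(abs(moRdf(coords, w, g) - oracleMoRdf(coords, w, g))),
            1e-12)
  expect_error(moRdf(coords, w[-1]), "mismatch")
  expect_warning(moRdf(coords, -w), "negative")
})

test_that("MO-RDF is invariant under rigid motion and atom reindexing", {
  set.seed(17)
  coords <- randomGeometry(6)
  w <- runif(6)
  ref <- moRdf(coords, w)
  R <- randomRotation()
  moved <- sweep(coords %*% R, 2L, runif(3, -5, 5), "+")
  expect_lt(max(abs(moRdf(moved, w) - ref)), 1e-9)
  perm <- sample(6)
  expect_lt(max(abs(moRdf(coords[perm, ], w[perm]) - ref)), 1e-12)
})

test_that("Gaussian mass is conserved on the grid for interior distances", {
  set.seed(18)
  g <- mordfGrid()
  for (rep in 1:5) {
    coords <- randomGeometry(5, spread = 3)
    d <- dist(coords)
    # keep all pair distances at least 5 sigma inside the grid
    stopifnot(min(d) > g@rMin + 5 * g@sigma,
              max(d) < g@rMax - 5 * g@sigma)
    w <- runif(5)
    f <- moRdf(coords, w, g)
    wp <- sum(outer(w, w)[upper.tri(matrix(0, 5, 5))])
    expect_lt(abs(g@step * sum(f) - wp) / wp, 1e-6)
  }
})

test_that("Morgan fingerprints are 2048-bit, canonical, and discriminative", {
  fp <- morganFingerprint("c1ccccc1")
  expect_length(fp, 2048L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(morganFingerprint("c1ccccc1C"),
                   morganFingerprint("Cc1ccccc1"))
  expect_false(identical(morganFingerprint("C"), morganFingerprint("CC")))
})

test_that("node features have the contracted widths and EA ordering", {
  fx <- toyFixtures()
  benzene <- molecules(fx)$benzene
  elec <- electronicRecords(fx)$benzene
  da <- buildNodeFeatures(benzene, mode = "DA")
  expect_identical(dim(da), c(12L, 41L))
  ea <- buildNodeFeatures(benzene, elec, mode = "DA+EA")
  expect_identical(dim(ea), c(12L, 45L))
  # raw EA columns in fixed order when no standardization is supplied
  expect_equal(ea[, 42], elec$mulliken)
  expect_equal(ea[, 43], elec$potential)
  expect_equal(ea[, 44], elec$n_elec)
  expect_equal(ea[, 45], elec$n_hole)
  st <- list(mean = c(0, 1, 0.5, 0), sd = c(2, 3, 1, 1))
  eaz <- buildNodeFeatures(benzene, elec, mode = "DA+EA", eaStats = st)
  expect_equal(eaz[, 42], elec$mulliken / 2)
  expect_equal(eaz[, 43], (elec$potential - 1) / 3)
  expect_error(buildNodeFeatures(benzene, NULL, mode = "DA+EA"),
               "refusing to zero-fill")
})

test_that("edge features flag bond type, conjugation and rings", {
  fx <- toyFixtures()
  eth <- buildEdgeFeatures(molecules(fx)$ethane)
  expect_identical(dim(eth), c(1L, 10L))
  expect_equal(eth[1, 1:4], c(1, 0, 0, 0))   # single-bond one-hot
  expect_equal(eth[1, 5], 0)                 # not conjugated
  expect_equal(eth[1, 6], 0)                 # not in a ring
  bz <- buildEdgeFeatures(molecules(fx)$benzene)
  ringRows <- 1:6
  expect_true(all(bz[ringRows, 4] == 1))     # aromatic one-hot
  expect_true(all(bz[ringRows, 6] == 1))     # in ring
  # symmetric under bond direction reversal
  m <- molecules(fx)$pyridine
  rev <- Molecule(m@id, m@elements, m@coords,
                  bonds = m@bonds[, c(2, 1, 3)],
                  aromaticAtom = m@aromaticAtom,
                  aromaticBond = m@aromaticBond, nH = m@nH)
  expect_equal(buildEdgeFeatures(rev), buildEdgeFeatures(m))
})

test_that("molecules with identical graphs but different orbitals separate in MO-RDF, not MFP", {
  fx <- toyFixtures()
  m <- molecules(fx)$naphthalene
  n <- nAtoms(m)
  w1 <- rep(1 / n, n)
  w2 <- c(rep(0.15, 4), rep((1 - 0.6) / (n - 4), n - 4))
  f1 <- moRdf(m, w1)
  f2 <- moRdf(m, w2)
  expect_gt(sqrt(sum((f1 - f2)^2)), 0)
  expect_identical(morganFingerprint(m), morganFingerprint(m))
})
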