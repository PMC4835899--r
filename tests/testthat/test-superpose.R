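test_that("kabschFit recovers exact transforms", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  f0 <- kabschFit(a, a)
  expect_lt(f0$rmsd, 1e-12)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-9)

  R0 <- randomRotation(5)
  b <- a %*% t(R0) + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  f1 <- kabschFit(a, b)
  expect_lt(max(abs(f1$rotation - R0)), 1e-6)
  expect_lt(f1$rmsd, 1e-9)

  expect_error(kabschFit(a, b[1:5, ]), "size")
  expect_error(kabschFit(a[1:2, ], b[1:2, ]), "three")
})

test_that("kabschFit matches the brute-force rotation-search oracle", {
  for (s in 1:10) {
    set.seed(s)
    a <- matrix(rnorm(30), 10, 3)
    b <- a %*% t(randomRotation(s + 50)) +
      matrix(rnorm(30, sd = 0.5), 10, 3)
    expect_lt(abs(kabschFit(a, b)$rmsd - bruteForceRMSD(a, b)), 1e-4)
  }
})

test_that("noisy-copy RMSD lands in the expected band", {
  set.seed(99)
  a <- matrix(rnorm(60, sd = 6), 20, 3)
  b <- a + matrix(rnorm(60, sd = 0.5), 20, 3)
  f <- kabschFit(a, b)
  ## isotropic noise sigma: expected RMSD ~ sigma*sqrt(3) before fitting;
  ## the fit removes 6 dof, keep a generous band around it
  expect_gt(f$rmsd, 0.5 * 0.7)
  expect_lt(f$rmsd, 0.5 * sqrt(3) * 1.3)
  expect_lt(abs(f$rmsd - bruteForceRMSD(a, b)), 1e-4)
})

test_that("enumerateMappings returns bijections and drops missing labels", {
  p <- makeDomainPair("direct", seed = 1)
  maps <- enumerateMappings(p$A$domain, p$B$domain)
  expect_named(maps, c("direct", "rotated", "permuted", "rotated+permuted"))
  for (m in maps) {
    expect_equal(anyDuplicated(m), 0L)
    expect_equal(anyDuplicated(names(m)), 0L)
  }
  ## the half-swap is an involution: applying it twice gives the identity
  hs <- maps$rotated
  expect_identical(unname(hs[hs]), names(hs))

  ## missing a2 on one side removes pairs involving its image
  domB <- p$B$domain
  domB@elementIdx[["a2"]] <- NA_integer_
  maps2 <- enumerateMappings(p$A$domain, domB)
  expect_false("a2" %in% maps2$direct)
  expect_false("a2" %in% maps2$rotated)
})

test_that("a domain aligns to itself exactly under the direct map", {
  p <- makeDomainPair("direct", seed = 3, noiseSigma = 0)
  al <- alignDomains(p$A$domain, p$A$domain, p$A$model, p$A$model)
  expect_identical(al$best@kind, "direct")
  expect_lt(al$best@rmsd, 1e-6)
  nCa <- sum(lengths(p$A$domain@elementResidues))
  expect_equal(al$best@nPairs, nCa)
})

test_that("a sequence-level circular permutant is recognized", {
  p <- makeDomainPair("permuted", seed = 4, noiseSigma = 0)
  al <- alignDomains(p$A$domain, p$B$domain, p$A$model, p$B$model)
  expect_identical(al$best@kind, "permuted")
  expect_lt(al$best@rmsd, 1e-3)
  expect_identical(unname(al$best@elementMap["b1"]), "b3")
})

test_that("all four constructed mapping kinds are recovered under noise", {
  for (kind in c("direct", "rotated", "permuted", "rotated+permuted")) {
    for (s in 1:5) {
      p <- makeDomainPair(kind, seed = s, noiseSigma = 0.5)
      al <- alignDomains(p$A$domain, p$B$domain, p$A$model, p$B$model)
      expect_identical(al$best@kind, kind)
    }
  }
})

test_that("alignment is symmetric and rigid-invariant", {
  p <- makeDomainPair("rotated", seed = 11, noiseSigma = 0.3)
  ab <- alignDomains(p$A$domain, p$B$domain, p$A$model, p$B$model)
  ba <- alignDomains(p$B$domain, p$A$domain, p$B$model, p$A$model)
  expect_equal(ab$best@rmsd, ba$best@rmsd, tolerance = 1e-6)
  expect_equal(ab$best@rotation %*% ba$best@rotation, diag(3),
               tolerance = 1e-6)

  m2 <- transformModel(p$B$model, randomRotation(77), c(4, 4, -9))
  ab2 <- alignDomains(p$A$domain, p$B$domain, p$A$model, m2)
  expect_equal(ab2$best@rmsd, ab$best@rmsd, tolerance = 1e-6)
  expect_identical(ab2$best@kind, ab$best@kind)
})

test_that("correspondences validate their rotation matrices", {
  p <- makeDomainPair("direct", seed = 6)
  al <- alignDomains(p$A$domain, p$B$domain, p$A$model, p$B$model)
  R <- al$best@rotation
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-9)
})
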