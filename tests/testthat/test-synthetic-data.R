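test_that("the generator is deterministic: same seed, identical output", {
  b1 <- makeBarrel(packing = "Type-1", hemeMode = "cleft_alpha2", seed = 42,
                   noiseSigma = 0.4, rigidTransform = TRUE)
  b2 <- makeBarrel(packing = "Type-1", hemeMode = "cleft_alpha2", seed = 42,
                   noiseSigma = 0.4, rigidTransform = TRUE)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(b1$model, f1)
  writeStructure(b2$model, f2)
  expect_identical(readLines(f1), readLines(f2))

  b3 <- makeBarrel(packing = "Type-1", hemeMode = "cleft_alpha2", seed = 43,
                   noiseSigma = 0.4, rigidTransform = TRUE)
  expect_false(identical(b3$model@atoms$x, b1$model@atoms$x))
})

test_that("ground truth is exactly recovered at zero noise", {
  for (pk in c("Type-1", "Type-2")) for (arr in c("homodimer", "fused")) {
    b <- makeBarrel(packing = pk, arrangement = arr, seed = 31)
    rep <- runClassify(model = b$model, annotation = b$truth$annotation)
    expect_identical(rep$packing$packing, pk)
    expect_identical(rep$arrangement, arr)
  }
})

test_that("the annotation is consistent with the emitted coordinates", {
  b <- makeBarrel(packing = "Type-2", seed = 8)
  el <- acceptAnnotation(b$model, b$truth$annotation)
  tr <- b$truth$elements
  expect_equal(sum(el$kind == "strand"), sum(tr$kind == "strand"))
  expect_setequal(el$start[el$kind == "strand"],
                  tr$start[tr$kind == "strand"])
})

test_that("classification accuracy does not improve with noise", {
  sigmas <- c(0, 0.3, 0.6, 1.0)
  nSeeds <- 8
  acc <- vapply(sigmas, function(sg) {
    ok <- 0
    for (s in seq_len(nSeeds)) {
      pk <- if (s %% 2 == 0) "Type-1" else "Type-2"
      rep <- classifySynthetic(pk, seed = 200 + s, sigma = sg)
      if (identical(rep$packing$packing, pk)) ok <- ok + 1
    }
    ok / nSeeds
  }, numeric(1))
  expect_equal(acc[1], 1)
  ## non-increasing within one misclassification of slack
  for (k in seq_len(length(acc) - 1))
    expect_lte(acc[k + 1], acc[k] + 1 / nSeeds)
})

test_that("the pseudo-porphyrin has the canonical atom complement", {
  ring <- makePorphyrin()
  expect_length(ring$name, 25L)
  expect_equal(sum(ring$elem == "N"), 4L)
  expect_equal(sum(ring$elem == "C"), 20L)
  ## planar by construction
  dev <- FdxBarrel:::fitPlane(ring$xyz[-1, ])$rms
  expect_lt(dev, 1e-12)
  ## Fe centered in the N4 square
  expect_equal(colMeans(ring$xyz[2:5, ]), ring$xyz[1, ], tolerance = 1e-9)
})

test_that("makePseudoHeme regenerates the same barrel with a ligand", {
  b <- makeBarrel(packing = "Type-1", seed = 3)
  bh <- makePseudoHeme(b, "cavity_beta2")
  expect_length(bh$model@ligands, 1L)
  expect_identical(bh$truth$siteMode, "SITE_CAVITY")
  ## polymer geometry identical to the apo barrel except the added NE2
  apo <- b$model@atoms
  holo <- bh$model@atoms
  holoCa <- holo[holo$elety == "CA" & holo$type == "ATOM", ]
  expect_equal(holoCa$x, apo$x[apo$elety == "CA"], tolerance = 1e-9)
})

test_that("domain pairs carry labeled, alignable domains", {
  p <- makeDomainPair("direct", seed = 2)
  for (side in list(p$A, p$B)) {
    expect_s4_class(side$domain, "FerredoxinDomain")
    expect_false(anyNA(side$domain@elementIdx))
    expect_equal(sum(side$elements$kind == "strand"), 4L)
  }
})
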