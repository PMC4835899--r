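classifyHeme <- function(mode, seed, sigma = 0) {
  b <- makeBarrel(packing = "Type-1", hemeMode = mode, seed = seed,
                  noiseSigma = sigma)
  rep <- runClassify(model = b$model, annotation = b$truth$annotation)
  list(rep = rep, truth = b$truth)
}

test_that("pseudo-heme sites classify into the three modes with the right proximal residue", {
  modes <- c(cleft_alpha2 = "SITE_CLEFT_ISDG_OXDA",
             cleft_alpha1 = "SITE_CLD_DYP",
             cavity_beta2 = "SITE_CAVITY")
  for (mode in names(modes)) for (s in c(1, 7, 20)) {
    r <- classifyHeme(mode, s)
    h <- r$rep$hemes[[1]]
    expect_identical(h$mode, unname(modes[mode]))
    expect_identical(h$proximal$chain, r$truth$proximal$chain)
    expect_identical(h$proximal$resno, r$truth$proximal$resno)
    expect_identical(h$proximal$resid, "HIS")
  }
})

test_that("a heme far from any candidate residue is flagged, not erroneous", {
  b <- makeBarrel(packing = "Type-1", seed = 4)  # no His side chains at all
  ring <- makePorphyrin(center = c(40, 40, 0), normal = c(0, 0, 1))
  het <- data.frame(type = "HETATM", elety = ring$name, alt = "",
                    resid = "HEM", chain = "A", resno = 900L, insert = "",
                    x = ring$xyz[, 1], y = ring$xyz[, 2], z = ring$xyz[, 3],
                    o = 1, b = 0, elesy = ring$elem, residx = NA_integer_,
                    stringsAsFactors = FALSE)
  m <- FdxBarrel:::buildStructureModel(rbind(b$model@atoms, het), id = "FARHEME")
  ax <- findAxialResidues(m, m@ligands[[1]])
  expect_length(ax$proximal, 0L)
  rep <- runClassify(model = m, annotation = b$truth$annotation)
  expect_match(rep$hemes[[1]]$diagnostics, "proximal")
})

test_that("ruffling is zero for planar rings and follows the imposed distortion", {
  planar <- makePorphyrin(ruffle = 0)
  lig <- function(ring) new("LigandGroup", hetCode = "HEM", chain = "A",
    resno = 1L, insert = "",
    atoms = data.frame(),
    fePos = ring$xyz[1, ],
    macrocycle = data.frame(elety = ring$name[-1], x = ring$xyz[-1, 1],
                            y = ring$xyz[-1, 2], z = ring$xyz[-1, 3]))
  r0 <- rufflingScore(lig(planar))
  expect_lt(r0$rms, 1e-9)
  expect_false(r0$ruffled)

  ## alternating +/-0.4 on the four meso carbons: zero net moment, so the
  ## plane is unchanged and the RMS has the closed form sqrt(4*0.4^2/24)
  r1 <- rufflingScore(lig(makePorphyrin(ruffle = 0.4)))
  expect_equal(r1$rms, sqrt(4 * 0.4^2 / 24), tolerance = 1e-9)

  ## a strong distortion crosses the ruffled threshold
  r2 <- rufflingScore(lig(makePorphyrin(ruffle = 0.7)))
  expect_true(r2$ruffled)

  short <- lig(planar)
  short@macrocycle <- short@macrocycle[1:8, ]
  expect_error(rufflingScore(short), "few")
})

test_that("heme counting respects the association cutoff", {
  withHeme <- makeBarrel(packing = "Type-1", hemeMode = "cleft_alpha2",
                         seed = 2)
  expect_equal(countHemes(withHeme$model,
                          unique(withHeme$model@residues$chain)), 1L)
  apo <- makeBarrel(packing = "Type-1", seed = 2)
  expect_equal(countHemes(apo$model, unique(apo$model@residues$chain)), 0L)
})

test_that("homodimer protomers give symmetric proximal assignments", {
  ## mirror the domain-A heme onto domain B with the barrel's own two-fold
  b <- makeBarrel(packing = "Type-1", hemeMode = "cleft_alpha2", seed = 15)
  a <- b$model@atoms
  Rz <- FdxBarrel:::rotationAboutAxis(c(0, 0, 1), pi)
  hetB <- a[a$type == "HETATM" | (a$elety == "NE2"), ]
  xyz <- as.matrix(hetB[, c("x", "y", "z")]) %*% t(Rz)
  hetB$x <- xyz[, 1]; hetB$y <- xyz[, 2]; hetB$z <- xyz[, 3]
  hetB$chain <- "B"
  ## rename the mirrored target residue on chain B
  tgt <- b$truth$proximal
  a$resid[a$chain == "B" & a$resno == tgt$resno] <- "HIS"
  m <- FdxBarrel:::buildStructureModel(rbind(a, hetB), id = "TWOHEME")
  expect_length(m@ligands, 2L)
  rep <- runClassify(model = m, annotation = b$truth$annotation)
  expect_equal(rep$hemeCount, 2L)
  prox <- vapply(rep$hemes, function(h) h$proximal$resno, numeric(1))
  expect_equal(prox[1], prox[2])
  chains <- vapply(rep$hemes, function(h) h$proximal$chain, character(1))
  expect_setequal(chains, c("A", "B"))
})

test_that("heme geometry outputs are rigid-transform invariant", {
  b <- makeBarrel(packing = "Type-1", hemeMode = "cavity_beta2", seed = 5)
  rep0 <- runClassify(model = b$model, annotation = b$truth$annotation)
  m2 <- transformModel(b$model, randomRotation(9), c(12, -7, 3))
  rep1 <- runClassify(model = m2, annotation = b$truth$annotation)
  h0 <- rep0$hemes[[1]]; h1 <- rep1$hemes[[1]]
  expect_identical(h1$mode, h0$mode)
  expect_equal(h1$proximal$dist, h0$proximal$dist, tolerance = 1e-6)
  expect_equal(h1$feRadial, h0$feRadial, tolerance = 1e-6)
  expect_equal(h1$rufflingRMS, h0$rufflingRMS, tolerance = 1e-6)
})
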