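buildBarrelModel <- function(b) {
  el <- acceptAnnotation(b$model, b$truth$annotation)
  sheet <- buildBarrelSheet(pairStrands(el, NULL, b$model), el, b$model)
  mapDomains(el, sheet, b$model)
}

test_that("homodimeric and fused barrels map to two labeled domains", {
  b <- makeBarrel(packing = "Type-1", arrangement = "homodimer", seed = 2)
  bm <- buildBarrelModel(b)
  expect_identical(bm@arrangement, "homodimer")
  for (d in list(bm@domainA, bm@domainB)) {
    expect_false(anyNA(d@elementIdx))
    expect_false(d@relaxed)
  }
  ## labels come in sequence order b1 < a1 < b2 < b3 < a2 < b4
  ord <- bm@elements$start[bm@domainA@elementIdx[FdxBarrel:::FDX_LABELS]]
  expect_identical(order(ord), seq_along(ord))

  bf <- makeBarrel(packing = "Type-1", arrangement = "fused", seed = 2)
  bmf <- buildBarrelModel(bf)
  expect_identical(bmf@arrangement, "fused")
  expect_setequal(names(bmf@barrelLabels),
                  c(paste0("b", 1:8), paste0("a", 1:4)))
})

test_that("fused barrel-level helices map to the second domain's a1/a2", {
  b <- makeBarrel(packing = "Type-2", arrangement = "fused", seed = 6)
  bm <- buildBarrelModel(b)
  expect_equal(bm@barrelLabels[["a3"]], bm@domainB@elementIdx[["a1"]])
  expect_equal(bm@barrelLabels[["a4"]], bm@domainB@elementIdx[["a2"]])
  expect_equal(bm@barrelLabels[["b6"]], bm@domainB@elementIdx[["b2"]])
})

test_that("termini projections separate Type-1 from Type-2", {
  b1 <- makeBarrel(packing = "Type-1", seed = 3)
  bm1 <- buildBarrelModel(b1)
  tA <- terminiSide(bm1@domainA, bm1@sheet, b1$model)
  tB <- terminiSide(bm1@domainB, bm1@sheet, b1$model)
  expect_length(unique(sign(c(tA, tB))), 1L)

  b2 <- makeBarrel(packing = "Type-2", seed = 3)
  bm2 <- buildBarrelModel(b2)
  tA <- terminiSide(bm2@domainA, bm2@sheet, b2$model)
  tB <- terminiSide(bm2@domainB, bm2@sheet, b2$model)
  expect_identical(sign(tA[["N"]]), sign(tA[["C"]]))
  expect_identical(sign(tB[["N"]]), sign(tB[["C"]]))
  expect_true(sign(tA[["N"]]) != sign(tB[["N"]]))
})

test_that("labels survive rigid motion and chain renaming", {
  b <- makeBarrel(packing = "Type-1", seed = 12, noiseSigma = 0.2)
  bm0 <- buildBarrelModel(b)
  lab0 <- bm0@elements$label

  m2 <- transformModel(b$model, randomRotation(42), c(7, -2, 11))
  a <- m2@atoms
  a$chain <- chartr("AB", "XY", a$chain)
  m2 <- FdxBarrel:::buildStructureModel(a, id = "RENAMED")
  ann <- b$truth$annotation
  names(ann) <- chartr("AB", "XY", names(ann))
  el <- acceptAnnotation(m2, ann)
  sheet <- buildBarrelSheet(pairStrands(el, NULL, m2), el, m2)
  bm1 <- mapDomains(el, sheet, m2)
  expect_identical(bm1@elements$label, lab0)
  expect_identical(bm1@arrangement, bm0@arrangement)
})

test_that("decoy decorations do not disturb core labels", {
  b <- makeBarrel(packing = "Type-1", seed = 17)
  bm0 <- buildBarrelModel(b)
  ## append a peripheral strand + helix far outside the barrel to chain A
  a <- b$model@atoms
  nA <- max(a$resno[a$chain == "A"])
  extra <- do.call(rbind, lapply(seq_len(10), function(i) {
    data.frame(type = "ATOM", elety = "CA", alt = "", resid = "GLY",
               chain = "A", resno = nA + i, insert = "",
               x = 30, y = 30, z = i * 3.3, o = 1, b = 0,
               elesy = "C", residx = NA_integer_, stringsAsFactors = FALSE)
  }))
  aB <- a[a$chain == "B", ]
  m2 <- FdxBarrel:::buildStructureModel(
    rbind(a[a$chain == "A", ], extra, aB), id = "DECOY")
  ann <- b$truth$annotation
  ann[["A"]] <- paste0(ann[["A"]], "-EEEE-HHHH")
  el <- acceptAnnotation(m2, ann)
  expect_gt(sum(el$kind == "strand"), 8)
  sheet <- buildBarrelSheet(pairStrands(el, NULL, m2), el, m2)
  expect_true(sheet@closed)
  bm1 <- mapDomains(el, sheet, m2)
  coreA <- bm1@domainA@elementIdx
  expect_false(anyNA(coreA))
  expect_identical(
    bm1@elements$start[coreA[FdxBarrel:::FDX_LABELS]],
    bm0@elements$start[bm0@domainA@elementIdx[FdxBarrel:::FDX_LABELS]])
})

test_that("a lone domain cannot be mapped into a barrel", {
  b <- makeBarrel(packing = "Type-1", seed = 2)
  aA <- b$model@atoms[b$model@atoms$chain == "A", ]
  m <- FdxBarrel:::buildStructureModel(aA, id = "HALF")
  el <- acceptAnnotation(m, b$truth$annotation["A"])
  pr <- pairStrands(el, NULL, m)
  sheet <- buildBarrelSheet(pr, el, m)
  expect_false(sheet@closed)
  expect_error(mapDomains(el, sheet, m), "closed")
})
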