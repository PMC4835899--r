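test_that("distant strands form no hydrogen bonds", {
  lad <- makeLadder(6, "antiparallel")
  a <- lad$model@atoms
  a$y[a$chain == "B"] <- a$y[a$chain == "B"] + 30
  far <- FdxBarrel:::buildStructureModel(a, id = "FAR")
  hb <- detectHBonds(far)
  res <- far@residues
  expect_equal(sum(res$chain[hb$donor] != res$chain[hb$acceptor]), 0L)
})

test_that("ideal ladders show the inter-strand bond ladder", {
  lad <- makeLadder(6, "antiparallel")
  hb <- detectHBonds(lad$model)
  res <- lad$model@residues
  inter <- hb[res$chain[hb$donor] != res$chain[hb$acceptor], ]
  expect_gte(nrow(inter), 4)
  ## independent oracle: every accepted bond must be a short N...O contact
  bb <- FdxBarrel:::backboneCoords(lad$model)
  for (k in seq_len(nrow(inter))) {
    nPos <- bb[[inter$donor[k]]]["N", ]
    oPos <- bb[[inter$acceptor[k]]]["O", ]
    expect_lt(FdxBarrel:::vdist(nPos, oPos), 3.5)
  }
  expect_true(all(hb$energy < -0.5))

  lad4 <- makeLadder(4, "antiparallel")
  hb4 <- detectHBonds(lad4$model)
  r4 <- lad4$model@residues
  expect_gte(sum(r4$chain[hb4$donor] != r4$chain[hb4$acceptor]), 2)
})

test_that("an ideal helix donates i -> i-4 bonds along its interior", {
  h <- makeHelix(12)
  hb <- detectHBonds(h$model)
  turns <- hb[hb$donor - hb$acceptor == 4, ]
  expect_gte(nrow(turns), 7)  # donors 5..12 at most
  el <- assignSS(h$model, hb)
  expect_equal(nrow(el), 1L)
  expect_identical(el$kind, "helix")
  expect_gte(el$start, 2L)
  expect_lte(el$end, 11L)
})

test_that("a random-walk coil yields no elements", {
  coil <- randomCoil(20, seed = 7)
  hb <- detectHBonds(coil)
  el <- assignSS(coil, hb)
  expect_equal(nrow(el), 0L)
})

test_that("hydrogen bonds are invariant under rigid motion", {
  lad <- makeLadder(6, "antiparallel")
  hb0 <- detectHBonds(lad$model)
  for (s in 1:3) {
    m2 <- transformModel(lad$model, randomRotation(s), c(5, -3, 2) * s)
    hb1 <- detectHBonds(m2)
    expect_equal(hb1$donor, hb0$donor)
    expect_equal(hb1$acceptor, hb0$acceptor)
    expect_equal(hb1$energy, hb0$energy, tolerance = 1e-8)
  }
})

test_that("assignSS recovers most ground-truth strand residues on ladders", {
  hits <- 0; total <- 0
  for (n in c(5, 6, 8, 10)) {
    lad <- makeLadder(n, "antiparallel")
    el <- assignSS(lad$model, detectHBonds(lad$model))
    marked <- unlist(lapply(which(el$kind == "strand"),
                            function(e) el$start[e]:el$end[e]))
    hits <- hits + length(marked)
    total <- total + 2 * n
  }
  ## edge residues lack the second bridge by construction; interiors must be
  ## fully recovered
  expect_gte(hits / total, 0.6)
})

test_that("acceptAnnotation transcribes and filters runs", {
  b <- makeBarrel(packing = "Type-1", seed = 2)
  onechain <- FdxBarrel:::buildStructureModel(
    b$model@atoms[b$model@atoms$chain == "A", ], id = "ONE")
  n <- nrow(onechain@residues)

  ann <- paste0("---EEEE---HHHHH", strrep("-", n - 15))
  el <- acceptAnnotation(onechain, c(A = ann))
  expect_equal(nrow(el), 2L)
  expect_equal(el$kind, c("strand", "helix"))
  expect_equal(el$end[1] - el$start[1] + 1L, 4L)
  expect_equal(el$end[2] - el$start[2] + 1L, 5L)

  ## short E run dropped
  ann2 <- paste0("---EE--", strrep("-", n - 7))
  expect_equal(nrow(acceptAnnotation(onechain, c(A = ann2))), 0L)

  ## length mismatch is an error
  expect_error(acceptAnnotation(onechain, c(A = "EEE")), "length")
})

test_that("annotation-driven elements match geometry-driven ones", {
  lad <- makeLadder(6, "antiparallel")
  geo <- assignSS(lad$model, detectHBonds(lad$model))
  ann <- acceptAnnotation(lad$model, lad$truth$annotation)
  ## geometry marks a subset of the annotated strands, same count and kind
  expect_equal(nrow(ann), 2L)
  expect_true(all(geo$kind == "strand"))
  for (k in seq_len(nrow(geo)))
    expect_true(any(ann$start <= geo$start[k] & ann$end >= geo$end[k] &
                    ann$chain == geo$chain[k]))
})
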