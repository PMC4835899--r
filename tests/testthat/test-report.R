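test_that("runClassify produces a schema-tagged reproducible JSON report", {
  b <- makeBarrel(packing = "Type-1", hemeMode = "cleft_alpha2", seed = 6)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  rep <- runClassify(model = b$model, annotation = b$truth$annotation,
                     json = f1)
  runClassify(model = b$model, annotation = b$truth$annotation, json = f2)
  expect_identical(readLines(f1), readLines(f2))

  parsed <- jsonlite::read_json(f1)
  expect_identical(parsed$schema, "fdxbarrel-report/1")
  expect_identical(parsed$packing$packing, "Type-1")
  expect_true(!is.null(parsed$config$contactDist))
  expect_identical(parsed$hemes[[1]]$mode, "SITE_CLEFT_ISDG_OXDA")
})

test_that("a structure with no ligand reports an empty heme section", {
  b <- makeBarrel(packing = "Type-2", seed = 9)
  rep <- runClassify(model = b$model, annotation = b$truth$annotation)
  expect_length(rep$hemes, 0L)
  expect_equal(rep$hemeCount, 0L)
  expect_identical(rep$packing$packing, "Type-2")
})

test_that("file-driven classification matches the in-memory path", {
  b <- makeBarrel(packing = "Type-2", hemeMode = "cavity_beta2", seed = 14)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(b$model, path)
  repFile <- runClassify(path = path, annotation = b$truth$annotation)
  repMem <- runClassify(model = b$model, annotation = b$truth$annotation)
  expect_identical(repFile$packing$packing, repMem$packing$packing)
  expect_identical(repFile$hemes[[1]]$mode, repMem$hemes[[1]]$mode)
})

test_that("runCompare reports all candidates and flags the winner", {
  pA <- makeDomainPair("direct", seed = 2)
  fA <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(pA$A$model, fA)
  ann <- FdxBarrel:::elementsToAnnotation(pA$A$elements, pA$A$model)
  rep <- runCompare(pathA = fA, pathB = fA,
                    annotationA = ann, annotationB = ann)
  expect_identical(rep$best$kind, "direct")
  expect_lt(rep$best$rmsd, 1e-6)
  expect_gte(length(rep$candidates), 2L)

  p <- makeDomainPair("permuted", seed = 5)
  rep2 <- runCompare(modelA = p$A$model, modelB = p$B$model,
                     annotationA = FdxBarrel:::elementsToAnnotation(p$A$elements, p$A$model),
                     annotationB = FdxBarrel:::elementsToAnnotation(p$B$elements, p$B$model))
  expect_identical(rep2$best$kind, "permuted")
})

test_that("an open sheet yields an unclassified report, not an error", {
  b <- makeBarrel(packing = "Type-1", seed = 2)
  aA <- b$model@atoms[b$model@atoms$chain == "A", ]
  m <- FdxBarrel:::buildStructureModel(aA, id = "HALF")
  rep <- runClassify(model = m, annotation = b$truth$annotation["A"])
  expect_identical(rep$packing$packing, "unclassified")
  expect_gt(length(rep$warnings), 0L)
})

test_that("config overrides are embedded in the report", {
  b <- makeBarrel(packing = "Type-1", seed = 2)
  rep <- runClassify(model = b$model, annotation = b$truth$annotation,
                     config = list(contactDist = 6.0))
  expect_equal(rep$config$contactDist, 6.0)
})
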