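test_that("synthetic barrel survives a write/parse round trip", {
  b <- makeBarrel(packing = "Type-1", hemeMode = "cleft_alpha2", seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(b$model, path)
  m <- loadStructure(path)

  expect_equal(nrow(m@residues), nrow(b$model@residues))
  expect_equal(m@residues$chain, b$model@residues$chain)
  expect_equal(m@residues$resno, b$model@residues$resno)
  expect_equal(m@residues$resid, b$model@residues$resid)
  expect_equal(length(unique(m@residues$chain)), 2L)
  expect_lt(max(abs(m@atoms$x - b$model@atoms$x)), 1e-3)
  expect_lt(max(abs(m@atoms$z - b$model@atoms$z)), 1e-3)

  expect_length(m@ligands, 1L)
  lig <- m@ligands[[1]]
  expect_identical(lig@hetCode, "HEM")
  expect_length(lig@fePos, 3L)
  expect_equal(nrow(lig@macrocycle), 24L)

  ## parse-write-parse idempotence
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, path2)
  m2 <- loadStructure(path2)
  expect_equal(m2@residues, m@residues)
  expect_lt(max(abs(m2@atoms$x - m@atoms$x)), 1e-3)
})

test_that("altloc collapses to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.458   1.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.000   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       2.000   2.200   0.000  1.00  0.00           O",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- loadStructure(path)
  ca <- m@atoms[m@atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$y, 0)  # occupancy 0.60 conformer won
})

test_that("chain filtering errors on absent chains and preserves order", {
  b <- makeBarrel(packing = "Type-1", seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(b$model, path)
  expect_error(loadStructure(path, chains = c("A", "Z")), "absent")
  mA <- loadStructure(path, chains = "A")
  expect_identical(unique(mA@residues$chain), "A")
  expect_identical(mA@residues$resno, sort(mA@residues$resno))
})

test_that("ligand extraction never captures polymer residues", {
  b <- makeBarrel(packing = "Type-2", hemeMode = "cavity_beta2", seed = 9)
  for (lig in b$model@ligands)
    expect_true(all(lig@atoms$type == "HETATM"))
})

test_that("writing an empty model is an error", {
  empty <- new("StructureModel", id = "X",
               atoms = FdxBarrel:::buildStructureModel(
                 data.frame(type = character(), elety = character(),
                            alt = character(), resid = character(),
                            chain = character(), resno = integer(),
                            insert = character(), x = numeric(),
                            y = numeric(), z = numeric(), o = numeric(),
                            b = numeric(), elesy = character()), "X")@atoms,
               residues = data.frame(), ligands = list(), model = 1L)
  expect_error(writeStructure(empty, tempfile()), "empty")
})

test_that("unparseable input raises a format error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("this is", "not a structure"), path)
  expect_error(loadStructure(path), "parse|format|PDB")
})
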