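#' @importFrom bio3d read.pdb read.cif
NULL

## Default set of heme-like het codes: protoporphyrin IX (HEM), heme C/B
## variants, and the sirohydrochlorin/siroheme codes used by siroheme
## decarboxylase entries. Configurable everywhere it is consumed because
## siroheme codes vary across PDB entries.
DEFAULT_HEME_CODES <- c("HEM", "HEC", "HEB", "SRM", "SHH")

WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

## Atom names of the porphyrin/isobacteriochlorin macrocycle heavy atoms
## (4 pyrrole N, 16 pyrrole C, 4 meso C) by PDB convention.
MACROCYCLE_ATOMS <- c(
  "NA", "NB", "NC", "ND",
  as.vector(outer(paste0("C", 1:4), c("A", "B", "C", "D"), paste0)),
  "CHA", "CHB", "CHC", "CHD")

## Build a StructureModel from a normalized atom table. Shared by the file
## reader and the synthetic generator.
buildStructureModel <- function(atoms, id, model = 1L,
                                hemeCodes = DEFAULT_HEME_CODES) {
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$alt <- if ("alt" %in% names(atoms)) ifelse(is.na(atoms$alt), "", atoms$alt) else ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  if (!"elesy" %in% names(atoms) || all(is.na(atoms$elesy)))
    atoms$elesy <- substr(gsub("[0-9']", "", atoms$elety), 1, 1)

  pol <- atoms$type == "ATOM"
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  polkey <- unique(key[pol])
  atoms$residx <- rep(NA_integer_, nrow(atoms))
  atoms$residx[pol] <- match(key[pol], polkey)

  first <- !duplicated(key[pol])
  residues <- data.frame(
    residx = seq_along(polkey),
    chain = atoms$chain[pol][first],
    resno = atoms$resno[pol][first],
    insert = atoms$insert[pol][first],
    resid = atoms$resid[pol][first],
    stringsAsFactors = FALSE)

  ligands <- extractLigands(atoms, hemeCodes)
  new("StructureModel", id = id, atoms = atoms, residues = residues,
      ligands = ligands, model = as.integer(model))
}

extractLigands <- function(atoms, hemeCodes) {
  het <- atoms$type == "HETATM" & atoms$resid %in% hemeCodes
  if (!any(het)) return(list())
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, sep = "|")
  out <- list()
  for (k in unique(key[het])) {
    rows <- atoms[het & key == k, , drop = FALSE]
    isFe <- (!is.na(rows$elesy) & toupper(rows$elesy) == "FE") | rows$elety == "FE"
    fePos <- if (any(isFe))
      as.numeric(rows[which(isFe)[1], c("x", "y", "z")]) else numeric(0)
    macro <- rows[rows$elety %in% MACROCYCLE_ATOMS, , drop = FALSE]
    out[[length(out) + 1L]] <- new("LigandGroup",
      hetCode = rows$resid[1], chain = rows$chain[1],
      resno = as.integer(rows$resno[1]), insert = rows$insert[1],
      atoms = rows, fePos = fePos, macrocycle = macro)
  }
  out
}

#' Read a PDB or mmCIF file into a StructureModel
#'
#' Parses coordinates with \pkg{bio3d}, keeps a single coordinate model,
#' collapses alternate locations to the highest-occupancy conformer, drops
#' waters, and collects heme-like HETATM groups into [LigandGroup-class]
#' objects (iron position from the FE atom, macrocycle heavy atoms by PDB
#' atom-name convention).
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chains optional character vector of chain identifiers to retain.
#' @param model coordinate model number (default 1; X-ray entries have one).
#' @param hemeCodes het codes treated as heme-like.
#' @return a [StructureModel-class].
#' @examples
#' b <- makeBarrel(packing = "Type-1", hemeMode = "cleft_alpha2", seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(b$model, f)
#' m <- loadStructure(f)
#' m
#' @export
loadStructure <- function(path, chains = NULL, model = 1L,
                          hemeCodes = DEFAULT_HEME_CODES) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch({
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = (model > 1), verbose = FALSE)
  }, error = function(e) stop("cannot parse structure file '", path,
                              "': ", conditionMessage(e)))
  atoms <- pdb$atom
  if (model > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model)
      stop("requested model ", model, " not present")
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms <- atoms[!(atoms$resid %in% WATER_CODES), , drop = FALSE]
  if (!nrow(atoms)) stop("no atom records parsed from '", path, "'")
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(atoms$chain))
    if (length(missing))
      stop("requested chain(s) absent: ", paste(missing, collapse = ", "))
    atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  }
  ## altloc: keep the highest-occupancy conformer per atom
  alt <- ifelse(is.na(atoms$alt), "", atoms$alt)
  if (any(nzchar(alt))) {
    occ <- ifelse(is.na(atoms$o), 1, atoms$o)
    ord0 <- seq_len(nrow(atoms))
    keep <- ord0[order(-occ, alt)]
    akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
                  atoms$elety, sep = "|")
    keep <- keep[!duplicated(akey[keep])]
    atoms <- atoms[sort(keep), , drop = FALSE]
    atoms$alt <- ""
  }
  rownames(atoms) <- NULL
  id <- toupper(sub("\\.[^.]*$", "", basename(path)))
  buildStructureModel(atoms, id = id, model = model, hemeCodes = hemeCodes)
}

#' Write a StructureModel to a PDB file
#'
#' Emits fixed-width ATOM/HETATM records; `loadStructure()` on the result
#' reproduces residue and atom identities and coordinates to 1e-3 Å (the
#' format's printed precision).
#'
#' @param model a [StructureModel-class] with at least one atom.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeStructure <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  if (!nrow(a)) stop("refusing to write an empty model")
  name4 <- ifelse(nchar(a$elety) >= 4, a$elety,
                  paste0(" ", formatC(a$elety, width = -3)))
  lines <- sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$type, seq_len(nrow(a)) %% 100000, name4, "",
                   a$resid, a$chain, a$resno, a$insert,
                   a$x, a$y, a$z, a$o, a$b, toupper(a$elesy))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' Fetch a PDB entry (optional convenience)
#'
#' Thin wrapper around `utils::download.file()` for users with network
#' access; nothing in the package or its tests requires it.
#'
#' @param id four-character PDB identifier.
#' @param dir destination directory.
#' @param format "pdb" or "cif".
#' @return the downloaded file path.
#' @export
pdbFetch <- function(id, dir = ".", format = c("pdb", "cif")) {
  format <- match.arg(format)
  id <- toupper(id)
  dest <- file.path(dir, paste0(id, ".", format))
  url <- sprintf("https://files.rcsb.org/download/%s.%s", id, format)
  utils::download.file(url, dest, quiet = TRUE)
  dest
}

## Cα coordinate matrix for a set of internal residue indices (rows in order
## of residx); rows are NA-free or an error is raised.
caCoords <- function(model, residx) {
  a <- model@atoms
  ca <- a[!is.na(a$residx) & a$elety == "CA", , drop = FALSE]
  m <- match(residx, ca$residx)
  if (anyNA(m)) stop("missing CA atom for residue index ",
                     paste(residx[is.na(m)], collapse = ","))
  as.matrix(ca[m, c("x", "y", "z"), drop = FALSE])
}

## Backbone atom positions (N, CA, C, O) per residue as a list of matrices.
backboneCoords <- function(model) {
  a <- model@atoms
  bb <- a[!is.na(a$residx) & a$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  out <- vector("list", nrow(model@residues))
  idx <- split(seq_len(nrow(bb)), bb$residx)
  for (k in names(idx)) {
    rows <- bb[idx[[k]], , drop = FALSE]
    m <- as.matrix(rows[match(c("N", "CA", "C", "O"), rows$elety),
                        c("x", "y", "z")])
    rownames(m) <- c("N", "CA", "C", "O")
    out[[as.integer(k)]] <- m
  }
  out
}

## One-letter sequence of a residue-index vector (X for non-standard).
seqOneLetter <- function(model, residx) {
  r <- model@residues
  aa <- bio3d::aa321(r$resid[match(residx, r$residx)])
  aa[is.na(aa)] <- "X"
  aa
}
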