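#' @import methods
NULL

## Canonical element labels of a ferredoxin-like domain in sequence order.
FDX_LABELS <- c("b1", "a1", "b2", "b3", "a2", "b4")

## Pretty (unicode) forms used in reports and strand-order strings.
prettyLabel <- function(x) {
  map <- c(b1 = "β1", b2 = "β2", b3 = "β3", b4 = "β4",
           a1 = "α1", a2 = "α2",
           b5 = "β5", b6 = "β6", b7 = "β7", b8 = "β8",
           a3 = "α3", a4 = "α4")
  unname(map[x])
}

#' Parsed macromolecular structure
#'
#' One coordinate model of a PDB/mmCIF entry: an atom table, a polymer residue
#' table with contiguous internal indices (`residx`), and the extracted
#' heme-like ligand groups. Public residue identity is author numbering
#' (`chain`, `resno`, `insert`), the convention used when citing residues such
#' as the proximal His of a heme site.
#'
#' @slot id structure identifier (file stem or PDB id).
#' @slot atoms data.frame of atom records (both ATOM and HETATM).
#' @slot residues data.frame of polymer residues, one row per `residx`.
#' @slot ligands list of [LigandGroup-class] objects.
#' @slot model model number retained.
#' @exportClass StructureModel
setClass("StructureModel",
  representation(id = "character", atoms = "data.frame",
                 residues = "data.frame", ligands = "list", model = "integer"))

setValidity("StructureModel", function(object) {
  need <- c("type", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "b", "elesy", "residx")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms table lacks columns:",
                 paste(setdiff(need, names(object@atoms)), collapse = ", ")))
  r <- object@residues
  if (nrow(r)) {
    key <- paste(r$chain, r$resno, r$insert)
    if (anyDuplicated(key)) return("duplicate residue keys (chain, resno, insert)")
    if (!identical(r$residx, seq_len(nrow(r))))
      return("residue internal indices must be 1..n in order")
  }
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && !all(is.finite(xyz))) return("non-finite coordinates")
  TRUE
})

#' Heme-like ligand group
#'
#' A HETATM residue from the configurable heme-like code set (HEM, HEC, HEB,
#' SRM, SHH by default) with its iron position and porphyrin/isobacteriochlorin
#' macrocycle heavy atoms identified by atom-name convention.
#'
#' @slot hetCode three-letter het code.
#' @slot chain,resno,insert author identity of the ligand residue.
#' @slot atoms data.frame with all atoms of the group.
#' @slot fePos numeric(3) iron position, or numeric(0) when no FE atom exists.
#' @slot macrocycle data.frame with the ring heavy atoms (N and C).
#' @exportClass LigandGroup
setClass("LigandGroup",
  representation(hetCode = "character", chain = "character", resno = "integer",
                 insert = "character", atoms = "data.frame",
                 fePos = "numeric", macrocycle = "data.frame"))

setValidity("LigandGroup", function(object) {
  if (length(object@fePos) %in% c(0L, 3L)) TRUE else "fePos must be length 0 or 3"
})

#' Barrel sheet: the cyclic strand-pairing of an eight-stranded barrel
#'
#' @slot strands integer vector of element-row indices in cyclic order
#'   (length 8 when closed).
#' @slot orientations orientation ("antiparallel"/"parallel") between each
#'   cyclically adjacent strand pair.
#' @slot axis unit barrel axis; sign fixed so the first chain N-terminus
#'   projects negatively.
#' @slot center mean of strand midpoints.
#' @slot closed TRUE when the pairing graph contains a single 8-cycle
#'   covering the core strands.
#' @slot elements the secondary-structure element table the indices refer to.
#' @slot radial mean radial distance of core strand midpoints from the axis.
#' @slot diagnostics human-readable notes (e.g. open-sheet diagnosis).
#' @exportClass BarrelSheet
setClass("BarrelSheet",
  representation(strands = "integer", orientations = "character",
                 axis = "numeric", center = "numeric", closed = "logical",
                 elements = "data.frame", radial = "numeric",
                 diagnostics = "character"))

#' One ferredoxin-like domain with labeled core elements
#'
#' @slot chain chain identifier.
#' @slot elementIdx named integer vector mapping labels b1,a1,b2,b3,a2,b4 to
#'   rows of the element table (NA for a missing/degraded helix).
#' @slot span internal residue index range (start, end) of the domain.
#' @slot fused TRUE when the domain is one half of a tandem fusion.
#' @slot half 1 or 2 for fused halves, 0 otherwise.
#' @slot relaxed TRUE when a helix label could not be assigned (degraded
#'   helix tolerance).
#' @slot elementResidues named list label -> internal residue index vector,
#'   so a domain is self-contained for superposition.
#' @exportClass FerredoxinDomain
setClass("FerredoxinDomain",
  representation(chain = "character", elementIdx = "integer", span = "integer",
                 fused = "logical", half = "integer", relaxed = "logical",
                 elementResidues = "list"))

#' Two ferredoxin-like domains assembled into a barrel
#'
#' @slot domainA,domainB the labeled domains (A precedes B in chain/sequence
#'   order).
#' @slot sheet the [BarrelSheet-class].
#' @slot arrangement "homodimer", "heterodimer" or "fused".
#' @slot barrelLabels named integer vector mapping barrel-level labels
#'   (b1..b8, a1..a4) to element rows for fused barrels (empty otherwise).
#' @slot elements the element table.
#' @slot identity sequence identity between the two domains (fraction).
#' @exportClass BarrelModel
setClass("BarrelModel",
  representation(domainA = "FerredoxinDomain", domainB = "FerredoxinDomain",
                 sheet = "BarrelSheet", arrangement = "character",
                 barrelLabels = "integer", elements = "data.frame",
                 identity = "numeric"))

#' Type-1 / Type-2 packing classification of a barrel
#'
#' @slot packing "Type-1", "Type-2" or "unclassified".
#' @slot interDomainPairs data.frame of the strand pairs crossing the domain
#'   boundary in the 8-cycle.
#' @slot orderString cyclic strand order in arrow notation, starting at
#'   domain A beta2.
#' @slot terminiConsistent TRUE when termini axial positions corroborate the
#'   packing call (advisory).
#' @slot diagnostics evidence and warnings.
#' @exportClass PackingCall
setClass("PackingCall",
  representation(packing = "character", interDomainPairs = "data.frame",
                 orderString = "character", terminiConsistent = "logical",
                 diagnostics = "character"))

#' Residue-level correspondence between two ferredoxin-like domains
#'
#' @slot kind "direct", "rotated", "permuted" or "rotated+permuted".
#' @slot elementMap named character vector label(A) -> label(B).
#' @slot pairs two-column matrix of paired internal residue indices (A, B).
#' @slot rotation 3x3 proper rotation taking A coordinates onto B.
#' @slot translation translation component.
#' @slot rmsd RMSD over the final pair set.
#' @slot nPairs number of residue pairs.
#' @slot score number of pairs within the scoring distance after the fit.
#' @slot seqIdentity fraction of paired residues with identical amino acid.
#' @exportClass DomainCorrespondence
setClass("DomainCorrespondence",
  representation(kind = "character", elementMap = "character",
                 pairs = "matrix", rotation = "matrix",
                 translation = "numeric", rmsd = "numeric", nPairs = "integer",
                 score = "integer", seqIdentity = "numeric"))

setValidity("DomainCorrespondence", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6) return("rotation not orthonormal")
  if (det(R) < 0) return("rotation must be proper (det +1)")
  if (length(object@rmsd) && object@rmsd < 0) return("rmsd must be >= 0")
  if (nrow(object@pairs) != object@nPairs) return("nPairs != nrow(pairs)")
  TRUE
})

#' A located and classified heme/siroheme binding site
#'
#' @slot ligand the [LigandGroup-class].
#' @slot proximal list(chain, resno, insert, resid, atom, dist, residx) for
#'   the axial residue nearest the iron, or empty list when absent.
#' @slot distal same shape for the distal-face residue, or empty.
#' @slot hostDomain domain-level host element of the proximal residue, e.g.
#'   "a2" with domain tag.
#' @slot hostBarrel barrel-level label for fused barrels ("" otherwise).
#' @slot mode "SITE_CLEFT_ISDG_OXDA", "SITE_CLD_DYP", "SITE_CAVITY" or
#'   "undetermined".
#' @slot feRadial distance of the iron from the barrel axis.
#' @slot rufflingRMS RMS out-of-plane deviation of the macrocycle.
#' @slot ruffled TRUE when rufflingRMS exceeds the configured threshold.
#' @slot diagnostics evidence notes.
#' @exportClass HemeSite
setClass("HemeSite",
  representation(ligand = "LigandGroup", proximal = "list", distal = "list",
                 hostDomain = "character", hostBarrel = "character",
                 mode = "character", feRadial = "numeric",
                 rufflingRMS = "numeric", ruffled = "logical",
                 diagnostics = "character"))
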