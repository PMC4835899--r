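#' Accessors
#'
#' Small accessor generics for the package's S4 containers; user code should
#' use these rather than reaching into slots.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname accessors
#' @export
setGeneric("ligandGroups", function(x) standardGeneric("ligandGroups"))

#' @rdname accessors
#' @export
setGeneric("packingType", function(x) standardGeneric("packingType"))

#' @rdname accessors
#' @export
setGeneric("strandOrder", function(x) standardGeneric("strandOrder"))

#' @rdname accessors
#' @export
setGeneric("mappingKind", function(x) standardGeneric("mappingKind"))

#' @rdname accessors
#' @export
setGeneric("alignmentRMSD", function(x) standardGeneric("alignmentRMSD"))

#' @rdname accessors
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))

#' @rdname accessors
#' @export
setGeneric("siteMode", function(x) standardGeneric("siteMode"))

#' @rdname accessors
#' @export
setMethod("structureId", "StructureModel", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("residueTable", "StructureModel", function(x) x@residues)

#' @rdname accessors
#' @export
setMethod("ligandGroups", "StructureModel", function(x) x@ligands)

#' @rdname accessors
#' @export
setMethod("packingType", "PackingCall", function(x) x@packing)

#' @rdname accessors
#' @export
setMethod("strandOrder", "PackingCall", function(x) x@orderString)

#' @rdname accessors
#' @export
setMethod("mappingKind", "DomainCorrespondence", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("alignmentRMSD", "DomainCorrespondence", function(x) x@rmsd)

#' @rdname accessors
#' @export
setMethod("pairCount", "DomainCorrespondence", function(x) x@nPairs)

#' @rdname accessors
#' @export
setMethod("siteMode", "HemeSite", function(x) x@mode)

setMethod("show", "StructureModel", function(object) {
  ch <- unique(object@residues$chain)
  cat("StructureModel", object@id, "\n")
  cat("  ", nrow(object@residues), "polymer residues in",
      length(ch), "chain(s):", paste(ch, collapse = " "), "\n")
  cat("  ", nrow(object@atoms), "atoms;",
      length(object@ligands), "heme-like ligand group(s)\n")
  invisible(object)
})

setMethod("show", "BarrelSheet", function(object) {
  cat("BarrelSheet:", if (object@closed) "closed 8-stranded barrel"
      else "open sheet", "\n")
  if (length(object@strands))
    cat("  cycle:", paste(object@strands, collapse = " "), "\n")
  cat("  axis: (", paste(sprintf("%.3f", object@axis), collapse = ", "),
      "), mean radius ", sprintf("%.2f", object@radial), " Å\n", sep = "")
  invisible(object)
})

setMethod("show", "BarrelModel", function(object) {
  cat("BarrelModel (", object@arrangement, ")\n", sep = "")
  for (d in list(object@domainA, object@domainB)) {
    lab <- names(d@elementIdx)[!is.na(d@elementIdx)]
    cat("  domain", if (d@fused) paste0("half ", d@half) else d@chain,
        ": elements", paste(prettyLabel(lab), collapse = " "),
        if (d@relaxed) "(relaxed: missing helix)" else "", "\n")
  }
  invisible(object)
})

setMethod("show", "PackingCall", function(object) {
  cat("PackingCall:", object@packing, "\n")
  if (nzchar(object@orderString))
    cat("  strand order:", object@orderString, "\n")
  cat("  termini consistent:", object@terminiConsistent, "\n")
  invisible(object)
})

setMethod("show", "DomainCorrespondence", function(object) {
  cat(sprintf("DomainCorrespondence [%s]: RMSD %.3f Å over %d pairs\n",
              object@kind, object@rmsd, object@nPairs))
  invisible(object)
})

setMethod("show", "HemeSite", function(object) {
  cat("HemeSite", object@ligand@hetCode, "->", object@mode, "\n")
  if (length(object@proximal))
    cat(sprintf("  proximal %s %s%d (%s, %.2f Å), host %s\n",
                object@proximal$resid, object@proximal$chain,
                object@proximal$resno, object@proximal$atom,
                object@proximal$dist, object@hostDomain))
  cat(sprintf("  ruffling RMS %.3f Å (%s)\n", object@rufflingRMS,
              if (object@ruffled) "ruffled" else "planar"))
  invisible(object)
})
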