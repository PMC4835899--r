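## Identification and labeling of the two ferredoxin-like domains
## (beta1-alpha1-beta2-beta3-alpha2-beta4 per domain).

## Center-anchored residue pairing of two index vectors: truncate to the
## shorter one, anchored at the element midpoints.
centerAnchoredPairs <- function(ia, ib) {
  m <- min(length(ia), length(ib))
  offA <- (length(ia) - m) %/% 2
  offB <- (length(ib) - m) %/% 2
  cbind(ia[offA + seq_len(m)], ib[offB + seq_len(m)])
}

## Build one labeled domain from four core strand element rows (chain order).
domainFromStrands <- function(elements, strandIds, chain,
                              fused = FALSE, half = 0L) {
  s <- strandIds[order(elements$start[strandIds])]
  idx <- c(b1 = s[1], a1 = NA_integer_, b2 = s[2],
           b3 = s[3], a2 = NA_integer_, b4 = s[4])
  helices <- which(elements$kind == "helix" & elements$chain == chain)
  pickHelix <- function(afterEl, beforeEl) {
    cand <- helices[elements$start[helices] > elements$end[afterEl] &
                    elements$end[helices] < elements$start[beforeEl]]
    if (!length(cand)) return(NA_integer_)
    cand[which.max(elements$end[cand] - elements$start[cand])]
  }
  idx["a1"] <- pickHelix(s[1], s[2])
  idx["a2"] <- pickHelix(s[3], s[4])
  relaxed <- anyNA(idx[c("a1", "a2")])
  used <- idx[!is.na(idx)]
  span <- c(min(elements$start[used]), max(elements$end[used]))
  elementResidues <- lapply(idx, function(e)
    if (is.na(e)) integer(0) else elements$start[e]:elements$end[e])
  new("FerredoxinDomain", chain = chain, elementIdx = idx,
      span = as.integer(span), fused = fused, half = as.integer(half),
      relaxed = relaxed, elementResidues = elementResidues)
}

## Residue indices of a domain element (label like "b2"); integer(0) if absent.
domainElementResidues <- function(domain, elements, label) {
  e <- domain@elementIdx[[label]]
  if (is.na(e)) return(integer(0))
  elements$start[e]:elements$end[e]
}

## Sequence identity between two labeled domains over center-anchored pairs
## of equivalent elements.
domainIdentity <- function(domA, domB, elements, model) {
  same <- 0L; tot <- 0L
  for (lab in FDX_LABELS) {
    ia <- domainElementResidues(domA, elements, lab)
    ib <- domainElementResidues(domB, elements, lab)
    if (!length(ia) || !length(ib)) next
    p <- centerAnchoredPairs(ia, ib)
    sa <- seqOneLetter(model, p[, 1]); sb <- seqOneLetter(model, p[, 2])
    same <- same + sum(sa == sb); tot <- tot + nrow(p)
  }
  if (tot == 0) NA_real_ else same / tot
}

#' Map and label the two ferredoxin-like domains of a barrel
#'
#' Core strands are the members of the sheet's 8-cycle; peripheral
#' decorations are skipped. A chain contributing four core strands hosts one
#' domain; eight core strands on one chain mean tandemly duplicated, fused
#' domains (halves ordered by sequence). Strands are labeled β1-β4 in chain
#' order; α1 is the (longest) helix between β1 and β2, α2 between β3 and β4.
#' A missing helix is tolerated (degraded-helix case) and flagged via the
#' domain's `relaxed` slot. Two separate chains give a homodimer when their
#' domain sequence identity exceeds `identityThreshold`, else a heterodimer.
#'
#' @param elements element data.frame.
#' @param sheet a closed [BarrelSheet-class] (set `requireClosed = FALSE` to
#'   override).
#' @param model the [StructureModel-class].
#' @param identityThreshold homodimer sequence-identity threshold.
#' @param requireClosed error when the sheet is not a closed 8-cycle.
#' @return a [BarrelModel-class].
#' @export
mapDomains <- function(elements, sheet, model, identityThreshold = 0.95,
                       requireClosed = TRUE) {
  if (requireClosed && !sheet@closed)
    stop("sheet is not a closed 8-stranded barrel (", sheet@diagnostics, ")")
  core <- sheet@strands
  if (length(core) < 8 && requireClosed)
    stop("fewer than eight core strands")
  chains <- unique(elements$chain[core])
  domains <- list()
  for (ch in chains) {
    cs <- core[elements$chain[core] == ch]
    cs <- cs[order(elements$start[cs])]
    if (length(cs) == 4) {
      domains[[length(domains) + 1L]] <- domainFromStrands(elements, cs, ch)
    } else if (length(cs) == 8) {
      domains[[length(domains) + 1L]] <-
        domainFromStrands(elements, cs[1:4], ch, fused = TRUE, half = 1L)
      domains[[length(domains) + 1L]] <-
        domainFromStrands(elements, cs[5:8], ch, fused = TRUE, half = 2L)
    } else {
      stop("chain ", ch, " contributes ", length(cs),
           " core strands; cannot partition into ferredoxin-like domains. ",
           "Candidate strand elements: ",
           paste(cs, collapse = ", "))
    }
  }
  if (length(domains) != 2)
    stop("expected two ferredoxin-like domains, found ", length(domains),
         "; candidate elements per chain: ",
         paste(vapply(chains, function(ch)
           paste0(ch, ":", sum(elements$chain[core] == ch)), character(1)),
           collapse = " "))
  ## order: by chain appearance then sequence
  ord <- order(vapply(domains, function(d)
    match(d@chain, unique(model@residues$chain)), integer(1)),
    vapply(domains, function(d) d@span[1], integer(1)))
  domA <- domains[[ord[1]]]; domB <- domains[[ord[2]]]

  fused <- domA@fused && domB@fused && domA@chain == domB@chain
  ident <- domainIdentity(domA, domB, elements, model)
  arrangement <- if (fused) "fused"
    else if (!is.na(ident) && ident > identityThreshold) "homodimer"
    else "heterodimer"

  barrelLabels <- integer(0)
  if (fused) {
    barrelLabels <- c(
      b1 = domA@elementIdx[["b1"]], a1 = domA@elementIdx[["a1"]],
      b2 = domA@elementIdx[["b2"]], b3 = domA@elementIdx[["b3"]],
      a2 = domA@elementIdx[["a2"]], b4 = domA@elementIdx[["b4"]],
      b5 = domB@elementIdx[["b1"]], a3 = domB@elementIdx[["a1"]],
      b6 = domB@elementIdx[["b2"]], b7 = domB@elementIdx[["b3"]],
      a4 = domB@elementIdx[["a2"]], b8 = domB@elementIdx[["b4"]])
  }

  ## annotate the element table with domain/label tags
  elements$label <- ""
  elements$domain <- ""
  for (dn in c("A", "B")) {
    d <- if (dn == "A") domA else domB
    for (lab in FDX_LABELS) {
      e <- d@elementIdx[[lab]]
      if (!is.na(e)) { elements$label[e] <- lab; elements$domain[e] <- dn }
    }
  }
  new("BarrelModel", domainA = domA, domainB = domB, sheet = sheet,
      arrangement = arrangement, barrelLabels = barrelLabels,
      elements = elements, identity = if (is.na(ident)) numeric(0) else ident)
}

#' Axial coordinates of a domain's termini
#'
#' Projects the Cα of the domain span's first and last residues onto the
#' barrel axis, relative to the barrel center. A same-sign pair means both
#' termini sit on one end of the barrel.
#'
#' @param domain a [FerredoxinDomain-class].
#' @param sheet the [BarrelSheet-class] providing axis and center.
#' @param model the [StructureModel-class].
#' @return named numeric `c(N = ..., C = ...)` axial coordinates in Å.
#' @export
terminiSide <- function(domain, sheet, model) {
  nPos <- as.numeric(caCoords(model, domain@span[1]))
  cPos <- as.numeric(caCoords(model, domain@span[2]))
  c(N = axialCoord(sheet, nPos), C = axialCoord(sheet, cPos))
}
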