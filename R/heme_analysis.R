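## Heme/siroheme site location and classification: proximal and distal axial
## residues, host element, binding-site mode, macrocycle ruffling.

## Side-chain atoms able to coordinate the iron axially (proximal) and
## candidates for the distal functional residue. Distances are standard
## coordination geometry; the source analyses name residues, not distances.
PROXIMAL_ATOMS <- list(HIS = c("NE2", "ND1"), TYR = "OH", CYS = "SG", MET = "SD")
DISTAL_ATOMS <- list(HIS = c("NE2", "ND1"), ARG = c("NH1", "NH2", "NE"),
                     ASN = c("ND2", "OD1"), SER = "OG")

.candidateAtoms <- function(model, spec) {
  a <- model@atoms
  keep <- !is.na(a$residx) & a$resid %in% names(spec)
  rows <- a[keep, , drop = FALSE]
  ok <- vapply(seq_len(nrow(rows)), function(r)
    rows$elety[r] %in% spec[[rows$resid[r]]], logical(1))
  rows[ok, , drop = FALSE]
}

#' Identify proximal and distal axial residues of a heme group
#'
#' The proximal residue holds the side-chain atom (His NE2/ND1, Tyr OH,
#' Cys SG or Met SD) nearest the iron within `axialCutoff`. The distal
#' residue is the nearest candidate (His, Arg, Asn, Ser side-chain atoms)
#' within `distalCutoff` of the iron on the opposite side of the porphyrin
#' plane, or absent. A heme with no proximal candidate within the cutoff is
#' flagged, not an error (the disordered-helix case).
#'
#' @param model a [StructureModel-class].
#' @param ligand a [LigandGroup-class] with an iron position.
#' @param axialCutoff proximal Fe-atom distance cutoff (Å).
#' @param distalCutoff distal Fe-atom distance cutoff (Å).
#' @return list(proximal, distal); each is a list(chain, resno, insert,
#'   resid, atom, dist, residx) or an empty list.
#' @export
findAxialResidues <- function(model, ligand, axialCutoff = 3.5,
                              distalCutoff = 6.0) {
  if (!length(ligand@fePos)) stop("ligand has no iron position")
  fe <- ligand@fePos
  asRecord <- function(row, d) list(
    chain = row$chain, resno = as.integer(row$resno), insert = row$insert,
    resid = row$resid, atom = row$elety, dist = d,
    residx = as.integer(row$residx))

  prox <- .candidateAtoms(model, PROXIMAL_ATOMS)
  proximal <- list()
  if (nrow(prox)) {
    d <- sqrt((prox$x - fe[1])^2 + (prox$y - fe[2])^2 + (prox$z - fe[3])^2)
    k <- which.min(d)
    if (d[k] <= axialCutoff) proximal <- asRecord(prox[k, ], d[k])
  }

  distal <- list()
  if (length(proximal) && nrow(ligand@macrocycle) >= 3) {
    pl <- fitPlane(as.matrix(ligand@macrocycle[, c("x", "y", "z")]))
    sideOf <- function(p) sign(sum((p - pl$center) * pl$normal))
    proxAtom <- prox[which.min(sqrt((prox$x - fe[1])^2 + (prox$y - fe[2])^2 +
                                    (prox$z - fe[3])^2)), ]
    proxSide <- sideOf(c(proxAtom$x, proxAtom$y, proxAtom$z))
    cand <- .candidateAtoms(model, DISTAL_ATOMS)
    cand <- cand[!(cand$residx %in% proximal$residx), , drop = FALSE]
    if (nrow(cand)) {
      d <- sqrt((cand$x - fe[1])^2 + (cand$y - fe[2])^2 + (cand$z - fe[3])^2)
      side <- vapply(seq_len(nrow(cand)), function(r)
        sideOf(c(cand$x[r], cand$y[r], cand$z[r])), numeric(1))
      ok <- d <= distalCutoff & side != proxSide
      if (any(ok)) {
        k <- which(ok)[which.min(d[ok])]
        distal <- asRecord(cand[k, ], d[k])
      }
    }
  }
  list(proximal = proximal, distal = distal)
}

## Which labeled element of the barrel hosts an internal residue index.
hostElement <- function(barrel, residx) {
  el <- barrel@elements
  hit <- which(el$label != "" & el$start <= residx & el$end >= residx)
  if (!length(hit)) return(list(domain = "", label = "", barrel = ""))
  e <- hit[1]
  barrelLab <- ""
  if (length(barrel@barrelLabels)) {
    m <- names(barrel@barrelLabels)[match(e, barrel@barrelLabels)]
    if (!is.na(m)) barrelLab <- m
  }
  list(domain = el$domain[e], label = el$label[e], barrel = barrelLab)
}

#' Classify the binding-site mode of a heme/siroheme group
#'
#' An iron lying inside the β-cylinder (radial distance below
#' `cavityMargin` times the mean core-strand radial distance) is the
#' barrel-cavity mode of siroheme decarboxylase. Otherwise the host element
#' of the proximal residue decides: domain-level α2 is the IsdG/OxdA cleft
#' mode, α1 the Cld/DyP mode; a proximal residue on β2 together with cavity
#' placement is again the cavity mode. Conflicting signals are reported in
#' the diagnostics, never silently resolved.
#'
#' @param barrel a [BarrelModel-class].
#' @param ligand the [LigandGroup-class].
#' @param proximal proximal record from [findAxialResidues()] (may be empty).
#' @param cavityMargin fraction of the mean strand radius below which the
#'   iron counts as in-cavity.
#' @return list(mode, hostDomain, hostBarrel, feRadial, diagnostics).
#' @export
classifySite <- function(barrel, ligand, proximal, cavityMargin = 0.75) {
  sheet <- barrel@sheet
  feRadial <- if (length(ligand@fePos)) radialDist(sheet, ligand@fePos)
              else NA_real_
  inCavity <- !is.na(feRadial) && feRadial < cavityMargin * sheet@radial
  host <- if (length(proximal)) hostElement(barrel, proximal$residx)
          else list(domain = "", label = "", barrel = "")
  hostDomain <- if (nzchar(host$label))
    paste0(prettyLabel(host$label), " (domain ", host$domain, ")") else ""
  diagnostics <- character(0)
  mode <- "undetermined"
  if (inCavity) {
    mode <- "SITE_CAVITY"
    if (nzchar(host$label) && !(host$label %in% c("b2", "b1", "b3", "b4")))
      diagnostics <- c(diagnostics, sprintf(
        "iron in barrel cavity but proximal residue on %s (expected a strand)",
        prettyLabel(host$label)))
  } else if (nzchar(host$label)) {
    mode <- switch(host$label,
      a2 = "SITE_CLEFT_ISDG_OXDA",
      a1 = "SITE_CLD_DYP",
      b2 = { diagnostics <- c(diagnostics,
               "proximal on β2 but iron outside the cavity margin")
             "SITE_CAVITY" },
      { diagnostics <- c(diagnostics, sprintf(
          "proximal residue on unexpected element %s", prettyLabel(host$label)))
        "undetermined" })
  } else {
    diagnostics <- c(diagnostics,
                     "no proximal residue and iron outside the barrel cavity")
  }
  list(mode = mode, hostDomain = hostDomain, hostBarrel = host$barrel,
       feRadial = feRadial,
       diagnostics = paste(diagnostics, collapse = "; "))
}

#' Quantify porphyrin ruffling
#'
#' Fits a least-squares plane to the macrocycle heavy atoms (ring N and C)
#' and reports the root-mean-square out-of-plane deviation; `ruffled` when
#' it exceeds `threshold`.
#'
#' @param ligand a [LigandGroup-class] with at least 12 macrocycle atoms.
#' @param threshold ruffled/planar threshold in Å (qualitative labels in the
#'   literature; the default separates idealized planar and ruffled test
#'   rings cleanly and is configurable).
#' @return list(rms, ruffled).
#' @export
rufflingScore <- function(ligand, threshold = 0.25) {
  m <- ligand@macrocycle
  if (nrow(m) < 12)
    stop("too few macrocycle atoms (", nrow(m), ") to fit a porphyrin plane")
  pl <- fitPlane(as.matrix(m[, c("x", "y", "z")]))
  list(rms = pl$rms, ruffled = pl$rms > threshold)
}

#' Count heme-like groups associated with a barrel
#'
#' A ligand belongs to the barrel when its iron (or macrocycle centroid)
#' lies within `maxDist` of any atom of the barrel chains.
#'
#' @param model a [StructureModel-class].
#' @param chains chain identifiers forming the barrel.
#' @param maxDist association cutoff (Å).
#' @return integer count.
#' @export
countHemes <- function(model, chains, maxDist = 15) {
  a <- model@atoms
  prot <- a[!is.na(a$residx) & a$chain %in% chains, c("x", "y", "z")]
  if (!nrow(prot)) return(0L)
  P <- as.matrix(prot)
  n <- 0L
  for (lig in model@ligands) {
    p <- if (length(lig@fePos)) lig@fePos
         else colMeans(as.matrix(lig@atoms[, c("x", "y", "z")]))
    d2 <- rowSums(sweep(P, 2, p)^2)
    if (min(d2) <= maxDist^2) n <- n + 1L
  }
  n
}

#' Full per-ligand heme-site analysis of a barrel
#'
#' Runs [findAxialResidues()], [classifySite()] and [rufflingScore()] for
#' every heme-like ligand group and assembles [HemeSite-class] objects.
#'
#' @param barrel a [BarrelModel-class].
#' @param model the [StructureModel-class].
#' @param axialCutoff,distalCutoff,cavityMargin,ruffleThreshold thresholds
#'   passed to the stage functions.
#' @return list of [HemeSite-class] objects (possibly empty).
#' @export
analyzeHemeSites <- function(barrel, model, axialCutoff = 3.5,
                             distalCutoff = 6.0, cavityMargin = 0.75,
                             ruffleThreshold = 0.25) {
  out <- list()
  for (lig in model@ligands) {
    diagnostics <- character(0)
    if (!length(lig@fePos)) {
      diagnostics <- c(diagnostics, "no iron atom in ligand group")
      ax <- list(proximal = list(), distal = list())
    } else {
      ax <- findAxialResidues(model, lig, axialCutoff, distalCutoff)
      if (!length(ax$proximal))
        diagnostics <- c(diagnostics,
          "no proximal candidate within the axial cutoff")
    }
    site <- classifySite(barrel, lig, ax$proximal, cavityMargin)
    ruff <- if (nrow(lig@macrocycle) >= 12) rufflingScore(lig, ruffleThreshold)
            else list(rms = NA_real_, ruffled = NA)
    if (nzchar(site$diagnostics))
      diagnostics <- c(diagnostics, site$diagnostics)
    out[[length(out) + 1L]] <- new("HemeSite",
      ligand = lig, proximal = ax$proximal, distal = ax$distal,
      hostDomain = site$hostDomain, hostBarrel = site$hostBarrel,
      mode = site$mode, feRadial = site$feRadial,
      rufflingRMS = ruff$rms, ruffled = isTRUE(ruff$ruffled),
      diagnostics = paste(diagnostics, collapse = "; "))
  }
  out
}
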