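## Secondary-structure assignment from backbone hydrogen bonding.
##
## A deliberately minimal two-state (helix/strand) assignment in the
## Kabsch-Sander tradition: amide hydrogens are placed geometrically, an
## electrostatic dipole-dipole energy is computed for donor/acceptor pairs,
## 4-turns define helices and bridge ladders define strands. 3-10/pi helices,
## isolated beta-bridges, bends and accessibility are out of scope; the
## downstream topology analysis only needs the helix/strand distinction.

HB_ENERGY_CONST <- 0.084 * 332  # kcal*Angstrom/mol, dipole-dipole prefactor

#' Detect backbone hydrogen bonds
#'
#' Amide H is placed 1.0 Å from N along the bisector opposite the N's two
#' bonded neighbours (preceding C and own CA). For each donor/acceptor pair
#' the electrostatic energy
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol is
#' computed from the four N,H,O,C distances; bonds with `E < cutoff` are
#' retained, at most the best two per donor. Prolines and chain-initial
#' residues do not donate. Residues with incomplete backbones are skipped
#' with a warning.
#'
#' @param model a [StructureModel-class] with backbone N, CA, C, O atoms.
#' @param cutoff energy cutoff in kcal/mol (default -0.5).
#' @param maxCaDist Cα-Cα prefilter distance in Å.
#' @return data.frame with columns `donor`, `acceptor` (internal residue
#'   indices) and `energy`.
#' @export
detectHBonds <- function(model, cutoff = -0.5, maxCaDist = 9) {
  res <- model@residues
  n <- nrow(res)
  if (n == 0) return(data.frame(donor = integer(), acceptor = integer(),
                                energy = numeric()))
  bb <- backboneCoords(model)
  getAtom <- function(i, k) if (!is.null(bb[[i]])) bb[[i]][k, ] else rep(NA_real_, 3)
  N <- t(vapply(seq_len(n), getAtom, numeric(3), k = 1L))
  CA <- t(vapply(seq_len(n), getAtom, numeric(3), k = 2L))
  C <- t(vapply(seq_len(n), getAtom, numeric(3), k = 3L))
  O <- t(vapply(seq_len(n), getAtom, numeric(3), k = 4L))

  incomplete <- !stats::complete.cases(cbind(N, CA, C))
  if (any(incomplete))
    warning(sum(incomplete), " residue(s) with incomplete backbone skipped")

  ## place amide hydrogens
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (incomplete[i]) next
    if (res$resid[i] == "PRO") next
    prev <- i - 1L
    if (prev < 1L || res$chain[prev] != res$chain[i] || incomplete[prev]) next
    u1 <- C[prev, ] - N[i, ]; u2 <- CA[i, ] - N[i, ]
    if (vnorm(u1) > 2.0 || vnorm(u1) < 0.5) next  # broken chain
    dir <- -(unitv(u1) + unitv(u2))
    if (vnorm(dir) < 1e-6) next
    H[i, ] <- N[i, ] + unitv(dir)
  }

  ok <- stats::complete.cases(cbind(N, CA, C, O))
  donors <- which(!is.na(H[, 1]))
  acceptors <- which(ok)
  if (!length(donors) || !length(acceptors))
    return(data.frame(donor = integer(), acceptor = integer(), energy = numeric()))

  ## CA-CA prefilter
  dmat <- as.matrix(stats::dist(CA))
  out <- vector("list", length(donors))
  for (k in seq_along(donors)) {
    i <- donors[k]
    js <- acceptors[abs(acceptors - i) >= 2 & dmat[i, acceptors] < maxCaDist]
    if (!length(js)) next
    rON <- sqrt(rowSums((O[js, , drop = FALSE] -
                           matrix(N[i, ], length(js), 3, byrow = TRUE))^2))
    rOH <- sqrt(rowSums((O[js, , drop = FALSE] -
                           matrix(H[i, ], length(js), 3, byrow = TRUE))^2))
    rCN <- sqrt(rowSums((C[js, , drop = FALSE] -
                           matrix(N[i, ], length(js), 3, byrow = TRUE))^2))
    rCH <- sqrt(rowSums((C[js, , drop = FALSE] -
                           matrix(H[i, ], length(js), 3, byrow = TRUE))^2))
    bad <- pmin(rON, rOH, rCN, rCH) < 0.5
    e <- HB_ENERGY_CONST * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    keep <- !bad & e < cutoff
    if (!any(keep)) next
    e <- e[keep]; js <- js[keep]
    if (length(e) > 2) { o <- order(e)[1:2]; e <- e[o]; js <- js[o] }
    out[[k]] <- data.frame(donor = i, acceptor = js, energy = e)
  }
  hb <- do.call(rbind, out)
  if (is.null(hb)) hb <- data.frame(donor = integer(), acceptor = integer(),
                                    energy = numeric())
  rownames(hb) <- NULL
  hb
}

## Safe H-bond lookup matrix (donor row, acceptor column).
.hbMatrix <- function(hbonds, n) {
  m <- matrix(FALSE, n, n)
  if (nrow(hbonds)) m[cbind(hbonds$donor, hbonds$acceptor)] <- TRUE
  m
}

#' Assign helix/strand elements from hydrogen bonds
#'
#' Helices come from consecutive 4-turns (N-H of residue i+4 to C=O of
#' residue i); strands from ladders of two or more consecutive parallel or
#' antiparallel bridges (Kabsch-Sander bridge patterns). Runs shorter than
#' the minimum element lengths are dropped and residues marked both ways
#' resolve strand-over-helix.
#'
#' @param model a [StructureModel-class].
#' @param hbonds data.frame from [detectHBonds()].
#' @param minStrand,minHelix minimum element lengths in residues.
#' @return data.frame of elements: `kind` ("strand"/"helix"), `chain`,
#'   `start`, `end` (internal residue indices, inclusive), `label` (blank;
#'   assigned by [mapDomains()]).
#' @export
assignSS <- function(model, hbonds, minStrand = 3, minHelix = 4) {
  res <- model@residues
  n <- nrow(res)
  if (n == 0 || !nrow(hbonds)) return(emptyElements())
  hb <- .hbMatrix(hbonds, n)
  sameChain <- function(i, j) res$chain[i] == res$chain[j]

  state <- rep("-", n)

  ## helices: two consecutive 4-turns mark the four bracketed residues
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n - 4))
    turn4[i] <- hb[i + 4, i] && sameChain(i, i + 4)
  for (i in seq_len(max(0, n - 5)))
    if (turn4[i] && turn4[i + 1]) state[(i + 1):(i + 4)] <- "H"

  ## bridges
  hbS <- function(d, a) d >= 1 && d <= n && a >= 1 && a <= n && hb[d, a]
  bridges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + 3) next
      anti <- (hbS(i, j) && hbS(j, i)) || (hbS(j + 1, i - 1) && hbS(i + 1, j - 1))
      par <- (hbS(j, i - 1) && hbS(i + 1, j)) || (hbS(i, j - 1) && hbS(j + 1, i))
      if (anti || par)
        bridges[[length(bridges) + 1L]] <-
          c(i = i, j = j, anti = as.integer(anti && !par))
    }
  }
  if (length(bridges)) {
    B <- do.call(rbind, bridges)
    bkey <- paste(B[, 1], B[, 2], B[, 3])
    for (r in seq_len(nrow(B))) {
      i <- B[r, 1]; j <- B[r, 2]; anti <- B[r, 3]
      jn <- if (anti == 1L) j - 1L else j + 1L
      if (paste(i + 1L, jn, anti) %in% bkey ||
          (anti == 1L && paste(jn, i + 1L, anti) %in% bkey)) {
        state[c(i, i + 1L, j, jn)] <- "E"
      }
    }
  }

  elementsFromState(state, res, minStrand, minHelix)
}

emptyElements <- function() {
  data.frame(kind = character(), chain = character(), start = integer(),
             end = integer(), label = character(), stringsAsFactors = FALSE)
}

## Contiguous same-chain runs of H/E, with minimum lengths.
elementsFromState <- function(state, res, minStrand, minHelix) {
  n <- length(state)
  out <- list()
  i <- 1L
  while (i <= n) {
    s <- state[i]
    if (s == "-") { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] == s && res$chain[j + 1L] == res$chain[i]) j <- j + 1L
    len <- j - i + 1L
    keep <- if (s == "E") len >= minStrand else len >= minHelix
    if (keep)
      out[[length(out) + 1L]] <- data.frame(
        kind = if (s == "E") "strand" else "helix",
        chain = res$chain[i], start = i, end = j, label = "",
        stringsAsFactors = FALSE)
    i <- j + 1L
  }
  el <- if (length(out)) do.call(rbind, out) else emptyElements()
  el <- el[order(el$chain, el$start), , drop = FALSE]
  rownames(el) <- NULL
  el
}

## Inverse of acceptAnnotation: per-chain H/E/- strings from an element table.
elementsToAnnotation <- function(elements, model) {
  res <- model@residues
  state <- rep("-", nrow(res))
  for (k in seq_len(nrow(elements)))
    state[elements$start[k]:elements$end[k]] <-
      if (elements$kind[k] == "strand") "E" else "H"
  vapply(split(state, res$chain), paste0, character(1), collapse = "")
}

#' Build elements from an external secondary-structure annotation
#'
#' Bypasses geometry: the injection point that lets Cα-only synthetic barrels
#' and third-party (e.g. DSSP-derived) annotations drive the topology stages.
#'
#' @param model a [StructureModel-class].
#' @param annotation a named character vector of per-chain strings over the
#'   alphabet `H`, `E`, `-` (names are chain ids), or a single unnamed string
#'   for single-chain models. Each string's length must equal the chain's
#'   residue count.
#' @param minStrand,minHelix minimum element lengths in residues.
#' @return element data.frame as for [assignSS()].
#' @export
acceptAnnotation <- function(model, annotation, minStrand = 3, minHelix = 4) {
  res <- model@residues
  chains <- unique(res$chain)
  if (is.null(names(annotation))) {
    if (length(annotation) == 1 && length(chains) == 1) {
      names(annotation) <- chains
    } else if (length(annotation) == length(chains)) {
      names(annotation) <- chains
    } else stop("annotation must be named by chain")
  }
  state <- rep("-", nrow(res))
  for (ch in names(annotation)) {
    idx <- which(res$chain == ch)
    ss <- strsplit(annotation[[ch]], "")[[1]]
    if (length(ss) != length(idx))
      stop("annotation length ", length(ss), " != residue count ",
           length(idx), " for chain ", ch)
    if (!all(ss %in% c("H", "E", "-", ".")))
      stop("annotation alphabet must be {H, E, -}")
    state[idx] <- ifelse(ss == ".", "-", ss)
  }
  elementsFromState(state, res, minStrand, minHelix)
}
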