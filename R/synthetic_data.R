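## Deterministic generator of idealized structures with full ground truth:
## backbone ladders and helices (for the hydrogen-bond module), Cα-level
## two-domain barrels with controllable packing, arrangement, circular
## permutation, pseudo-hemes, rigid transforms and coordinate noise.
##
## Barrels are Cα-level and ship with their ground-truth secondary-structure
## annotation (driving the pipeline through acceptAnnotation); building a
## fully hydrogen-bonded closed-barrel backbone would add geometric realism
## with no extra topological content. Full-backbone fixtures are the ladders
## and helices.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "SER", "THR", "TRP", "TYR",
         "VAL", "PRO")

## ---- ideal backbone construction (NeRF from internal coordinates) --------

## Build an n-residue backbone (N, CA, C, O) with constant phi/psi (degrees).
buildBackbone <- function(n, phi, psi, omega = 180) {
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- (180 - 111.2) * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                        1.329, 116.2, psi)
    CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                         1.458, 121.7, omega)
    C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                        1.525, 111.2, phi)
  }
  for (i in seq_len(n)) {
    nNext <- if (i < n) N[i + 1, ]
             else placeAtom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi)
    O[i, ] <- C[i, ] - 1.231 * unitv(unitv(nNext - C[i, ]) +
                                     unitv(CA[i, ] - C[i, ]))
  }
  list(N = N, CA = CA, C = C, O = O)
}

## Hydrogen-bond energy between donor backbone (N, H) and acceptor (C, O).
.hbEnergyRaw <- function(Nd, Hd, Ca, Oa) {
  HB_ENERGY_CONST * (1 / vdist(Oa, Nd) + 1 / vdist(Ca, Hd) -
                     1 / vdist(Oa, Hd) - 1 / vdist(Ca, Nd))
}

.amideH <- function(Ni, Cprev, CAi) Ni + unitv(-(unitv(Cprev - Ni) + unitv(CAi - Ni)))

## Atom table rows for one backbone chain.
.backboneAtoms <- function(bb, chain, resnoStart = 1L, names = NULL) {
  n <- nrow(bb$N)
  if (is.null(names)) names <- rep("ALA", n)
  rows <- lapply(seq_len(n), function(i) {
    data.frame(type = "ATOM",
               elety = c("N", "CA", "C", "O"),
               alt = "", resid = names[i], chain = chain,
               resno = resnoStart + i - 1L, insert = "",
               x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
               y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
               z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]),
               o = 1, b = 0, elesy = c("N", "C", "C", "O"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Analytic flat pleated strand in the xy-plane, running +x: the N-H and
## C=O of each residue point to the same side, alternating sides along the
## chain, which is what sheet registry requires.
.idealStrand <- function(n) {
  i <- seq_len(n)
  s <- ifelse(i %% 2 == 0, 1, -1)
  x <- 3.45 * i
  list(N = cbind(x - 1.06, 0.5 * s, 0),
       CA = cbind(x, -0.5 * s, 0),
       C = cbind(x + 1.06, 0.5 * s, 0),
       O = cbind(x + 1.06, 1.73 * s, 0))
}

#' Ideal two-strand beta ladder
#'
#' Two extended strands (full backbone, constant strand dihedrals) placed by
#' a deterministic grid search over the inter-strand offset that maximizes
#' the number of backbone hydrogen bonds under the package's own energy
#' criterion, i.e. textbook sheet geometry with inter-strand N···O around
#' 2.9 Å.
#'
#' @param n residues per strand (>= 4).
#' @param orientation "antiparallel" or "parallel".
#' @return list(model, truth); `truth` holds the per-chain annotation and
#'   expected orientation.
#' @export
makeLadder <- function(n, orientation = c("antiparallel", "parallel")) {
  orientation <- match.arg(orientation)
  stopifnot(n >= 4)
  s1 <- .idealStrand(n)
  base <- if (orientation == "antiparallel") {
    ## two-fold about the sheet normal reverses the chain direction in-plane
    lapply(s1, function(m) m %*% t(rotationAboutAxis(c(0, 0, 1), pi)))
  } else s1
  ## re-center over strand 1 so the offset search covers one strand period
  shift <- colMeans(s1$CA) - colMeans(base$CA)
  base <- lapply(base, function(m) sweep(m, 2, shift, "+"))

  H1 <- lapply(2:n, function(i) .amideH(s1$N[i, ], s1$C[i - 1, ], s1$CA[i, ]))
  score <- function(off) {
    s2 <- lapply(base, function(m) sweep(m, 2, off, "+"))
    H2 <- lapply(2:n, function(i) .amideH(s2$N[i, ], s2$C[i - 1, ], s2$CA[i, ]))
    cnt <- 0L
    for (i in 2:n) for (j in seq_len(n)) {
      if (.hbEnergyRaw(s1$N[i, ], H1[[i - 1]], s2$C[j, ], s2$O[j, ]) < -0.9) cnt <- cnt + 1L
      if (.hbEnergyRaw(s2$N[i, ], H2[[i - 1]], s1$C[j, ], s1$O[j, ]) < -0.9) cnt <- cnt + 1L
    }
    cnt
  }
  grid <- expand.grid(dx = seq(-3.6, 3.6, 0.15), dy = seq(4.0, 6.0, 0.1))
  best <- 0L; bestOff <- c(0, 4.9, 0)
  for (r in seq_len(nrow(grid))) {
    off <- c(grid$dx[r], grid$dy[r], 0)
    sc <- score(off)
    if (sc > best) { best <- sc; bestOff <- off }
  }
  s2 <- lapply(base, function(m) sweep(m, 2, bestOff, "+"))
  atoms <- rbind(.backboneAtoms(s1, "A"), .backboneAtoms(s2, "B"))
  model <- buildStructureModel(atoms, id = paste0("LADDER_", toupper(substr(orientation, 1, 4))))
  ann <- stats::setNames(rep(strrep("E", n), 2), c("A", "B"))
  list(model = model,
       truth = list(annotation = ann, orientation = orientation,
                    hbondCount = best))
}

#' Ideal alpha-helix
#'
#' Full-backbone helix at canonical helical dihedrals; interior residues
#' donate i -> i-4 hydrogen bonds.
#'
#' @param n number of residues (>= 6).
#' @return list(model, truth).
#' @export
makeHelix <- function(n) {
  stopifnot(n >= 6)
  bb <- buildBackbone(n, phi = -57, psi = -47)
  model <- buildStructureModel(.backboneAtoms(bb, "A"), id = "HELIX")
  list(model = model,
       truth = list(annotation = c(A = strrep("H", n))))
}

## ---- idealized barrels ----------------------------------------------------

## Element lengths of the ferredoxin-like domain template. The two beta-
## alpha-beta units are deliberately non-identical (realistic domains are
## only approximately internally symmetric), which keeps the direct and
## half-swap correspondences separable.
FDX_TEMPLATE <- list(
  b1 = list(kind = "strand", len = 6L),
  a1 = list(kind = "helix", len = 8L),
  b2 = list(kind = "strand", len = 6L),
  b3 = list(kind = "strand", len = 5L),
  a2 = list(kind = "helix", len = 6L),
  b4 = list(kind = "strand", len = 5L))

## Cα geometry of one ferredoxin-like domain, strands on a cylinder of the
## given radius at slots (azimuth k*45 deg): b2@0, b3@1, b1@2, b4@3 (the
## within-domain sheet order beta2-beta3-beta1-beta4), up at even slots;
## helices radially outside between their flanking strands.
.domainTemplate <- function(radius = 5.8, caRise = 3.3, helixRise = 1.5,
                            helixOffset = 5.0) {
  slotAz <- function(k) k * pi / 4
  strandXyz <- function(slot, len, up) {
    z <- (seq_len(len) - (len + 1) / 2) * caRise
    ## odd-length strands shift half a rise so all strands share one z-grid;
    ## nearest inter-strand contacts then sit at the sheet spacing itself
    if (len %% 2 == 1) z <- z + caRise / 2
    if (!up) z <- -z
    cbind(radius * cos(slotAz(slot)), radius * sin(slotAz(slot)), z)
  }
  helixXyz <- function(az, len, up) {
    z <- (seq_len(len) - (len + 1) / 2) * helixRise
    if (!up) z <- -z
    r2 <- radius + helixOffset
    cbind(r2 * cos(az), r2 * sin(az), z)
  }
  slots <- c(b2 = 0L, b3 = 1L, b1 = 2L, b4 = 3L)
  ups <- c(b2 = TRUE, b3 = FALSE, b1 = TRUE, b4 = FALSE)
  blocks <- list()
  for (lab in names(FDX_TEMPLATE)) {
    spec <- FDX_TEMPLATE[[lab]]
    xyz <- if (spec$kind == "strand") {
      strandXyz(slots[[lab]], spec$len, ups[[lab]])
    } else if (lab == "a1") {
      helixXyz(pi / 4, spec$len, up = FALSE)   # between b1 (90) and b2 (0)
    } else {
      helixXyz(pi / 2, spec$len, up = TRUE)    # between b3 (45) and b4 (135)
    }
    blocks[[lab]] <- list(label = lab, kind = spec$kind, xyz = xyz)
  }
  blocks
}

## Interpolated loop Cα positions between two anchor points (~3.5 Å spacing).
.loopPoints <- function(p, q, spacing = 3.5, minPoints = 1L) {
  d <- vdist(p, q)
  k <- max(minPoints, as.integer(round(d / spacing)) - 1L)
  if (k == 0L) return(matrix(numeric(0), 0, 3))
  t(vapply(seq_len(k), function(i) p + (q - p) * i / (k + 1), numeric(3)))
}

## Assemble labeled blocks into one chain: per-residue table with loops.
.assembleBlocks <- function(blocks, names) {
  res <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (bi > 1) {
      prev <- blocks[[bi - 1]]
      lp <- .loopPoints(prev$xyz[nrow(prev$xyz), ], b$xyz[1, ])
      if (nrow(lp))
        res[[length(res) + 1L]] <- data.frame(
          label = "", kind = "-", x = lp[, 1], y = lp[, 2], z = lp[, 3],
          stringsAsFactors = FALSE)
    }
    res[[length(res) + 1L]] <- data.frame(
      label = b$label, kind = b$kind,
      x = b$xyz[, 1], y = b$xyz[, 2], z = b$xyz[, 3],
      stringsAsFactors = FALSE)
  }
  chain <- do.call(rbind, res)
  rownames(chain) <- NULL
  ## residue names: elements keep the supplied per-block names, loops drawn
  ## from the same pool deterministically via the caller's RNG state
  chain$name <- NA_character_
  for (lab in names(names))
    chain$name[chain$label == lab] <- names[[lab]]
  nLoop <- sum(is.na(chain$name))
  chain$name[is.na(chain$name)] <- sample(AA3, nLoop, replace = TRUE)
  chain
}

## The rigid motion taking domain A onto domain B's position.
.domainBTransform <- function(packing) {
  if (packing == "Type-1") {
    rotationAboutAxis(c(0, 0, 1), pi)          # C2 about the barrel axis
  } else {
    ## 180 deg about the horizontal axis at azimuth 157.5 deg: flips the
    ## domain upside down, beta4 meets beta4 -- the Type-2 arrangement
    az <- 157.5 * pi / 180
    rotationAboutAxis(c(cos(az), sin(az), 0), pi)
  }
}

#' Idealized two-domain barrel with ground truth
#'
#' Eight Cα-level strands on a cylinder in the cyclic order dictated by the
#' packing type, alternating up/down, with flanking helices outside the
#' sheet and straight Cα loops; domain B is a rigid copy of domain A (C2
#' about the barrel axis for Type-1; flipped over a horizontal two-fold for
#' Type-2, which puts its termini on the opposite barrel end). Chains are
#' separate (homodimer) or fused in tandem. Optionally domain B's two
#' β-α-β units are swapped in chain order with coordinates unchanged (a
#' sequence-level circular permutation), a pseudo-heme is placed at one of
#' the three binding-site modes, Gaussian coordinate noise is added to the
#' polymer, and a seeded random rigid transform is applied.
#'
#' @param packing "Type-1" or "Type-2".
#' @param arrangement "homodimer" or "fused".
#' @param permuteDomainB swap domain B's units in sequence order.
#' @param noiseSigma Gaussian coordinate noise sd in Å (polymer atoms).
#' @param seed integer; fixes all randomness (residue names, noise,
#'   transform).
#' @param hemeMode "none", "cleft_alpha2", "cleft_alpha1" or "cavity_beta2".
#' @param rigidTransform NULL, TRUE (seeded random), or list(R, t).
#' @param radius barrel radius in Å. The default keeps adjacent vertical
#'   strands at sheet-like ~4.8 Å spacing.
#' @return list(model = [StructureModel-class], truth = list(annotation,
#'   elements, packing, arrangement, proximal, siteMode, ...)).
#' @export
makeBarrel <- function(packing = c("Type-1", "Type-2"),
                       arrangement = c("homodimer", "fused"),
                       permuteDomainB = FALSE, noiseSigma = 0, seed = 1,
                       hemeMode = c("none", "cleft_alpha2", "cleft_alpha1",
                                    "cavity_beta2"),
                       rigidTransform = NULL, radius = 5.8) {
  packing <- match.arg(packing)
  arrangement <- match.arg(arrangement)
  hemeMode <- match.arg(hemeMode)
  set.seed(seed)

  blocks <- .domainTemplate(radius = radius)
  elNames <- lapply(FDX_TEMPLATE, function(s) sample(AA3, s$len, replace = TRUE))
  chainA <- .assembleBlocks(blocks, elNames)

  orderB <- if (permuteDomainB)
    c("b3", "a2", "b4", "b1", "a1", "b2") else names(FDX_TEMPLATE)
  chainB <- .assembleBlocks(blocks[orderB], elNames[orderB])
  RB <- .domainBTransform(packing)
  chainB[, c("x", "y", "z")] <- as.matrix(chainB[, c("x", "y", "z")]) %*% t(RB)

  if (arrangement == "homodimer") {
    chainA$chain <- "A"; chainB$chain <- "B"
    chainB$resno <- seq_len(nrow(chainB))
    chainA$resno <- seq_len(nrow(chainA))
    allRes <- rbind(chainA, chainB)
  } else {
    linker <- .loopPoints(as.numeric(chainA[nrow(chainA), c("x", "y", "z")]),
                          as.numeric(chainB[1, c("x", "y", "z")]))
    linkDf <- if (nrow(linker)) data.frame(
      label = "", kind = "-", x = linker[, 1], y = linker[, 2], z = linker[, 3],
      name = sample(AA3, nrow(linker), replace = TRUE),
      stringsAsFactors = FALSE) else NULL
    allRes <- rbind(chainA, linkDf, chainB)
    allRes$chain <- "A"
    allRes$resno <- seq_len(nrow(allRes))
  }
  nA <- nrow(chainA)
  allRes$domain <- ""
  allRes$domain[seq_len(nA)][chainA$label != ""] <- "A"
  tailIdx <- (nrow(allRes) - nrow(chainB) + 1L):nrow(allRes)
  allRes$domain[tailIdx][chainB$label != ""] <- "B"

  atoms <- data.frame(type = "ATOM", elety = "CA", alt = "",
                      resid = allRes$name, chain = allRes$chain,
                      resno = allRes$resno, insert = "",
                      x = allRes$x, y = allRes$y, z = allRes$z,
                      o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)

  truth <- list(packing = packing, arrangement = arrangement,
                permuted = permuteDomainB, seed = seed,
                noiseSigma = noiseSigma, radius = radius)

  ## ground-truth element table (internal indices = row order)
  allRes$residx <- seq_len(nrow(allRes))
  el <- list()
  for (dn in c("A", "B")) for (lab in unique(allRes$label[allRes$label != ""])) {
    idx <- allRes$residx[allRes$label == lab & allRes$domain == dn]
    if (length(idx))
      el[[length(el) + 1L]] <- data.frame(
        domain = dn, label = lab,
        kind = FDX_TEMPLATE[[lab]]$kind, start = min(idx), end = max(idx),
        chain = allRes$chain[min(idx)], stringsAsFactors = FALSE)
  }
  truth$elements <- do.call(rbind, el)

  ## annotation per chain
  ssChar <- ifelse(allRes$kind == "strand", "E",
                   ifelse(allRes$kind == "helix", "H", "-"))
  truth$annotation <- vapply(split(ssChar, allRes$chain), paste0,
                             character(1), collapse = "")
  truth$proximal <- NULL
  truth$siteMode <- NULL

  hetAtoms <- NULL
  if (hemeMode != "none") {
    ph <- .placePseudoHeme(atoms, allRes, hemeMode, radius)
    atoms <- ph$atoms
    hetAtoms <- ph$het
    truth$proximal <- ph$proximal
    truth$siteMode <- ph$siteMode
  }

  polymer <- atoms$type == "ATOM"
  if (noiseSigma > 0) {
    atoms$x[polymer] <- atoms$x[polymer] + stats::rnorm(sum(polymer), 0, noiseSigma)
    atoms$y[polymer] <- atoms$y[polymer] + stats::rnorm(sum(polymer), 0, noiseSigma)
    atoms$z[polymer] <- atoms$z[polymer] + stats::rnorm(sum(polymer), 0, noiseSigma)
  }
  if (!is.null(hetAtoms)) atoms <- rbind(atoms, hetAtoms)

  if (isTRUE(rigidTransform)) {
    rigidTransform <- list(R = rotationFromEuler(stats::runif(1, 0, 2 * pi),
                                                 stats::runif(1, 0, pi),
                                                 stats::runif(1, 0, 2 * pi)),
                           t = stats::runif(3, -20, 20))
  }
  if (is.list(rigidTransform)) {
    xyz <- applyRigid(as.matrix(atoms[, c("x", "y", "z")]),
                      rigidTransform$R, rigidTransform$t)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    truth$rigid <- rigidTransform
  }

  model <- buildStructureModel(atoms, id = sprintf("SYN_%s_%s_%d",
    sub("-", "", packing), toupper(substr(arrangement, 1, 4)), seed))
  list(model = model, truth = truth)
}

## Place a planar Fe + N4 + C20 pseudo-porphyrin near a His-designated
## residue of domain A at the requested site; returns modified polymer atoms
## (target renamed HIS, NE2 added) and the HETATM block.
.placePseudoHeme <- function(atoms, allRes, site, radius) {
  lab <- switch(site, cleft_alpha2 = "a2", cleft_alpha1 = "a1",
                cavity_beta2 = "b2")
  idx <- allRes$residx[allRes$label == lab & allRes$domain == "A"]
  if (!length(idx)) stop("requested element absent: ", lab)
  target <- idx[ceiling(length(idx) / 2)]
  arow <- which(atoms$resno == allRes$resno[target] &
                atoms$chain == allRes$chain[target])[1]
  ca <- as.numeric(atoms[arow, c("x", "y", "z")])
  u <- if (site == "cavity_beta2") {
    unitv(c(-ca[1], -ca[2], 0))            # toward the barrel axis
  } else {
    unitv(c(ca[1], ca[2], 0))              # radially outward past the helix
  }
  atoms$resid[arow] <- "HIS"
  ne2 <- ca + 2.0 * u
  fe <- ca + 4.1 * u
  atoms <- rbind(atoms, data.frame(
    type = "ATOM", elety = "NE2", alt = "", resid = "HIS",
    chain = atoms$chain[arow], resno = atoms$resno[arow], insert = "",
    x = ne2[1], y = ne2[2], z = ne2[3], o = 1, b = 0, elesy = "N",
    stringsAsFactors = FALSE))
  ring <- makePorphyrin(fe, u)
  het <- data.frame(type = "HETATM", elety = ring$name, alt = "",
                    resid = "HEM", chain = atoms$chain[arow], resno = 901L,
                    insert = "", x = ring$xyz[, 1], y = ring$xyz[, 2],
                    z = ring$xyz[, 3], o = 1, b = 0, elesy = ring$elem,
                    stringsAsFactors = FALSE)
  list(atoms = atoms, het = het,
       proximal = list(chain = atoms$chain[arow],
                       resno = as.integer(atoms$resno[arow])),
       siteMode = switch(site, cleft_alpha2 = "SITE_CLEFT_ISDG_OXDA",
                         cleft_alpha1 = "SITE_CLD_DYP",
                         cavity_beta2 = "SITE_CAVITY"))
}

#' Idealized porphyrin ring coordinates
#'
#' Fe at the center, four pyrrole N at 2.05 Å, sixteen pyrrole C at 3.45 Å
#' and four meso C at 3.4 Å, in the plane normal to `normal`; `ruffle`
#' displaces the meso carbons alternately +/- that amount out of plane (the
#' classic ruffling distortion, with zero net moment so the least-squares
#' plane is unchanged).
#'
#' @param center Fe position.
#' @param normal plane normal (unit length not required).
#' @param ruffle meso-carbon out-of-plane displacement in Å.
#' @return list(name, elem, xyz) suitable for building HETATM records.
#' @export
makePorphyrin <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                          ruffle = 0) {
  nrm <- unitv(normal)
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(pracmaCross(nrm, ref))
  e2 <- pracmaCross(nrm, e1)
  at <- function(rd, angDeg, dz = 0) {
    a <- angDeg * pi / 180
    center + rd * cos(a) * e1 + rd * sin(a) * e2 + dz * nrm
  }
  names <- c("FE", "NA", "NB", "NC", "ND",
             as.vector(outer(paste0("C", 1:4), c("A", "B", "C", "D"), paste0)),
             "CHA", "CHB", "CHC", "CHD")
  xyz <- matrix(NA_real_, length(names), 3)
  xyz[1, ] <- center
  for (k in 0:3) xyz[2 + k, ] <- at(2.05, k * 90)
  ringAng <- as.vector(vapply(0:3, function(q)
    q * 90 + c(-30, -10, 10, 30), numeric(4)))
  for (k in seq_along(ringAng)) xyz[5 + k, ] <- at(3.45, ringAng[k])
  for (k in 0:3) xyz[22 + k, ] <- at(3.4, 45 + k * 90,
                                     dz = ruffle * (-1)^k)
  elem <- c("FE", rep("N", 4), rep("C", 20))
  list(name = names, elem = elem, xyz = xyz)
}

#' Add a pseudo-heme to a synthetic barrel
#'
#' Convenience wrapper that re-generates the barrel with the requested
#' heme mode (the placement needs the generator's clean, untransformed
#' frame).
#'
#' @param barrel a list from [makeBarrel()].
#' @param site "cleft_alpha2", "cleft_alpha1" or "cavity_beta2".
#' @return list(model, truth) with the ligand placed.
#' @export
makePseudoHeme <- function(barrel, site = c("cleft_alpha2", "cleft_alpha1",
                                            "cavity_beta2")) {
  site <- match.arg(site)
  tr <- barrel$truth
  makeBarrel(packing = tr$packing, arrangement = tr$arrangement,
             permuteDomainB = tr$permuted, noiseSigma = tr$noiseSigma,
             seed = tr$seed, hemeMode = site,
             rigidTransform = tr$rigid, radius = tr$radius)
}

#' Synthetic domain pair with a known mapping kind
#'
#' Constructs two single-domain models related by one of the four
#' correspondence kinds: `direct` (a rigid copy), `permuted` (the chain
#' rethreaded so the second β-α-β unit comes first, coordinates unchanged),
#' `rotated` (rethreaded and the sequence re-randomized: a different
#' protein related through the fold's internal two-fold) and
#' `rotated+permuted` (copy in original order with re-randomized sequence).
#'
#' @param kind mapping kind to construct.
#' @param seed integer seed.
#' @param noiseSigma coordinate noise added to domain B (Å).
#' @return list(A, B, kind) where each side has `model`, `domain`
#'   ([FerredoxinDomain-class]) and `elements`.
#' @export
makeDomainPair <- function(kind = c("direct", "rotated", "permuted",
                                    "rotated+permuted"),
                           seed = 1, noiseSigma = 0) {
  kind <- match.arg(kind)
  set.seed(seed)
  blocks <- .domainTemplate()
  elNames <- lapply(FDX_TEMPLATE, function(s) sample(AA3, s$len, replace = TRUE))
  chainA <- .assembleBlocks(blocks, elNames)

  rethread <- kind %in% c("permuted", "rotated")
  resequence <- kind %in% c("rotated", "rotated+permuted")
  orderB <- if (rethread) c("b3", "a2", "b4", "b1", "a1", "b2")
            else names(FDX_TEMPLATE)
  namesB <- if (resequence)
    lapply(FDX_TEMPLATE, function(s) sample(AA3, s$len, replace = TRUE))
  else elNames
  chainB <- .assembleBlocks(blocks[orderB], namesB[orderB])
  if (noiseSigma > 0) {
    nB <- nrow(chainB)
    chainB$x <- chainB$x + stats::rnorm(nB, 0, noiseSigma)
    chainB$y <- chainB$y + stats::rnorm(nB, 0, noiseSigma)
    chainB$z <- chainB$z + stats::rnorm(nB, 0, noiseSigma)
  }
  ## random rigid placement of B
  R <- rotationFromEuler(stats::runif(1, 0, 2 * pi), stats::runif(1, 0, pi),
                         stats::runif(1, 0, 2 * pi))
  t <- stats::runif(3, -15, 15)
  chainB[, c("x", "y", "z")] <- applyRigid(as.matrix(chainB[, c("x", "y", "z")]), R, t)

  side <- function(chain, id) {
    chain$chain <- "A"
    chain$resno <- seq_len(nrow(chain))
    atoms <- data.frame(type = "ATOM", elety = "CA", alt = "",
                        resid = chain$name, chain = "A", resno = chain$resno,
                        insert = "", x = chain$x, y = chain$y, z = chain$z,
                        o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
    model <- buildStructureModel(atoms, id = id)
    ann <- c(A = paste0(ifelse(chain$kind == "strand", "E",
                        ifelse(chain$kind == "helix", "H", "-")),
                        collapse = ""))
    elements <- acceptAnnotation(model, ann)
    strands <- which(elements$kind == "strand")
    domain <- domainFromStrands(elements, strands, "A")
    list(model = model, domain = domain, elements = elements)
  }
  list(A = side(chainA, "DOM_A"), B = side(chainB, "DOM_B"), kind = kind)
}
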