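## Rigid superposition of ferredoxin-like domains under hypothesis-driven
## element correspondences (direct, 180-degree rotated half-swap, circular
## permutation, and their composition).

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation minimizing the RMSD between
#' paired coordinate sets, with the usual determinant correction excluding
#' reflections.
#'
#' @param a,b n x 3 coordinate matrices with matched rows (n >= 3).
#' @return list with `rotation` (3x3), `translation` (length 3) and `rmsd`,
#'   such that `b ~ a %*% t(rotation) + translation`.
#' @export
kabschFit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  if (nrow(a) < 3) stop("need at least three points")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  fitted <- sweep(A %*% t(R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

HALF_SWAP_MAP <- c(b1 = "b3", a1 = "a2", b2 = "b4",
                   b3 = "b1", a2 = "a1", b4 = "b2")
IDENTITY_MAP <- c(b1 = "b1", a1 = "a1", b2 = "b2",
                  b3 = "b3", a2 = "a2", b4 = "b4")

#' Enumerate candidate element correspondences between two domains
#'
#' Four hypothesis maps: `direct` (β1→β1, ...), `rotated` (the half-swap
#' β1→β3, α1→α2, β2→β4, ... exploiting the fold's internal two-fold
#' symmetry), `permuted` (one β-α-β unit cyclically shifted in sequence) and
#' `rotated+permuted` (their composition). As label bijections the permuted
#' map coincides with the half-swap and the composition with the identity;
#' the kinds are told apart after fitting by sequence evidence (see
#' [alignDomains()]). Labels missing from either domain are dropped from the
#' map.
#'
#' @param domA,domB [FerredoxinDomain-class] objects.
#' @return named list of candidate maps (named character vectors
#'   label(A) -> label(B)).
#' @export
enumerateMappings <- function(domA, domB) {
  availA <- names(domA@elementIdx)[!is.na(domA@elementIdx)]
  availB <- names(domB@elementIdx)[!is.na(domB@elementIdx)]
  strip <- function(m) m[names(m) %in% availA & m %in% availB]
  list(direct = strip(IDENTITY_MAP),
       rotated = strip(HALF_SWAP_MAP),
       permuted = strip(HALF_SWAP_MAP),
       `rotated+permuted` = strip(IDENTITY_MAP))
}

## Longest strictly-increasing subsequence (indices), O(n^2); pair sets per
## element are small.
.lis <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  best <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1))
    if (x[j] < x[i] && best[j] + 1L > best[i]) { best[i] <- best[j] + 1L; prev[i] <- j }
  k <- which.max(best)
  out <- integer(best[k])
  for (p in rev(seq_len(best[k]))) { out[p] <- k; k <- prev[k] }
  out
}

## Evaluate one element map: center-anchored seeding, Kabsch fit, iterative
## re-pairing by mutually nearest CA within pairDist (sequence order kept
## within each element), scored by pairs within scoreDist.
.evaluateMapping <- function(map, domA, domB, modelA, modelB,
                             pairDist = 4.5, scoreDist = 4.0, maxIter = 10) {
  elPairs <- lapply(names(map), function(la) {
    ia <- domA@elementResidues[[la]]
    ib <- domB@elementResidues[[map[[la]]]]
    list(ia = ia, ib = ib)
  })
  pairs <- do.call(rbind, lapply(elPairs, function(p)
    centerAnchoredPairs(p$ia, p$ib)))
  if (is.null(pairs) || nrow(pairs) < 3) return(NULL)
  xyzA <- caCoords(modelA, unlist(lapply(elPairs, `[[`, "ia")))
  rownames(xyzA) <- unlist(lapply(elPairs, `[[`, "ia"))
  xyzB <- caCoords(modelB, unlist(lapply(elPairs, `[[`, "ib")))
  rownames(xyzB) <- unlist(lapply(elPairs, `[[`, "ib"))
  getA <- function(i) xyzA[as.character(i), , drop = FALSE]
  getB <- function(i) xyzB[as.character(i), , drop = FALSE]

  fit <- kabschFit(getA(pairs[, 1]), getB(pairs[, 2]))
  for (iter in seq_len(maxIter)) {
    newPairs <- list()
    for (p in elPairs) {
      A <- applyRigid(getA(p$ia), fit$rotation, fit$translation)
      B <- getB(p$ib)
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      d2[d2 < 0] <- 0
      nb <- apply(d2, 1, which.min)   # nearest B for each A
      na <- apply(d2, 2, which.min)   # nearest A for each B
      keep <- which(na[nb] == seq_along(p$ia) &
                    sqrt(d2[cbind(seq_along(p$ia), nb)]) <= pairDist)
      if (!length(keep)) next
      cand <- cbind(p$ia[keep], p$ib[nb[keep]])
      cand <- cand[order(cand[, 1]), , drop = FALSE]
      cand <- cand[.lis(cand[, 2]), , drop = FALSE]
      newPairs[[length(newPairs) + 1L]] <- cand
    }
    newPairs <- do.call(rbind, newPairs)
    if (is.null(newPairs) || nrow(newPairs) < 3) break
    if (nrow(newPairs) == nrow(pairs) && all(newPairs == pairs)) {
      pairs <- newPairs; break
    }
    pairs <- newPairs
    fit <- kabschFit(getA(pairs[, 1]), getB(pairs[, 2]))
  }
  fit <- kabschFit(getA(pairs[, 1]), getB(pairs[, 2]))
  A <- applyRigid(getA(pairs[, 1]), fit$rotation, fit$translation)
  dists <- sqrt(rowSums((A - getB(pairs[, 2]))^2))
  list(pairs = pairs, fit = fit, rmsd = fit$rmsd,
       score = sum(dists <= scoreDist), n = nrow(pairs))
}

#' Superpose two ferredoxin-like domains under all candidate mappings
#'
#' Each candidate map is seeded by center-anchored pairing of mapped
#' elements, fitted with [kabschFit()], and refined by re-pairing mutually
#' nearest Cα within `pairDist` (sequence order preserved within each
#' element, not across elements, which is what permits the permutation
#' case) until the pair set is stable. The best candidate has the most
#' pairs within `scoreDist` after the fit, ties broken by lower RMSD.
#'
#' Because a circular permutant of an internally symmetric domain is
#' rigid-geometrically indistinguishable from a 180°-rotated relative, the
#' half-swap and identity maps each cover two kinds; within the winning
#' spatial class the kind is called `permuted` (or `direct`) when sequence
#' identity over the aligned pairs reaches `seqIdThreshold` — claiming a
#' sequence-level event requires sequence evidence — and `rotated` (or
#' `rotated+permuted`) otherwise.
#'
#' @param domA,domB labeled [FerredoxinDomain-class] objects.
#' @param modelA,modelB their parent [StructureModel-class] objects
#'   (`modelB` defaults to `modelA`).
#' @param mappings optional character subset of kinds to try.
#' @param pairDist re-pairing distance (Å).
#' @param scoreDist scoring distance (Å).
#' @param seqIdThreshold sequence-identity threshold separating
#'   sequence-level kinds from purely spatial ones.
#' @param maxIter refinement iteration cap.
#' @return list with `best` (a [DomainCorrespondence-class]) and
#'   `candidates` (all four, same order as [enumerateMappings()]).
#' @export
alignDomains <- function(domA, domB, modelA, modelB = modelA,
                         mappings = NULL, pairDist = 4.5, scoreDist = 4.0,
                         seqIdThreshold = 0.4, maxIter = 10) {
  maps <- enumerateMappings(domA, domB)
  if (!is.null(mappings)) maps <- maps[names(maps) %in% mappings]
  if (!length(maps)) stop("no candidate mappings requested")

  ## identical bijections share one numeric evaluation
  cache <- list()
  evals <- lapply(maps, function(m) {
    keyv <- paste(names(m), m, collapse = ";")
    if (is.null(cache[[keyv]]))
      cache[[keyv]] <<- .evaluateMapping(m, domA, domB, modelA, modelB,
                                         pairDist, scoreDist, maxIter)
    cache[[keyv]]
  })
  if (all(vapply(evals, is.null, logical(1))))
    stop("alignment error: fewer than three seed pairs for every mapping")

  toCorr <- function(kind, map, ev) {
    seqId <- mean(seqOneLetter(modelA, ev$pairs[, 1]) ==
                  seqOneLetter(modelB, ev$pairs[, 2]))
    new("DomainCorrespondence", kind = kind, elementMap = map,
        pairs = ev$pairs, rotation = ev$fit$rotation,
        translation = ev$fit$translation, rmsd = ev$rmsd,
        nPairs = as.integer(ev$n), score = as.integer(ev$score),
        seqIdentity = seqId)
  }
  candidates <- list()
  for (k in names(maps))
    if (!is.null(evals[[k]]))
      candidates[[k]] <- toCorr(k, maps[[k]], evals[[k]])

  ## winner: spatial class by (score, -rmsd); kind within class by sequence
  isHalfSwap <- vapply(candidates, function(co)
    !all(names(co@elementMap) == co@elementMap), logical(1))
  classRep <- candidates[!duplicated(isHalfSwap)]
  classHalf <- isHalfSwap[!duplicated(isHalfSwap)]
  scores <- vapply(classRep, function(co) co@score, numeric(1))
  rmsds <- vapply(classRep, function(co) co@rmsd, numeric(1))
  bestClass <- order(-scores, rmsds)[1]
  best <- classRep[[bestClass]]
  seqKind <- best@seqIdentity >= seqIdThreshold
  best@kind <- if (classHalf[bestClass]) {
    if (seqKind) "permuted" else "rotated"
  } else {
    if (seqKind) "direct" else "rotated+permuted"
  }
  list(best = best, candidates = candidates)
}
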