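## Strand-pairing graph and cyclic strand order of the barrel.

#' Pair strands by inter-strand hydrogen bonding (or Cα contacts)
#'
#' In hydrogen-bond mode, backbone H-bonds between residues of two strand
#' elements are counted and pairs with at least `minBonds` bonds kept. In
#' contact mode (Cα-only models driven by an external annotation) Cα-Cα
#' contacts closer than `contactDist` substitute for bonds with threshold
#' `minContacts`; the thresholds reproduce hydrogen-bond-mode pairing on
#' idealized sheets. Orientation comes from the sign of the dot product of
#' the two strands' N-to-C direction vectors (least-squares lines through
#' their Cα).
#'
#' @param elements element data.frame (from [assignSS()] or
#'   [acceptAnnotation()]).
#' @param hbonds data.frame from [detectHBonds()]; may be NULL in contact
#'   mode.
#' @param model the [StructureModel-class].
#' @param mode "auto" uses H-bonds when available, else contacts.
#' @param minBonds minimum inter-strand H-bond count.
#' @param contactDist,minContacts contact-mode thresholds (Å, count).
#' @return data.frame of strand pairs: `a`, `b` (element row indices),
#'   `n` (bond/contact count), `orientation`.
#' @export
pairStrands <- function(elements, hbonds = NULL, model,
                        mode = c("auto", "hbond", "contact"),
                        minBonds = 2, contactDist = 5.5, minContacts = 3) {
  mode <- match.arg(mode)
  strands <- which(elements$kind == "strand")
  if (length(strands) < 2) stop("need at least two strand elements")
  if (mode == "auto")
    mode <- if (!is.null(hbonds) && nrow(hbonds)) "hbond" else "contact"

  memb <- rep(NA_integer_, nrow(model@residues))
  for (s in strands) memb[elements$start[s]:elements$end[s]] <- s

  counts <- matrix(0L, nrow(elements), nrow(elements))
  if (mode == "hbond") {
    d <- memb[hbonds$donor]; a <- memb[hbonds$acceptor]
    ok <- !is.na(d) & !is.na(a) & d != a
    for (k in which(ok)) {
      i <- min(d[k], a[k]); j <- max(d[k], a[k])
      counts[i, j] <- counts[i, j] + 1L
    }
    thr <- minBonds
  } else {
    for (ii in seq_along(strands)) {
      for (jj in seq_along(strands)) {
        if (jj <= ii) next
        s1 <- strands[ii]; s2 <- strands[jj]
        c1 <- caCoords(model, elements$start[s1]:elements$end[s1])
        c2 <- caCoords(model, elements$start[s2]:elements$end[s2])
        dmat <- outer(rowSums(c1^2), rowSums(c2^2), "+") - 2 * c1 %*% t(c2)
        counts[s1, s2] <- sum(dmat < contactDist^2)
      }
    }
    thr <- minContacts
  }

  out <- list()
  idx <- which(counts >= thr, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    s1 <- idx[r, 1]; s2 <- idx[r, 2]
    d1 <- fitDirection(caCoords(model, elements$start[s1]:elements$end[s1]))
    d2 <- fitDirection(caCoords(model, elements$start[s2]:elements$end[s2]))
    out[[length(out) + 1L]] <- data.frame(
      a = s1, b = s2, n = counts[s1, s2],
      orientation = if (sum(d1 * d2) < 0) "antiparallel" else "parallel",
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(a = integer(), b = integer(), n = integer(),
               orientation = character())
  rownames(pairs) <- NULL
  pairs
}

#' Extract the barrel's strand cycle, axis and center
#'
#' The largest cycle of the strand-pairing graph is taken as the barrel
#' core. The sheet is `closed` when that cycle has exactly eight strands.
#' The axis is chosen among the principal directions of the centered strand
#' midpoints as the one best aligned with the strand direction vectors
#' (the smallest-spread direction of the midpoints is the in-plane normal
#' of the midpoint circle and is explicitly not wanted); its sign is fixed
#' so the first chain's N-terminus projects negatively. An open sheet is a
#' diagnosis, not an error.
#'
#' @param pairs data.frame from [pairStrands()].
#' @param elements element data.frame.
#' @param model the [StructureModel-class].
#' @return a [BarrelSheet-class].
#' @export
buildBarrelSheet <- function(pairs, elements, model) {
  if (!nrow(pairs)) {
    return(new("BarrelSheet", strands = integer(), orientations = character(),
               axis = c(0, 0, 1), center = c(0, 0, 0), closed = FALSE,
               elements = elements, radial = NA_real_,
               diagnostics = "no strand pairs"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs$a), to = as.character(pairs$b)),
    directed = FALSE)
  ## peel leaves until only cycles remain
  repeat {
    deg <- igraph::degree(g)
    if (!length(deg) || all(deg >= 2)) break
    g <- igraph::delete_vertices(g, names(deg)[deg < 2])
  }
  cycleIds <- integer()
  if (igraph::vcount(g) > 0) {
    comp <- igraph::components(g)
    best <- NULL
    for (ci in seq_len(comp$no)) {
      vs <- names(comp$membership)[comp$membership == ci]
      sub <- igraph::induced_subgraph(g, vs)
      if (all(igraph::degree(sub) == 2) &&
          igraph::ecount(sub) == igraph::vcount(sub)) {
        if (is.null(best) || length(vs) > length(best)) best <- vs
      }
    }
    if (!is.null(best)) {
      ## walk the cycle
      sub <- igraph::induced_subgraph(g, best)
      vnames <- igraph::V(sub)$name
      adj <- lapply(igraph::adjacent_vertices(sub, vnames),
                    function(v) v$name)
      names(adj) <- vnames
      walk <- vnames[1]
      prev <- NA_character_
      while (length(walk) < length(vnames)) {
        nxt <- setdiff(adj[[walk[length(walk)]]], c(prev, walk[length(walk)]))
        prev <- walk[length(walk)]
        walk <- c(walk, nxt[1])
      }
      cycleIds <- as.integer(walk)
    }
  }
  closed <- length(cycleIds) == 8
  diag <- if (closed) "closed 8-cycle"
          else sprintf("no closed 8-cycle (largest cycle: %d strands)",
                       length(cycleIds))
  core <- if (length(cycleIds)) cycleIds else unique(c(pairs$a, pairs$b))

  mids <- t(vapply(core, function(s)
    colMeans(caCoords(model, elements$start[s]:elements$end[s])), numeric(3)))
  dirs <- t(vapply(core, function(s)
    fitDirection(caCoords(model, elements$start[s]:elements$end[s])), numeric(3)))
  center <- colMeans(mids)
  sv <- svd(sweep(mids, 2, center), nu = 0, nv = 3)
  align <- vapply(1:3, function(k) mean(abs(dirs %*% sv$v[, k])), numeric(1))
  axis <- sv$v[, which.max(align)]
  ## sign convention: first chain's N-terminus projects negatively
  firstChain <- model@residues$chain[1]
  nterm <- caCoords(model, min(model@residues$residx[
    model@residues$chain == firstChain]))
  if (sum((as.numeric(nterm) - center) * axis) > 0) axis <- -axis
  radial <- mean(sqrt(rowSums((sweep(mids, 2, center) -
    (sweep(mids, 2, center) %*% axis) %*% t(axis))^2)))

  orient <- character(length(cycleIds))
  if (length(cycleIds)) {
    pkey <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
    for (k in seq_along(cycleIds)) {
      s1 <- cycleIds[k]; s2 <- cycleIds[if (k == length(cycleIds)) 1 else k + 1]
      m <- match(paste(min(s1, s2), max(s1, s2)), pkey)
      orient[k] <- pairs$orientation[m]
    }
  }
  new("BarrelSheet", strands = cycleIds, orientations = orient,
      axis = as.numeric(axis), center = as.numeric(center), closed = closed,
      elements = elements, radial = radial, diagnostics = diag)
}

## Axial coordinate of a point relative to a sheet.
axialCoord <- function(sheet, p) sum((p - sheet@center) * sheet@axis)

## Radial distance of a point from the sheet axis.
radialDist <- function(sheet, p) {
  v <- p - sheet@center
  vnorm(v - sum(v * sheet@axis) * sheet@axis)
}
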