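## Type-1 / Type-2 packing classification.
##
## The two packing modes are defined by which strands cross the domain
## boundary in the barrel's 8-cycle: beta2--beta4 / beta4--beta2 (Type-1,
## IsdG-like) versus beta2--beta2 / beta4--beta4 (Type-2, OxdA-like).
## Termini orientation (both domains' termini on one barrel end for Type-1,
## opposite ends for Type-2) is reported as corroborating evidence but never
## vetoes the strand-pairing signal.

#' Classify barrel packing as Type-1 or Type-2
#'
#' Reads the two strand pairs crossing the domain boundary off the 8-cycle
#' and matches them against the two canonical patterns. The cyclic strand
#' order is emitted in arrow notation starting at domain A's β2 and
#' proceeding toward its β3; the first strand is drawn ↑ and arrows flip at
#' each antiparallel adjacency. When the inter-domain pairs match neither
#' pattern the call is "unclassified" with diagnostics - never a silent
#' guess.
#'
#' @param barrel a [BarrelModel-class] from [mapDomains()].
#' @param model the [StructureModel-class] (for termini projections).
#' @return a [PackingCall-class].
#' @export
classifyPacking <- function(barrel, model) {
  sheet <- barrel@sheet
  el <- barrel@elements
  emptyPairs <- data.frame(labelA = character(), labelB = character(),
                           domainA = character(), domainB = character())
  if (!sheet@closed)
    return(new("PackingCall", packing = "unclassified",
               interDomainPairs = emptyPairs, orderString = "",
               terminiConsistent = NA, diagnostics = sheet@diagnostics))
  cyc <- sheet@strands
  dom <- el$domain[cyc]
  lab <- el$label[cyc]
  if (any(dom == "") || any(lab == ""))
    return(new("PackingCall", packing = "unclassified",
               interDomainPairs = emptyPairs, orderString = "",
               terminiConsistent = NA,
               diagnostics = "cycle contains unlabeled strands"))

  nxt <- c(2:8, 1)
  boundary <- which(dom != dom[nxt])
  pairsDf <- data.frame(labelA = lab[boundary], labelB = lab[nxt[boundary]],
                        domainA = dom[boundary], domainB = dom[nxt[boundary]],
                        stringsAsFactors = FALSE)
  packing <- "unclassified"
  diagnostics <- ""
  if (length(boundary) != 2) {
    diagnostics <- sprintf(
      "expected 2 inter-domain strand pairs in the 8-cycle, found %d (domains not contiguous)",
      length(boundary))
  } else {
    key <- apply(pairsDf[, c("labelA", "labelB")], 1,
                 function(r) paste(sort(r), collapse = "-"))
    if (all(sort(key) == c("b2-b4", "b2-b4"))) packing <- "Type-1"
    else if (all(sort(key) == c("b2-b2", "b4-b4"))) packing <- "Type-2"
    else diagnostics <- paste("inter-domain pairs match neither pattern:",
                              paste(key, collapse = "; "))
  }

  ## strand-order string in arrow notation, anchored at domain A beta2
  orientOf <- local({
    m <- new.env()
    for (k in seq_along(cyc)) {
      s1 <- cyc[k]; s2 <- cyc[nxt[k]]
      assign(paste(min(s1, s2), max(s1, s2)), sheet@orientations[k], envir = m)
    }
    function(s1, s2) get(paste(min(s1, s2), max(s1, s2)), envir = m)
  })
  start <- which(dom == "A" & lab == "b2")
  orderString <- ""
  if (length(start) == 1) {
    ## walk toward domain A's beta3
    left <- if (start == 1) 8 else start - 1
    right <- nxt[start]
    step <- if (dom[right] == "A" && lab[right] == "b3") 1L
            else if (dom[left] == "A" && lab[left] == "b3") -1L else 1L
    ord <- ((start - 1 + step * (0:7)) %% 8) + 1
    arrows <- character(8); arrows[1] <- "↑"
    for (k in 2:8) {
      o <- orientOf(cyc[ord[k - 1]], cyc[ord[k]])
      arrows[k] <- if (o == "antiparallel") {
        if (arrows[k - 1] == "↑") "↓" else "↑"
      } else arrows[k - 1]
    }
    orderString <- paste0(prettyLabel(lab[ord]), arrows, collapse = " ")
  }

  ## advisory termini check
  tA <- sign(terminiSide(barrel@domainA, sheet, model))
  tB <- sign(terminiSide(barrel@domainB, sheet, model))
  terminiConsistent <- switch(packing,
    "Type-1" = length(unique(c(tA, tB))) == 1,
    "Type-2" = tA[1] == tA[2] && tB[1] == tB[2] && tA[1] != tB[1],
    NA)
  new("PackingCall", packing = packing, interDomainPairs = pairsDf,
      orderString = orderString, terminiConsistent = terminiConsistent,
      diagnostics = diagnostics)
}
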