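## Pipeline drivers and machine-readable reporting.

#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline with their defaults; every report
#' embeds the effective configuration.
#'
#' @return named list of parameters.
#' @export
defaultConfig <- function() {
  list(hemeCodes = DEFAULT_HEME_CODES,
       hbondCutoff = -0.5, minStrand = 3, minHelix = 4,
       minBonds = 2, contactDist = 5.5, minContacts = 3,
       identityThreshold = 0.95,
       pairDist = 4.5, scoreDist = 4.0, seqIdThreshold = 0.4,
       axialCutoff = 3.5, distalCutoff = 6.0,
       cavityMargin = 0.75, ruffleThreshold = 0.25,
       hemeAssocDist = 15)
}

.mergeConfig <- function(config) {
  cfg <- defaultConfig()
  for (k in names(config)) cfg[[k]] <- config[[k]]
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

## residue author id string for reports
.authorId <- function(model, residx) {
  r <- model@residues[match(residx, model@residues$residx), ]
  paste0(r$chain, r$resno, ifelse(nzchar(r$insert), r$insert, ""))
}

.domainReport <- function(domain, model) {
  labs <- names(domain@elementIdx)[!is.na(domain@elementIdx)]
  ranges <- lapply(labs, function(lab) {
    idx <- domain@elementResidues[[lab]]
    paste0(.authorId(model, idx[1]), "-", .authorId(model, idx[length(idx)]))
  })
  list(chain = domain@chain,
       fused = domain@fused, half = domain@half, relaxed = domain@relaxed,
       elements = stats::setNames(ranges, prettyLabel(labs)))
}

.hemeReport <- function(site, model) {
  resRec <- function(r) if (!length(r)) NULL else
    list(chain = r$chain, resno = r$resno, resid = r$resid,
         atom = r$atom, dist = round(r$dist, 2))
  list(hetCode = site@ligand@hetCode,
       ligandId = paste0(site@ligand@chain, site@ligand@resno),
       proximal = resRec(site@proximal), distal = resRec(site@distal),
       hostDomain = site@hostDomain, hostBarrel = site@hostBarrel,
       mode = site@mode,
       feRadial = if (is.na(site@feRadial)) NULL else round(site@feRadial, 2),
       rufflingRMS = if (is.na(site@rufflingRMS)) NULL
                     else round(site@rufflingRMS, 3),
       ruffled = site@ruffled,
       diagnostics = site@diagnostics)
}

.corrReport <- function(co) {
  list(kind = co@kind, rmsd = round(co@rmsd, 3), nPairs = co@nPairs,
       score = co@score, seqIdentity = round(co@seqIdentity, 3))
}

#' Run the full barrel classification pipeline
#'
#' Loads (or accepts) a structure, assigns secondary structure from backbone
#' hydrogen bonds (or an external annotation), builds the strand-pairing
#' graph and barrel sheet, maps and labels the two ferredoxin-like domains,
#' classifies Type-1/Type-2 packing, superposes the two domains, and
#' analyzes every heme-like ligand. Biologically ambiguous outcomes
#' ("unclassified", "undetermined") are reported, never raised as errors.
#'
#' @param path structure file (PDB/mmCIF); alternatively pass `model`.
#' @param model a [StructureModel-class] (overrides `path`).
#' @param chains optional chain selection (the two chains forming one
#'   barrel for multi-barrel crystal forms).
#' @param annotation optional per-chain secondary-structure strings (see
#'   [acceptAnnotation()]); required for Cα-only models.
#' @param config list of threshold overrides (see [defaultConfig()]).
#' @param json optional path for the JSON report.
#' @param verbose print a human-readable summary.
#' @return the report as a nested list (invisibly when `verbose`).
#' @export
runClassify <- function(path = NULL, model = NULL, chains = NULL,
                        annotation = NULL, config = list(), json = NULL,
                        verbose = FALSE) {
  cfg <- .mergeConfig(config)
  warnings <- character(0)
  if (is.null(model)) {
    if (is.null(path)) stop("provide 'path' or 'model'")
    model <- .stage("structure_io",
      loadStructure(path, chains = chains, hemeCodes = cfg$hemeCodes))
  } else if (!is.null(chains)) {
    keep <- model@atoms$chain %in% chains
    model <- buildStructureModel(model@atoms[keep, , drop = FALSE],
                                 id = model@id, hemeCodes = cfg$hemeCodes)
  }

  hbonds <- NULL
  elements <- .stage("secondary_structure", {
    if (!is.null(annotation)) acceptAnnotation(model, annotation,
                                               cfg$minStrand, cfg$minHelix)
    else {
      hbonds <- detectHBonds(model, cutoff = cfg$hbondCutoff)
      assignSS(model, hbonds, cfg$minStrand, cfg$minHelix)
    }
  })

  report <- list(schema = "fdxbarrel-report/1",
                 id = model@id,
                 chains = unique(model@residues$chain),
                 nResidues = nrow(model@residues),
                 config = cfg)

  pairs <- .stage("sheet_topology",
    pairStrands(elements, hbonds, model, minBonds = cfg$minBonds,
                contactDist = cfg$contactDist, minContacts = cfg$minContacts))
  sheet <- .stage("sheet_topology", buildBarrelSheet(pairs, elements, model))

  if (!sheet@closed) {
    report$packing <- list(packing = "unclassified",
                           diagnostics = sheet@diagnostics)
    report$warnings <- c(warnings, sheet@diagnostics)
    if (!is.null(json)) writeReport(report, json)
    if (verbose) .printReport(report)
    return(invisible(report))
  }

  barrel <- .stage("ferredoxin_map",
    mapDomains(elements, sheet, model,
               identityThreshold = cfg$identityThreshold))
  call <- .stage("barrel_classify", classifyPacking(barrel, model))

  report$arrangement <- barrel@arrangement
  report$identity <- if (length(barrel@identity)) round(barrel@identity, 3) else NULL
  report$packing <- list(
    packing = call@packing, orderString = call@orderString,
    interDomainPairs = apply(call@interDomainPairs, 1, function(r)
      sprintf("%s(%s)--%s(%s)", prettyLabel(r[["labelA"]]), r[["domainA"]],
              prettyLabel(r[["labelB"]]), r[["domainB"]])),
    terminiConsistent = call@terminiConsistent,
    diagnostics = call@diagnostics)
  report$domains <- list(A = .domainReport(barrel@domainA, model),
                         B = .domainReport(barrel@domainB, model))

  corr <- tryCatch(
    alignDomains(barrel@domainA, barrel@domainB, model,
                 pairDist = cfg$pairDist, scoreDist = cfg$scoreDist,
                 seqIdThreshold = cfg$seqIdThreshold),
    error = function(e) { warnings <<- c(warnings, conditionMessage(e)); NULL })
  if (!is.null(corr))
    report$correspondence <- list(
      best = .corrReport(corr$best),
      candidates = lapply(corr$candidates, .corrReport))

  sites <- .stage("heme_analysis",
    analyzeHemeSites(barrel, model, cfg$axialCutoff, cfg$distalCutoff,
                     cfg$cavityMargin, cfg$ruffleThreshold))
  report$hemeCount <- countHemes(model, unique(model@residues$chain),
                                 cfg$hemeAssocDist)
  report$hemes <- lapply(sites, .hemeReport, model = model)
  report$warnings <- warnings

  if (!is.null(json)) writeReport(report, json)
  if (verbose) .printReport(report)
  invisible(report)
}

#' Extract one labeled ferredoxin-like domain from a structure
#'
#' Runs the pipeline far enough to label domains and returns the requested
#' one. For a closed barrel, `which` selects the sequence-first ("N"/"A")
#' or second ("C"/"B") domain; a structure whose selected chain carries a
#' lone four-strand ferredoxin-like domain (e.g. one protomer of a
#' homodimeric barrel) is labeled directly.
#'
#' @param model a [StructureModel-class].
#' @param whichDomain "auto", "N"/"A" or "C"/"B".
#' @param annotation optional per-chain annotation.
#' @param config threshold overrides.
#' @return list(domain, model, elements).
#' @export
extractFerredoxinDomain <- function(model, whichDomain = "auto", annotation = NULL,
                                    config = list()) {
  cfg <- .mergeConfig(config)
  hbonds <- NULL
  elements <- if (!is.null(annotation))
    acceptAnnotation(model, annotation, cfg$minStrand, cfg$minHelix)
  else {
    hbonds <- detectHBonds(model, cutoff = cfg$hbondCutoff)
    assignSS(model, hbonds, cfg$minStrand, cfg$minHelix)
  }
  strands <- which(elements$kind == "strand")
  if (length(strands) >= 8) {
    pairs <- pairStrands(elements, hbonds, model, minBonds = cfg$minBonds,
                         contactDist = cfg$contactDist,
                         minContacts = cfg$minContacts)
    sheet <- buildBarrelSheet(pairs, elements, model)
    if (sheet@closed) {
      barrel <- mapDomains(elements, sheet, model,
                           identityThreshold = cfg$identityThreshold)
      dom <- if (whichDomain %in% c("C", "B", "2")) barrel@domainB else barrel@domainA
      return(list(domain = dom, model = model, elements = barrel@elements))
    }
  }
  if (length(strands) == 4) {
    ch <- unique(elements$chain[strands])
    if (length(ch) != 1)
      stop("four strands but on multiple chains; select a chain first")
    return(list(domain = domainFromStrands(elements, strands, ch),
                model = model, elements = elements))
  }
  stop("cannot extract a ferredoxin-like domain: ", length(strands),
       " strand elements, no closed barrel")
}

#' Compare two ferredoxin-like domains
#'
#' Extracts one labeled domain from each input and reports all four
#' correspondence candidates with the winner flagged.
#'
#' @param pathA,pathB structure files (or pass models via `modelA`/`modelB`).
#' @param modelA,modelB optional pre-loaded [StructureModel-class] objects.
#' @param chainsA,chainsB optional chain selections.
#' @param whichA,whichB domain selector per side ("auto", "N", "C").
#' @param annotationA,annotationB optional per-chain annotations.
#' @param config threshold overrides.
#' @param json optional JSON report path.
#' @return report list with `best` and `candidates`.
#' @export
runCompare <- function(pathA = NULL, pathB = NULL, modelA = NULL,
                       modelB = NULL, chainsA = NULL, chainsB = NULL,
                       whichA = "auto", whichB = "auto",
                       annotationA = NULL, annotationB = NULL,
                       config = list(), json = NULL) {
  cfg <- .mergeConfig(config)
  loadSide <- function(path, model, chains) {
    if (is.null(model)) {
      if (is.null(path)) stop("provide a path or model for both sides")
      loadStructure(path, chains = chains, hemeCodes = cfg$hemeCodes)
    } else model
  }
  mA <- .stage("structure_io", loadSide(pathA, modelA, chainsA))
  mB <- .stage("structure_io", loadSide(pathB, modelB, chainsB))
  dA <- .stage("ferredoxin_map",
               extractFerredoxinDomain(mA, whichDomain = whichA, annotation = annotationA, config = cfg))
  dB <- .stage("ferredoxin_map",
               extractFerredoxinDomain(mB, whichDomain = whichB, annotation = annotationB, config = cfg))
  corr <- .stage("superpose",
    alignDomains(dA$domain, dB$domain, dA$model, dB$model,
                 pairDist = cfg$pairDist, scoreDist = cfg$scoreDist,
                 seqIdThreshold = cfg$seqIdThreshold))
  report <- list(schema = "fdxbarrel-compare/1",
                 idA = mA@id, idB = mB@id, config = cfg,
                 best = .corrReport(corr$best),
                 candidates = lapply(corr$candidates, .corrReport))
  if (!is.null(json)) writeReport(report, json)
  report
}

#' Write a report as JSON
#'
#' @param report a report list.
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.printReport <- function(report) {
  cat("structure:", report$id, " chains:",
      paste(report$chains, collapse = " "), "\n")
  if (!is.null(report$arrangement))
    cat("arrangement:", report$arrangement, "\n")
  if (!is.null(report$packing)) {
    cat("packing:", report$packing$packing, "\n")
    if (!is.null(report$packing$orderString) &&
        nzchar(report$packing$orderString))
      cat("strand order:", report$packing$orderString, "\n")
  }
  for (h in report$hemes) {
    cat(sprintf("heme %s: mode %s", h$hetCode, h$mode))
    if (!is.null(h$proximal))
      cat(sprintf(", proximal %s %s%d (%.2f Å)", h$proximal$resid,
                  h$proximal$chain, h$proximal$resno, h$proximal$dist))
    cat("\n")
  }
  invisible(report)
}
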