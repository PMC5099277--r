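#' Pipeline configuration
#'
#' One object holding every tunable threshold of the analysis, with the
#' documented defaults. A short fingerprint of the configuration
#' (\code{\link{configHash}}) is stamped into every report header so reruns
#' can be matched to their settings.
#'
#' @param typing Typing bands, \code{\link{typingThresholds}}.
#' @param hbond H-bond criteria, \code{\link{hbondCriteria}}.
#' @param kinkThreshold,curveThreshold,bracketOffset,axisTurnMin See
#'   \code{\link{geometryClass}}.
#' @param bendOffset Window offset for the reported bend column (default 1).
#' @param vicinityCutoff Crossing-angle vicinity cutoff in Angstrom.
#' @param prolineWindow See \code{\link{perturbationType}}.
#' @param seed Seed recorded for simulation runs.
#' @return List of class \code{helixscan_config}.
#' @export
pipelineConfig <- function(typing = typingThresholds(),
                           hbond = hbondCriteria(),
                           kinkThreshold = 20, curveThreshold = 6,
                           bracketOffset = 4L, axisTurnMin = 15,
                           bendOffset = 1L, vicinityCutoff = 8,
                           prolineWindow = 4L, seed = NULL) {
  cfg <- list(typing = typing, hbond = hbond, kinkThreshold = kinkThreshold,
              curveThreshold = curveThreshold, bracketOffset = bracketOffset,
              axisTurnMin = axisTurnMin, bendOffset = bendOffset,
              vicinityCutoff = vicinityCutoff, prolineWindow = prolineWindow,
              seed = seed)
  class(cfg) <- "helixscan_config"
  cfg
}

#' @rdname pipelineConfig
#' @param config A \code{helixscan_config}.
#' @export
configHash <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

#' @export
print.helixscan_config <- function(x, ...) {
  cat("HelixScan pipeline configuration [", configHash(x), "]\n", sep = "")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Scan a structure: parameters, typing, perturbation and carbonyl reports
#'
#' Runs the full per-helix pipeline over the given TM segments: per-window
#' parameters, segment typing, geometric and perturbation classification,
#' backbone torsions, and the unpaired-carbonyl/stabilisation accounting.
#' Deterministic: two runs with the same inputs and configuration give
#' identical outputs.
#'
#' @param x A \linkS4class{ResidueSet} (the full structure).
#' @param segments data.frame from \code{\link{tmSegments}}.
#' @param config A \code{\link{pipelineConfig}}.
#' @return List of class \code{helixscan_scan}: \code{steps} (per-window
#'   table over all helices), \code{segments} (typed segment table),
#'   \code{perturbations} (one row per helix), \code{carbonyls} (unpaired
#'   carbonyls with stabilisation), \code{torsions} (anchor-relative phi/psi
#'   rows), \code{records} (the PerturbationRecord objects), and
#'   \code{config}.
#' @export
scanHelix <- function(x, segments, config = pipelineConfig()) {
  parts <- selectSegments(x, segments)
  allSteps <- list(); allSegs <- list(); allPert <- list()
  allCarb <- list(); allTors <- list(); records <- list()
  hb <- backboneHBonds(x, config$hbond)
  tors <- phiPsi(x)
  for (i in seq_along(parts)) {
    label <- names(parts)[i]
    rs <- parts[[i]]
    sg <- segments[i, ]
    steps <- stepSeries(rs, offset = config$bendOffset)
    st <- stepTable(steps)
    st$helix <- label
    allSteps[[i]] <- st
    labs <- classifySteps(steps, config$typing)
    segs <- mergeSegments(labs, steps, config$typing,
                          region = c(sg$first, sg$last))
    sgt <- segmentTable(segs)
    if (nrow(sgt)) sgt$helix <- label
    allSegs[[i]] <- sgt
    geo <- geometryClass(steps, kinkThreshold = config$kinkThreshold,
                         curveThreshold = config$curveThreshold,
                         bracketOffset = config$bracketOffset,
                         axisTurnMin = config$axisTurnMin)
    rt <- residueTable(rs)
    prolines <- rt$seqnum[rt$resname == "PRO"]
    rec <- perturbationType(geo, segs, prolines, helixId = label,
                            prolineWindow = config$prolineWindow)
    records[[label]] <- rec
    allPert[[i]] <- data.frame(
      helix = label, chain = sg$chain, first = sg$first, last = sg$last,
      class = pertClass(rec), maxba_res = maxbaSeq(rec),
      maxba_deg = round(maxbaValue(rec), 1), pro_res = prolineSeq(rec),
      segment = if (nrow(rec@segment))
        paste0(rec@segment$first, "-", rec@segment$last) else "",
      stringsAsFactors = FALSE)
    up <- unpairedCarbonyls(x, hb, region = c(sg$first, sg$last),
                            chain = sg$chain)
    stb <- stabilization(up, x, segments, config$hbond)
    cb <- stb$carbonyls
    if (nrow(cb)) {
      cb$helix <- label
      cb$class <- pertClass(rec)
      offs <- anchorOffsets(cb, rec)
      cb$anchor_offset <- if (length(offs)) offs else NA_integer_
    }
    allCarb[[i]] <- cb
    tr <- torsionReport(rec, tors[tors$chain == sg$chain, ])
    allTors[[i]] <- tr
  }
  out <- list(steps = do.call(rbind, allSteps),
              segments = do.call(rbind, allSegs),
              perturbations = do.call(rbind, allPert),
              carbonyls = do.call(rbind, allCarb),
              torsions = do.call(rbind, allTors),
              records = records,
              config = config)
  class(out) <- "helixscan_scan"
  out
}

#' @export
print.helixscan_scan <- function(x, ...) {
  cat("HelixScan scan:", nrow(x$perturbations), "helices\n")
  print(x$perturbations, row.names = FALSE)
  invisible(x)
}

#' Write scan reports to tab-separated files
#'
#' Writes the four report tables (per-window parameters, typed segments,
#' per-helix perturbation classes, unpaired carbonyls) as TSV files, each
#' headed by a comment line carrying the package version and the
#' configuration fingerprint. Reruns with identical inputs produce
#' byte-identical files.
#'
#' @param scan Output of \code{\link{scanHelix}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
writeReports <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# HelixScan ",
                as.character(utils::packageVersion("HelixScan")),
                " config=", configHash(scan$config))
  tabs <- list(steps = scan$steps, segments = scan$segments,
               perturbations = scan$perturbations, carbonyls = scan$carbonyls)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(p, "w")
    writeLines(hdr, con)
    d <- tabs[[nm]]
    if (is.null(d)) d <- data.frame()
    if (nrow(d)) {
      num <- vapply(d, is.numeric, logical(1))
      d[num] <- lapply(d[num], function(v) round(v, 3))
    }
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Simulate helices and write them with their ground-truth ledger
#'
#' Thin wrapper over \code{\link{generateBundle}} that writes the structure
#' as a PDB file and the ledger as JSON next to it.
#'
#' @param specs As \code{\link{generateBundle}}.
#' @param prefix Output path prefix; writes \code{<prefix>.pdb} and
#'   \code{<prefix>_ledger.json}.
#' @param seed Integer seed.
#' @return Invisibly, the \code{generateBundle} result.
#' @export
simulateHelix <- function(specs, prefix, seed = 1L) {
  b <- generateBundle(specs, seed = seed)
  writeStructure(b$structure, paste0(prefix, ".pdb"))
  jsonlite::write_json(b$ledger, paste0(prefix, "_ledger.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(b)
}
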