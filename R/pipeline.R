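#' Default analysis configuration
#'
#' Every threshold of the spectrin-repeat analysis, with the canonical
#' values as defaults: 20% relative-SASA burial cutoff, conservation grade
#' >= 7, pbs neighbour count > 5, 10 Angstrom contact radius, helicity gate
#' at 82% template average with 10% relative tolerance, Z-score bands at
#' -5.3 / -3.0, correlated-motion threshold 0.8.
#'
#' @param ... overrides for individual entries.
#' @return named list.
#' @export
srDefaults <- function(...) {
  cfg <- list(
    burialCutoff = 0.20,
    conservedMin = 7L,
    minNeighbours = 5L,
    contactRadius = 10,
    contactInclusive = TRUE,
    templateAvg = 0.82,
    helicityRelTol = 0.10,
    helicityReading = "relative",
    zVeryCut = -5.3,
    zLessCut = -3.0,
    minPbsPerRepeat = 5L,
    correlationThreshold = 0.8,
    probeRadius = 1.4,
    nSpherePoints = 960L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Per-repeat analysis of a spectrin-repeat model
#'
#' Orchestrates the whole pipeline on one structure: SASA and burial,
#' secondary structure and the helicity gate, conservation annotation, pbs
#' detection, per-repeat counts and flagged regions, and (optionally)
#' Z-score banding. Deterministic given inputs and configuration.
#'
#' @param pdb path to a PDB file, or an [SRStructure-class].
#' @param grades path to a grades TSV, or a named grade vector; may be
#'   `NULL`/empty (no residue is then conserved).
#' @param repeats path to a repeats TSV, or a data.frame
#'   (`repeat_id`,`start`,`end`); `NULL` treats the whole chain as one
#'   repeat "SR1".
#' @param zscores optional named numeric vector (or two-column TSV path
#'   `repeat_id<TAB>zscore`) of externally computed model Z-scores per repeat.
#' @param config list from [srDefaults()].
#' @return list with elements `reports` (data.frame, one row per repeat),
#'   `centres` (data.frame with author numbering), `flaggedRegions`,
#'   `manifest` (tool version, effective config, warnings).
#' @examples
#' s <- buildBundle(bundleSpec())
#' sr <- computeSasa(s, sasaParams(nSpherePoints = 240))
#' g <- plantConservation(s, sr, seed = 3)
#' res <- analyzeRepeats(s, g, config = srDefaults(nSpherePoints = 240))
#' res$reports
#' @export
analyzeRepeats <- function(pdb, grades = NULL, repeats = NULL, zscores = NULL,
                           config = srDefaults()) {
  warnings_ <- character()
  noteWarning <- function(w) {
    warnings_ <<- c(warnings_, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  s <- if (is(pdb, "SRStructure")) pdb else readPDB(pdb)
  g <- if (is.null(grades)) stats::setNames(integer(), character())
       else if (is.character(grades)) readGradesTSV(grades) else grades
  nres <- nResidues(s)
  reps <- if (is.null(repeats)) data.frame(repeat_id = "SR1", start = 0L,
                                           end = nres - 1L)
          else if (is.character(repeats)) readRepeatsTSV(repeats)
          else validateRepeats(repeats)
  zs <- if (is.character(zscores)) {
    zt <- utils::read.table(zscores, header = TRUE, sep = "\t")
    stats::setNames(zt[[2L]], zt[[1L]])
  } else zscores

  withCallingHandlers({
    params <- sasaParams(probeRadius = config$probeRadius,
                         nSpherePoints = config$nSpherePoints,
                         burialCutoff = config$burialCutoff)
    sasa <- computeSasa(s, params)
    ss <- assignSS(s)
    ann <- annotateResidues(s, g, sasa, conservedMin = config$conservedMin)
    if (!length(g)) warning("empty grade table: no residue is conserved")
    cm <- buildContactMap(s, radius = config$contactRadius,
                          inclusive = config$contactInclusive)
    pbs <- findPbs(ann, cm, minNeighbours = config$minNeighbours)
    pbs <- countPbsPerRepeat(pbs, reps, minPbs = config$minPbsPerRepeat)

    rt <- residueTable(s)
    rows <- lapply(seq_len(nrow(reps)), function(k) {
      sel <- ann$seqIndex >= reps$start[k] & ann$seqIndex <= reps$end[k]
      lab <- ss@labels[as.character(ann$seqIndex[sel])]
      hc <- helicalContentFromLabels(lab)
      annk <- ann[sel, , drop = FALSE]
      split_ <- suppressWarnings(conservedBurialSplit(annk))
      z <- if (!is.null(zs) && reps$repeat_id[k] %in% names(zs))
        unname(zs[reps$repeat_id[k]]) else NA_real_
      data.frame(
        repeat_id = reps$repeat_id[k],
        helical_content = hc,
        gate = helicityGate(hc, config$templateAvg, config$helicityRelTol,
                            reading = config$helicityReading),
        zscore = z,
        reliability = if (is.na(z)) NA_character_
                      else zscoreClassify(z, config$zVeryCut, config$zLessCut),
        percent_conserved = mean(annk$conserved),
        conserved_buried = unname(split_["buried"]),
        conserved_exposed = unname(split_["exposed"]),
        pbs_count = unname(pbs@perRepeatCounts[reps$repeat_id[k]]),
        stringsAsFactors = FALSE)
    })
    reports <- do.call(rbind, rows)

    centres <- data.frame(
      seq_index = pbs@centres,
      author_number = rt$authorNumber[match(pbs@centres, rt$seqIndex)],
      aa = rt$aa[match(pbs@centres, rt$seqIndex)],
      neighbour_count = unname(pbs@neighbourCounts[as.character(pbs@centres)]))

    manifest <- list(
      tool = "srpatch",
      version = as.character(utils::packageVersion("srpatch")),
      n_residues = nres,
      config = config,
      warnings = warnings_)

    list(reports = reports, centres = centres,
         flaggedRegions = pbs@flaggedRegions, manifest = manifest)
  }, warning = noteWarning)
}

#' Write an analysis report as canonical JSON
#'
#' Fixed float formatting (10 significant digits) so identical inputs give
#' byte-identical reports across runs and platforms.
#'
#' @param result list from [analyzeRepeats()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeAnalysisJSON <- function(result, path) {
  json <- jsonlite::toJSON(result, dataframe = "rows", auto_unbox = TRUE,
                           digits = I(10), pretty = TRUE, na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
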