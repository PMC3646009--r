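#' Build the C-alpha contact map
#'
#' Contact(i,j) = 1 iff |i-j| > 1 and the Euclidean distance between the
#' C-alpha atoms of i and j is <= `radius` (inclusive by default; set
#' `inclusive = FALSE` for the strict reading). Sequence neighbours and the
#' diagonal are never contacts. Residues lacking a C-alpha are excluded
#' with a warning.
#'
#' @param s an [SRStructure-class].
#' @param radius distance cutoff, Angstrom (default 10).
#' @param chain chain identifier (default: first chain).
#' @param inclusive treat d == radius as a contact (default TRUE).
#' @return a [ContactMap-class].
#' @export
buildContactMap <- function(s, radius = 10, chain = NULL, inclusive = TRUE) {
  stopifnot(is(s, "SRStructure"))
  a <- s@atoms
  if (is.null(chain)) chain <- a$chain[1L]
  ca <- caCoords(s, chain = chain)
  si <- as.integer(rownames(ca))
  d <- as.matrix(stats::dist(ca))
  m <- if (inclusive) d <= radius else d < radius
  sepOK <- abs(outer(si, si, "-")) > 1L
  m <- m & sepOK
  dimnames(m) <- list(si, si)
  new("ContactMap", map = m, radius = radius, seqIndex = si)
}

#' Merge conservation grades with burial classes
#'
#' Produces the per-residue annotation the patch detector consumes: grade,
#' conserved flag (grade >= `conservedMin`), burial class and relative
#' SASA. Residues absent from the grade table are treated as non-conserved
#' (grade `NA`) with a warning.
#'
#' @param s an [SRStructure-class].
#' @param grades named integer vector (names = seqIndex), as from
#'   [readGradesTSV()] or [plantConservation()].
#' @param sasa a [SasaResult-class] for `s`.
#' @param conservedMin minimal grade counted as conserved (default 7).
#' @return data.frame: `seqIndex`, `aa`, `grade`, `conserved`,
#'   `burialClass`, `relativeArea`.
#' @export
annotateResidues <- function(s, grades, sasa, conservedMin = 7L) {
  stopifnot(is(s, "SRStructure"), is(sasa, "SasaResult"))
  rt <- residueTable(s)
  key <- as.character(rt$seqIndex)
  grade <- unname(grades[key])
  if (anyNA(grade) && length(grades))
    warning(sum(is.na(grade)), " residue(s) missing from the grade table; treated as non-conserved")
  data.frame(
    seqIndex = rt$seqIndex,
    aa = rt$aa,
    grade = as.integer(grade),
    conserved = !is.na(grade) & grade >= conservedMin,
    burialClass = unname(sasa@burialClass[key]),
    relativeArea = unname(sasa@relativeArea[key]),
    stringsAsFactors = FALSE)
}

#' Detect putative binding sites (pbs)
#'
#' A residue is a pbs centre iff it is conserved and exposed and has more
#' than `minNeighbours` conserved, exposed neighbours under the contact
#' map. The centre itself never counts (the contact relation excludes
#' |i-j| <= 1 and the diagonal).
#'
#' @param ann annotation data.frame from [annotateResidues()].
#' @param cm a [ContactMap-class] over the same residues.
#' @param minNeighbours count threshold; a centre needs strictly more than
#'   this many qualifying neighbours (default 5).
#' @return a [PbsResult-class].
#' @examples
#' s <- buildBundle(bundleSpec())
#' sr <- computeSasa(s, sasaParams(nSpherePoints = 240))
#' g <- plantConservation(s, sr, seed = 7)
#' ann <- annotateResidues(s, g, sr)
#' findPbs(ann, buildContactMap(s))
#' @export
findPbs <- function(ann, cm, minNeighbours = 5L) {
  stopifnot(is(cm, "ContactMap"))
  eligible <- ann$seqIndex[ann$conserved & ann$burialClass == "exposed"]
  counts <- integer(0)
  centres <- integer(0)
  if (length(eligible)) {
    inMap <- intersect(eligible, cm@seqIndex)
    if (length(inMap) < length(eligible))
      warning("some conserved+exposed residues are absent from the contact map (no CA)")
    key <- as.character(inMap)
    sub <- cm@map[key, key, drop = FALSE]
    counts <- stats::setNames(as.integer(rowSums(sub)), key)
    centres <- inMap[counts > minNeighbours]
  }
  new("PbsResult", centres = as.integer(centres), neighbourCounts = counts,
      params = list(minNeighbours = as.integer(minNeighbours), radius = cm@radius))
}

#' Count pbs centres per repeat and flag contiguous high-pbs regions
#'
#' @param pbs a [PbsResult-class].
#' @param repeats data.frame with `repeat_id`, `start`, `end` (inclusive
#'   seqIndex bounds, sorted, non-overlapping), as from [readRepeatsTSV()].
#' @param minPbs a run of adjacent repeats is flagged when every repeat in
#'   it holds strictly more than this many centres (default 5).
#' @return the input `PbsResult` with `perRepeatCounts` and
#'   `flaggedRegions` filled; centres outside every repeat are counted
#'   under `"unassigned"` with a warning.
#' @export
countPbsPerRepeat <- function(pbs, repeats, minPbs = 5L) {
  stopifnot(is(pbs, "PbsResult"))
  repeats <- validateRepeats(repeats)
  counts <- stats::setNames(integer(nrow(repeats)), repeats$repeat_id)
  unassigned <- 0L
  for (c_ in pbs@centres) {
    hit <- which(repeats$start <= c_ & c_ <= repeats$end)
    if (length(hit)) counts[hit] <- counts[hit] + 1L else unassigned <- unassigned + 1L
  }
  if (unassigned > 0L) {
    warning(unassigned, " centre(s) fall outside every repeat")
    counts <- c(counts, unassigned = unassigned)
  }
  over <- counts[repeats$repeat_id] > minPbs
  runs <- rle(as.logical(over))
  flagged <- list()
  pos <- cumsum(c(1L, runs$lengths))
  for (k in seq_along(runs$values)) {
    if (isTRUE(runs$values[k]))
      flagged[[length(flagged) + 1L]] <-
        repeats$repeat_id[pos[k]:(pos[k] + runs$lengths[k] - 1L)]
  }
  methods::initialize(pbs, perRepeatCounts = counts, flaggedRegions = flagged,
                      params = c(pbs@params, list(minPbs = as.integer(minPbs))))
}

#' Buried/exposed split among conserved residues
#'
#' @param ann annotation data.frame from [annotateResidues()].
#' @return named numeric `c(buried=, exposed=)` summing to 1, or both `NA`
#'   (with a warning) when no residue is conserved.
#' @export
conservedBurialSplit <- function(ann) {
  cons <- ann[ann$conserved, , drop = FALSE]
  if (!nrow(cons)) {
    warning("no conserved residues; split undefined")
    return(c(buried = NA_real_, exposed = NA_real_))
  }
  b <- mean(cons$burialClass == "buried")
  c(buried = b, exposed = 1 - b)
}
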