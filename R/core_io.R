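#' Read a PDB file into SRStructure objects
#'
#' Parses ATOM records with bio3d; HETATM records, waters and hydrogens are
#' skipped, and alternate locations are resolved by keeping the highest
#' occupancy (ties broken alphabetically by altloc letter, so 'A' wins).
#' Residues are ordered by (chain, author number, insertion code) and given a
#' 0-based contiguous `seqIndex` per chain.
#'
#' @param path PDB file path.
#' @param modelPolicy `"first"` (default) returns one [SRStructure-class];
#'   `"all"` returns a list with one structure per MODEL record.
#' @return an `SRStructure`, or a list of them when `modelPolicy = "all"`.
#' @examples
#' s <- buildBundle(bundleSpec(helixLengths = c(10, 10, 10)))
#' f <- tempfile(fileext = ".pdb")
#' writePDB(s, f)
#' s2 <- readPDB(f)
#' nResidues(s2)
#' @export
readPDB <- function(path, modelPolicy = c("first", "all")) {
  modelPolicy <- match.arg(modelPolicy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isAtom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(startsWith(lines, "ATOM  ")))
    stop("no ATOM records in '", path, "'")
  bad <- which(isAtom & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad))
    stop(sprintf("malformed ATOM record at line %d of '%s'", bad[1L], path))

  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  nModels <- nrow(pdb$xyz)

  keep <- at$type == "ATOM"
  elesy <- at$elesy
  elesy[is.na(elesy) | !nzchar(trimws(elesy))] <-
    substr(gsub("[0-9]", "", at$elety[is.na(elesy) | !nzchar(trimws(elesy))]), 1, 1)
  elesy <- trimws(elesy)
  keep <- keep & !(elesy %in% c("H", "D")) & !(at$resid %in% c("HOH", "WAT", "DOD"))
  idx <- which(keep)

  a <- at[idx, , drop = FALSE]
  a$elesy <- elesy[idx]
  a$alt[is.na(a$alt)] <- ""
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- "A"
  a$o[is.na(a$o)] <- 1
  a$o <- pmin(pmax(a$o, 0), 1)

  # altloc resolution within (chain, resno, insert, elety)
  grp <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(grp, -a$o, a$alt)
  sel <- sort(ord[!duplicated(grp[ord])])  # keep original atom order
  a <- a[sel, , drop = FALSE]
  idx <- idx[sel]

  # canonical residue order and 0-based seqIndex per chain
  ord <- order(a$chain, a$resno, a$insert)
  a <- a[ord, , drop = FALSE]
  idx <- idx[ord]
  rkey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  seqIndex <- integer(nrow(a))
  for (ch in unique(a$chain)) {
    m <- a$chain == ch
    u <- unique(rkey[m])
    seqIndex[m] <- match(rkey[m], u) - 1L
  }

  makeStruct <- function(xyzrow) {
    atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                        resid = a$resid, elety = a$elety, element = a$elesy,
                        x = xyzrow[3L * (idx - 1L) + 1L],
                        y = xyzrow[3L * (idx - 1L) + 2L],
                        z = xyzrow[3L * (idx - 1L) + 3L],
                        o = a$o, seqIndex = seqIndex,
                        stringsAsFactors = FALSE)
    new("SRStructure", atoms = atoms, title = basename(path))
  }

  if (modelPolicy == "first") return(makeStruct(pdb$xyz[1L, ]))
  lapply(seq_len(nModels), function(i) makeStruct(pdb$xyz[i, ]))
}

#' Write one or more SRStructure objects as a PDB file
#'
#' A list of structures with identical atom tables is written as a
#' multi-MODEL file.
#'
#' @param s an [SRStructure-class] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(s, path) {
  if (is(s, "SRStructure")) s <- list(s)
  stopifnot(length(s) >= 1L, all(vapply(s, is, TRUE, "SRStructure")))
  a <- s[[1L]]@atoms
  xyz <- do.call(rbind, lapply(s, function(si)
    as.numeric(t(as.matrix(si@atoms[, c("x", "y", "z")])))))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain, insert = ifelse(nzchar(a$insert), a$insert, ""),
                   o = a$o, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Read a conservation grade table
#'
#' ConSurf-style grades: integer 1 (most variable) to 9 (most conserved),
#' one row per residue, keyed by the structure's 0-based `seqIndex`.
#'
#' @param path TSV file with header `seq_index<TAB>grade`.
#' @return named integer vector (names = seq_index).
#' @export
readGradesTSV <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("seq_index", "grade") %in% names(d)))
    stop("grades TSV must have columns 'seq_index' and 'grade'")
  bad <- which(!is.finite(d$grade) | d$grade < 1 | d$grade > 9 | d$grade != round(d$grade))
  if (length(bad))
    stop(sprintf("grade out of range 1..9 at row %d (seq_index %s, grade %s)",
                 bad[1L], d$seq_index[bad[1L]], d$grade[bad[1L]]))
  if (anyDuplicated(d$seq_index))
    stop("duplicated seq_index in grades TSV")
  stats::setNames(as.integer(d$grade), d$seq_index)
}

#' Write a conservation grade table
#' @param grades named integer vector as returned by [readGradesTSV()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeGradesTSV <- function(grades, path) {
  utils::write.table(
    data.frame(seq_index = as.integer(names(grades)), grade = as.integer(grades)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read repeat boundary definitions
#'
#' @param path TSV with header `repeat_id<TAB>start<TAB>end`; boundaries are
#'   inclusive 0-based `seqIndex` values, rows sorted and non-overlapping.
#' @return data.frame with columns `repeat_id`, `start`, `end`.
#' @export
readRepeatsTSV <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("repeat_id", "start", "end") %in% names(d)))
    stop("repeats TSV must have columns 'repeat_id', 'start', 'end'")
  validateRepeats(d)
}

validateRepeats <- function(d) {
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  if (any(d$start > d$end)) stop("repeat with start > end")
  if (nrow(d) > 1L) {
    if (is.unsorted(d$start)) stop("repeats must be sorted by start")
    if (any(d$start[-1L] <= d$end[-nrow(d)])) stop("repeats must be non-overlapping")
  }
  if (anyDuplicated(d$repeat_id)) stop("duplicated repeat_id")
  d[, c("repeat_id", "start", "end")]
}

#' Extract one repeat from a structure
#'
#' Returns the residues `start..end` (inclusive, 0-based `seqIndex`) of one
#' chain, with `seqIndex` re-based to 0 and author numbering preserved.
#'
#' @param s an [SRStructure-class].
#' @param start,end inclusive seqIndex bounds.
#' @param chain chain to slice (default: the first).
#' @return an `SRStructure`.
#' @export
sliceRepeat <- function(s, start, end, chain = NULL) {
  stopifnot(is(s, "SRStructure"))
  if (start > end) stop("slice start > end")
  a <- s@atoms
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  nres <- length(unique(a$seqIndex))
  if (start < 0L || end > nres - 1L)
    stop(sprintf("slice [%d, %d] outside residue range [0, %d]", start, end, nres - 1L))
  a <- a[a$seqIndex >= start & a$seqIndex <= end, , drop = FALSE]
  a$seqIndex <- a$seqIndex - as.integer(start)
  new("SRStructure", atoms = a, title = s@title, meta = s@meta)
}

#' Read a multi-MODEL PDB file as a C-alpha ensemble
#'
#' @param path multi-MODEL PDB file.
#' @return an [SREnsemble-class]; the reference is the first frame.
#' @export
readEnsemblePDB <- function(path) {
  frames <- readPDB(path, modelPolicy = "all")
  if (length(frames) < 2L) stop("ensemble file must contain at least 2 MODELs")
  cas <- lapply(frames, caCoords)
  n <- nrow(cas[[1L]])
  if (!all(vapply(cas, nrow, 1L) == n)) stop("frames differ in C-alpha count")
  xyz <- do.call(rbind, lapply(cas, function(m) as.numeric(t(m))))
  new("SREnsemble", xyz = xyz, reference = xyz[1L, ],
      seqIndex = as.integer(rownames(cas[[1L]])))
}
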