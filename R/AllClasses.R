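#' @import methods
NULL

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", X = "UNK")
AA1 <- stats::setNames(names(AA3), AA3)

aaThreeToOne <- function(x) {
  out <- unname(AA1[x])
  out[is.na(out)] <- "X"
  out
}

aaOneToThree <- function(x) {
  out <- unname(AA3[x])
  out[is.na(out)] <- "UNK"
  out
}

#' SRStructure: a protein structure for spectrin-repeat analysis
#'
#' Holds heavy-atom coordinates of one model, organised as a flat atom table
#' plus a derived residue index. Residues are identified internally by a
#' 0-based contiguous `seqIndex` per chain; the author numbering of the
#' source PDB (`resno` + insertion code) is retained for reporting, because
#' nesprin positions are conventionally quoted in author numbering
#' (e.g. Glu8191).
#'
#' @slot atoms data.frame with columns `chain`, `resno` (author number,
#'   integer), `insert` (insertion code, "" when absent), `resid`
#'   (three-letter residue code), `elety` (PDB atom name), `element`
#'   (element symbol), `x`, `y`, `z` (Angstrom), `o` (occupancy),
#'   `seqIndex` (0-based contiguous residue index within its chain).
#' @slot title free-text description.
#' @slot meta list of generator metadata (segment labels etc.), possibly empty.
#' @export
setClass("SRStructure",
  representation(atoms = "data.frame", title = "character", meta = "list"),
  prototype(title = "", meta = list()))

setValidity("SRStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "o", "seqIndex")
  if (!all(need %in% names(a)))
    return(paste("atoms table missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (!all(a$o >= 0 & a$o <= 1)) return("occupancy outside [0,1]")
  for (ch in unique(a$chain)) {
    si <- sort(unique(a$seqIndex[a$chain == ch]))
    if (!identical(si, seq_along(si) - 1L))
      return(sprintf("seqIndex not 0-based contiguous in chain '%s'", ch))
  }
  TRUE
})

#' SasaResult: per-atom and per-residue solvent accessibility
#'
#' @slot atomArea numeric, one area per row of the structure's atom table, Angstrom^2.
#' @slot residueArea named numeric, residue SASA by seqIndex, Angstrom^2.
#' @slot relativeArea named numeric, residueArea / reference Ala-Xxx-Ala area.
#' @slot burialClass named character, "buried" or "exposed" by seqIndex.
#' @slot params list: probe radius, sphere points, radii set used.
#' @export
setClass("SasaResult",
  representation(atomArea = "numeric", residueArea = "numeric",
                 relativeArea = "numeric", burialClass = "character",
                 params = "list"))

setValidity("SasaResult", function(object) {
  if (any(object@atomArea < -1e-9)) return("negative atom area")
  if (any(object@residueArea < -1e-9)) return("negative residue area")
  if (!all(object@burialClass %in% c("buried", "exposed")))
    return("burialClass must be 'buried' or 'exposed'")
  if (length(object@residueArea) != length(object@relativeArea))
    return("residueArea and relativeArea lengths differ")
  TRUE
})

#' SSAssignment: per-residue secondary-structure labels
#'
#' Labels follow the DSSP alphabet restricted to H (alpha), G (3-10),
#' I (pi), E (strand), T (turn) and C (coil). Helical content is the
#' fraction of residues labelled H, G or I.
#'
#' @slot labels named character vector by seqIndex.
#' @slot helicalContent fraction in [0,1].
#' @export
setClass("SSAssignment",
  representation(labels = "character", helicalContent = "numeric"))

setValidity("SSAssignment", function(object) {
  if (!all(object@labels %in% c("H", "G", "I", "E", "T", "C")))
    return("labels must be in {H,G,I,E,T,C}")
  if (length(object@helicalContent) != 1L ||
      object@helicalContent < 0 || object@helicalContent > 1)
    return("helicalContent must be a single value in [0,1]")
  TRUE
})

#' ContactMap: the C-alpha neighbour relation
#'
#' Contact(i,j) = 1 iff |i-j| > 1 and d(i,j) <= radius, where d is the
#' Euclidean distance between C-alpha atoms. Sequence neighbours and the
#' diagonal are never contacts.
#'
#' @slot map symmetric logical matrix, dimnames = seqIndex.
#' @slot radius cutoff, Angstrom.
#' @slot seqIndex integer vector of included residues (those with a C-alpha).
#' @export
setClass("ContactMap",
  representation(map = "matrix", radius = "numeric", seqIndex = "integer"))

setValidity("ContactMap", function(object) {
  m <- object@map
  if (!is.logical(m)) return("map must be logical")
  if (nrow(m) != ncol(m)) return("map must be square")
  if (!isTRUE(all(m == t(m)))) return("map must be symmetric")
  si <- object@seqIndex
  if (length(si) != nrow(m)) return("seqIndex length must match map dimension")
  d <- abs(outer(si, si, "-"))
  if (any(m & d <= 1L)) return("sequence neighbours (|i-j| <= 1) cannot be contacts")
  TRUE
})

#' PbsResult: putative binding sites detected on a structure surface
#'
#' A pbs centre is a conserved (grade >= 7), exposed residue with more than
#' five conserved, exposed C-alpha neighbours within the contact radius.
#'
#' @slot centres integer vector of seqIndex values.
#' @slot neighbourCounts named integer, qualifying-neighbour count for every
#'   conserved and exposed residue.
#' @slot perRepeatCounts named integer, pbs centres per repeat (filled by
#'   [countPbsPerRepeat()]).
#' @slot flaggedRegions list of character vectors, maximal runs of adjacent
#'   repeats each holding more than `minPbs` centres.
#' @slot params list of thresholds used.
#' @export
setClass("PbsResult",
  representation(centres = "integer", neighbourCounts = "integer",
                 perRepeatCounts = "integer", flaggedRegions = "list",
                 params = "list"),
  prototype(perRepeatCounts = integer(), flaggedRegions = list()))

#' SREnsemble: a C-alpha coordinate ensemble
#'
#' @slot xyz numeric matrix, n_frames x 3N, frame coordinates interleaved
#'   (x1,y1,z1,x2,...), Angstrom.
#' @slot reference numeric 3N vector, the reference coordinates.
#' @slot seqIndex integer vector of the N residues represented.
#' @export
setClass("SREnsemble",
  representation(xyz = "matrix", reference = "numeric", seqIndex = "integer"))

setValidity("SREnsemble", function(object) {
  if (nrow(object@xyz) < 2L) return("an ensemble needs at least 2 frames")
  if (ncol(object@xyz) %% 3L != 0L) return("coordinate dimension must be a multiple of 3")
  if (length(object@reference) != ncol(object@xyz))
    return("reference length must equal frame dimension")
  if (length(object@seqIndex) * 3L != ncol(object@xyz))
    return("seqIndex length must be n_coords / 3")
  TRUE
})

#' PCAResult: essential-dynamics decomposition of an ensemble
#'
#' @slot values eigenvalues of the 3N x 3N C-alpha covariance, descending, Angstrom^2.
#' @slot vectors orthonormal eigenvectors as columns (3N x k).
#' @slot mean numeric 3N vector, the ensemble mean structure.
#' @slot seqIndex integer vector of represented residues.
#' @export
setClass("PCAResult",
  representation(values = "numeric", vectors = "matrix", mean = "numeric",
                 seqIndex = "integer"))

setValidity("PCAResult", function(object) {
  if (is.unsorted(rev(object@values), strictly = FALSE))
    return("eigenvalues must be in descending order")
  if (any(object@values < -1e-8 * max(abs(object@values), 1)))
    return("eigenvalues must be non-negative to tolerance")
  v <- object@vectors
  g <- crossprod(v)
  if (max(abs(g - diag(ncol(v)))) > 1e-6)
    return("eigenvectors must be orthonormal")
  TRUE
})

#' OverlapResult: subspace overlap of two essential subspaces
#'
#' @slot pairMatrix k x k matrix of squared inner products (a_i . b_j)^2.
#' @slot averageSquareProjection scalar in [0,1]: sum(pairMatrix) / k.
#' @slot bestMatches integer vector, for each eigenvector of `a` the index of
#'   the best-matching eigenvector of `b`.
#' @export
setClass("OverlapResult",
  representation(pairMatrix = "matrix", averageSquareProjection = "numeric",
                 bestMatches = "integer"))

setValidity("OverlapResult", function(object) {
  asp <- object@averageSquareProjection
  if (length(asp) != 1L || asp < -1e-9 || asp > 1 + 1e-9)
    return("averageSquareProjection must be a scalar in [0,1]")
  if (any(object@pairMatrix < -1e-12)) return("pairMatrix entries must be >= 0")
  TRUE
})
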