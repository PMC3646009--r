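#' Number of residues in a structure
#' @param x an object with residues.
#' @param ... unused.
#' @export
setGeneric("nResidues", function(x, ...) standardGeneric("nResidues"))

#' Residue-level summary table
#'
#' @param x an [SRStructure-class].
#' @param ... unused.
#' @return data.frame with one row per residue: `seqIndex`, `chain`,
#'   `authorNumber`, `insert`, `aa` (one-letter), `hasCA`.
#' @export
setGeneric("residueTable", function(x, ...) standardGeneric("residueTable"))

#' C-alpha coordinates of a structure
#'
#' @param x an [SRStructure-class].
#' @param chain restrict to one chain (default: all, in order).
#' @param ... unused.
#' @return numeric matrix n x 3 with rownames = seqIndex; residues lacking a
#'   C-alpha are omitted.
#' @export
setGeneric("caCoords", function(x, ...) standardGeneric("caCoords"))

#' Helical content of a secondary-structure assignment
#'
#' Fraction of residues labelled H (alpha), G (3-10) or I (pi). This is the
#' model-quality observable compared against the spectrin-repeat template
#' average.
#'
#' @param x an [SSAssignment-class] or a character vector of labels.
#' @param classes labels counted as helical (default `c("H","G","I")`).
#' @param ... unused.
#' @return fraction in [0,1].
#' @export
setGeneric("helicalContent", function(x, ...) standardGeneric("helicalContent"))

#' Pbs centres of a detection result
#' @param x a [PbsResult-class].
#' @param ... unused.
#' @export
setGeneric("pbsCentres", function(x, ...) standardGeneric("pbsCentres"))

#' Eigenvalues / eigenvectors accessors
#' @param x a [PCAResult-class].
#' @param ... unused.
#' @export
setGeneric("eigenValues", function(x, ...) standardGeneric("eigenValues"))

#' @rdname eigenValues
#' @export
setGeneric("eigenVectors", function(x, ...) standardGeneric("eigenVectors"))

#' Number of frames in an ensemble
#' @param x an [SREnsemble-class].
#' @param ... unused.
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))
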