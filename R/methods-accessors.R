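#' @describeIn SRStructure number of residues (across all chains).
#' @param x,object an `SRStructure`.
#' @param ... unused.
#' @export
setMethod("nResidues", "SRStructure", function(x, ...) {
  a <- x@atoms
  nrow(unique(a[, c("chain", "seqIndex")]))
})

#' @describeIn SRStructure residue-level summary table.
#' @export
setMethod("residueTable", "SRStructure", function(x, ...) {
  a <- x@atoms
  key <- !duplicated(a[, c("chain", "seqIndex")])
  r <- a[key, c("chain", "seqIndex", "resno", "insert", "resid")]
  hasCA <- tapply(a$elety == "CA", paste(a$chain, a$seqIndex), any)
  r$hasCA <- as.logical(hasCA[paste(r$chain, r$seqIndex)])
  data.frame(seqIndex = r$seqIndex, chain = r$chain, authorNumber = r$resno,
             insert = r$insert, aa = aaThreeToOne(r$resid), hasCA = r$hasCA,
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @describeIn SRStructure C-alpha coordinate matrix (n x 3, rownames =
#'   seqIndex); residues without a C-alpha are omitted with a warning.
#' @param chain optional chain identifier.
#' @export
setMethod("caCoords", "SRStructure", function(x, chain = NULL, ...) {
  a <- x@atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca[, c("chain", "seqIndex")]), , drop = FALSE]
  nres <- nrow(unique(a[, c("chain", "seqIndex")]))
  if (nrow(ca) < nres)
    warning(sprintf("%d residue(s) lack a CA atom and are excluded", nres - nrow(ca)))
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$seqIndex
  m
})

setMethod("show", "SRStructure", function(object) {
  a <- object@atoms
  cat(sprintf("SRStructure: %d chain(s), %d residue(s), %d atom(s)\n",
              length(unique(a$chain)), nResidues(object), nrow(a)))
  if (nzchar(object@title)) cat("  title:", object@title, "\n")
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf(
    "SasaResult: %d residues; %d buried / %d exposed (probe %.2f A, %d points)\n",
    length(object@residueArea),
    sum(object@burialClass == "buried"), sum(object@burialClass == "exposed"),
    object@params$probeRadius, object@params$nSpherePoints))
})

#' @describeIn SSAssignment helical content (fraction H+G+I).
#' @param x,object an `SSAssignment`.
#' @param classes labels counted as helical.
#' @param ... unused.
#' @export
setMethod("helicalContent", "SSAssignment", function(x, classes = c("H", "G", "I"), ...) {
  helicalContentFromLabels(x@labels, classes = classes)
})

#' @export
setMethod("helicalContent", "character", function(x, classes = c("H", "G", "I"), ...) {
  helicalContentFromLabels(x, classes = classes)
})

setMethod("show", "SSAssignment", function(object) {
  tab <- table(factor(object@labels, levels = c("H", "G", "I", "E", "T", "C")))
  cat(sprintf("SSAssignment: %d residues; helical content %.1f%%\n",
              length(object@labels), 100 * object@helicalContent))
  print(tab)
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d residues, radius %.1f A, %d contact pairs\n",
              nrow(object@map), object@radius, sum(object@map) / 2L))
})

#' @describeIn PbsResult the detected centre seqIndex values.
#' @param x,object a `PbsResult`.
#' @param ... unused.
#' @export
setMethod("pbsCentres", "PbsResult", function(x, ...) x@centres)

setMethod("show", "PbsResult", function(object) {
  cat(sprintf("PbsResult: %d centre(s) among %d conserved+exposed residue(s)\n",
              length(object@centres), length(object@neighbourCounts)))
  if (length(object@perRepeatCounts)) {
    cat("  per-repeat counts:\n")
    print(object@perRepeatCounts)
    if (length(object@flaggedRegions))
      cat("  flagged regions:",
          paste(vapply(object@flaggedRegions, function(r)
            paste(r[c(1L, length(r))], collapse = "-"), ""), collapse = ", "), "\n")
  }
})

#' @describeIn SREnsemble number of frames.
#' @param x,object an `SREnsemble`.
#' @param ... unused.
#' @export
setMethod("nFrames", "SREnsemble", function(x, ...) nrow(x@xyz))

setMethod("show", "SREnsemble", function(object) {
  cat(sprintf("SREnsemble: %d frames x %d C-alpha atoms\n",
              nrow(object@xyz), ncol(object@xyz) / 3L))
})

#' @describeIn PCAResult eigenvalues (descending, Angstrom^2).
#' @param x,object a `PCAResult`.
#' @param ... unused.
#' @export
setMethod("eigenValues", "PCAResult", function(x, ...) x@values)

#' @describeIn PCAResult eigenvector matrix (3N x k, columns orthonormal).
#' @export
setMethod("eigenVectors", "PCAResult", function(x, ...) x@vectors)

setMethod("show", "PCAResult", function(object) {
  tot <- sum(object@values)
  lead <- if (tot > 0) 100 * object@values[1L] / tot else NA_real_
  cat(sprintf("PCAResult: %d modes over %d coordinates; PC1 carries %.1f%% of variance\n",
              ncol(object@vectors), length(object@mean), lead))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: k = %d, average square projection = %.3f\n",
              nrow(object@pairMatrix), object@averageSquareProjection))
})
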