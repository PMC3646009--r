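#' Default van der Waals radii
#'
#' A single published heavy-atom radius table: carbonyl/aromatic carbon
#' 1.70, aliphatic carbon (CA, CB and other side-chain carbons) 1.87,
#' nitrogen 1.55, oxygen 1.52, sulfur 1.80 Angstrom.
#'
#' @return named numeric vector by element, plus an `"C.aliphatic"` entry
#'   applied to CA/CB and side-chain carbon atom names.
#' @export
defaultVdwRadii <- function() {
  c(C = 1.70, C.aliphatic = 1.87, N = 1.55, O = 1.52, S = 1.80)
}

#' Parameters for the Shrake-Rupley SASA engine
#'
#' @param probeRadius solvent probe radius, Angstrom (water: 1.4).
#' @param nSpherePoints number of quadrature points per atom (>= 60); points
#'   come from a deterministic generalized spiral, so results are exactly
#'   reproducible without a seed.
#' @param radii radius table as from [defaultVdwRadii()].
#' @param burialCutoff relative-SASA threshold separating buried from
#'   exposed (exposed iff relative SASA > cutoff).
#' @return list of class `sasaParams`.
#' @export
sasaParams <- function(probeRadius = 1.4, nSpherePoints = 960L,
                       radii = defaultVdwRadii(), burialCutoff = 0.20) {
  if (probeRadius <= 0) stop("probeRadius must be > 0")
  if (nSpherePoints < 60L) stop("nSpherePoints must be >= 60")
  structure(list(probeRadius = probeRadius,
                 nSpherePoints = as.integer(nSpherePoints),
                 radii = radii, burialCutoff = burialCutoff),
            class = "sasaParams")
}

# Molecule-fixed orthonormal frame: principal axes of the atom cloud with
# signs anchored to the first atoms, so the frame co-rotates with the
# structure. Falls back to the identity for single atoms or degenerate
# clouds.
canonicalFrame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(diag(3))
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2L, ctr)
  eg <- eigen(crossprod(cc) / n, symmetric = TRUE)
  V <- eg$vectors
  refs <- rbind(cc[1L, ], cc[min(2L, n), ], cc[min(3L, n), ])
  for (k in 1:3) {
    d <- 0
    for (r in seq_len(nrow(refs))) {
      d <- sum(V[, k] * refs[r, ])
      if (abs(d) > 1e-6) break
    }
    if (d < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  V
}

# Radius per atom row: aliphatic-carbon class for CA/CB and side-chain
# carbons, element radius otherwise. Errors on uncovered elements.
atomRadii <- function(atoms, radii) {
  r <- radii[atoms$element]
  aliph <- atoms$element == "C" & atoms$elety != "C"
  if ("C.aliphatic" %in% names(radii)) r[aliph] <- radii[["C.aliphatic"]]
  missing <- unique(atoms$element[is.na(r)])
  if (length(missing))
    stop("no van der Waals radius configured for element(s): ",
         paste(missing, collapse = ", "))
  unname(r)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's accessible area is the fraction of `nSpherePoints` test
#' points on its solvent-expanded sphere (radius r + probe) not occluded by
#' any neighbouring atom's expanded sphere, times 4 pi (r + probe)^2.
#'
#' @param s an [SRStructure-class] (heavy atoms only).
#' @param params a [sasaParams()].
#' @return numeric vector of areas, Angstrom^2, one per atom row.
#' @export
atomSasa <- function(s, params = sasaParams()) {
  stopifnot(is(s, "SRStructure"), inherits(params, "sasaParams"))
  atoms <- s@atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atomRadii(atoms, params$radii) + params$probeRadius
  n <- nrow(xyz)
  # quadrature points live in a molecule-fixed canonical frame, so areas are
  # invariant (to floating-point precision) under rigid motion of the input
  sphere <- fibonacciSphere(params$nSpherePoints) %*% t(canonicalFrame(xyz))
  areas <- numeric(n)
  # neighbour lists via a cell-free cutoff: i occludable by j iff
  # d(i,j) < r_i + r_j
  dmat <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < r[i] + r & seq_len(n) != i)
    if (!length(nb)) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    pts <- sweep(sphere * r[i], 2L, xyz[i, ], "+")
    free <- rep(TRUE, nrow(pts))
    for (j in nb) {
      if (!any(free)) break
      dd <- (pts[free, 1L] - xyz[j, 1L])^2 + (pts[free, 2L] - xyz[j, 2L])^2 +
            (pts[free, 3L] - xyz[j, 3L])^2
      free[free] <- dd >= r[j]^2
    }
    areas[i] <- mean(free) * 4 * pi * r[i]^2
  }
  areas
}

refAreaCache <- new.env(parent = emptyenv())

#' Reference SASA of residue Xxx in an extended Ala-Xxx-Ala tripeptide
#'
#' The denominator of relative SASA: the area of the residue in an isolated,
#' internally built extended tripeptide (phi = -139, psi = +135 degrees),
#' measured with the same Shrake-Rupley engine and atom representation as
#' the numerator. Values are cached per parameter set.
#'
#' @param aa one-letter amino-acid code (standard 20).
#' @param params a [sasaParams()].
#' @return area, Angstrom^2.
#' @export
referenceArea <- function(aa, params = sasaParams()) {
  if (!aa %in% names(AA3)[names(AA3) != "X"])
    stop("no reference area for residue code '", aa, "'")
  key <- paste(aa, params$probeRadius, params$nSpherePoints,
               paste(names(params$radii), params$radii, collapse = ","), sep = "|")
  hit <- refAreaCache[[key]]
  if (!is.null(hit)) return(hit)
  atoms <- buildChainAtoms(c("A", aa, "A"), -139, 135)
  s <- new("SRStructure", atoms = atoms, title = sprintf("Ala-%s-Ala reference", aa))
  a <- atomSasa(s, params)
  val <- sum(a[atoms$seqIndex == 1L])
  refAreaCache[[key]] <- val
  val
}

#' Classify a relative SASA as buried or exposed
#'
#' A residue is buried when its SASA in the protein is 20% or less of its
#' SASA in the isolated Ala-Xxx-Ala tripeptide, exposed when above 20%
#' (the value exactly at the cutoff is classified buried; the source rule
#' states strict inequalities on both sides and leaves the boundary open).
#'
#' @param relativeArea numeric vector of relative areas (>= 0).
#' @param cutoff burial threshold (default 0.20).
#' @return character vector, "buried" or "exposed".
#' @export
classifyBurial <- function(relativeArea, cutoff = 0.20) {
  if (any(!is.finite(relativeArea)) || any(relativeArea < 0))
    stop("relativeArea must be finite and non-negative")
  ifelse(relativeArea > cutoff, "exposed", "buried")
}

#' Full per-residue SASA analysis of a structure
#'
#' Runs [atomSasa()], sums areas per residue, normalises by
#' [referenceArea()] and classifies burial.
#'
#' @param s an [SRStructure-class].
#' @param params a [sasaParams()].
#' @return a [SasaResult-class].
#' @examples
#' s <- buildBundle(bundleSpec())
#' sr <- computeSasa(s, sasaParams(nSpherePoints = 240))
#' table(sr@burialClass)
#' @export
computeSasa <- function(s, params = sasaParams()) {
  atoms <- s@atoms
  areas <- atomSasa(s, params)
  si <- sort(unique(atoms$seqIndex))
  resArea <- vapply(si, function(i) sum(areas[atoms$seqIndex == i]), 0)
  rt <- residueTable(s)
  aa <- rt$aa[match(si, rt$seqIndex)]
  refs <- vapply(aa, function(a)
    if (a == "X") referenceArea("A", params) else referenceArea(a, params), 0)
  rel <- resArea / refs
  cls <- classifyBurial(rel, params$burialCutoff)
  names(resArea) <- names(rel) <- names(cls) <- si
  new("SasaResult", atomArea = areas, residueArea = resArea,
      relativeArea = rel, burialClass = cls,
      params = list(probeRadius = params$probeRadius,
                    nSpherePoints = params$nSpherePoints,
                    radii = params$radii, burialCutoff = params$burialCutoff))
}

#' Write a per-residue SASA table
#'
#' @param s the analysed [SRStructure-class].
#' @param sasa its [SasaResult-class].
#' @param path output TSV path (columns seq_index, author_number, aa, area,
#'   relative_area, burial_class).
#' @return `path`, invisibly.
#' @export
writeSasaTSV <- function(s, sasa, path) {
  rt <- residueTable(s)
  si <- as.integer(names(sasa@residueArea))
  d <- data.frame(seq_index = si,
                  author_number = rt$authorNumber[match(si, rt$seqIndex)],
                  aa = rt$aa[match(si, rt$seqIndex)],
                  area = round(sasa@residueArea, 3),
                  relative_area = round(sasa@relativeArea, 4),
                  burial_class = sasa@burialClass)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
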