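#' Specification of a synthetic three-helix bundle
#'
#' Defines an idealized antiparallel three-helix bundle of the kind formed by
#' a single spectrin repeat: helices A, B, C packed on a triangular lattice
#' and connected by two short loops.
#'
#' @param helixLengths integer vector of three helix lengths (residues), each
#'   >= 8. Default `c(16, 18, 16)`.
#' @param loopLengths integer vector of two loop lengths (residues), each
#'   >= 2. Default `c(4, 4)`.
#' @param interHelixDistance axis-to-axis helix separation, Angstrom.
#' @param antiparallel logical; consecutive helices run in opposite
#'   directions (the spectrin-repeat topology).
#' @param risePerResidue helix rise per residue, Angstrom (informational).
#' @param residuesPerTurn alpha-helix periodicity (informational).
#' @return a validated list of class `bundleSpec`.
#' @export
bundleSpec <- function(helixLengths = c(16L, 18L, 16L), loopLengths = c(4L, 4L),
                       interHelixDistance = 10, antiparallel = TRUE,
                       risePerResidue = 1.5, residuesPerTurn = 3.6) {
  helixLengths <- as.integer(helixLengths)
  loopLengths <- as.integer(loopLengths)
  if (length(helixLengths) != 3L || any(helixLengths < 8L))
    stop("helixLengths must be three integers >= 8")
  if (length(loopLengths) != 2L || any(loopLengths < 2L))
    stop("loopLengths must be two integers >= 2")
  if (interHelixDistance <= 0) stop("interHelixDistance must be positive")
  structure(list(helixLengths = helixLengths, loopLengths = loopLengths,
                 interHelixDistance = interHelixDistance,
                 antiparallel = antiparallel, risePerResidue = risePerResidue,
                 residuesPerTurn = residuesPerTurn),
            class = "bundleSpec")
}

bundleSequence <- function(spec) {
  pat <- strsplit("LEAKQSVD", "")[[1L]]
  hseq <- function(n) rep_len(pat, n)
  lseq <- function(n) rep_len(c("G", "S"), n)
  c(hseq(spec$helixLengths[1L]), lseq(spec$loopLengths[1L]),
    hseq(spec$helixLengths[2L]), lseq(spec$loopLengths[2L]),
    hseq(spec$helixLengths[3L]))
}

# Quadratic Bezier sampled densely, then resampled at equal arc length.
bezierPath <- function(p0, p1, p2, nInterior, nDense = 600L) {
  tt <- seq(0, 1, length.out = nDense)
  B <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) + outer(tt^2, p2)
  seg <- sqrt(rowSums((B[-1L, , drop = FALSE] - B[-nDense, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[nDense]
  target <- total * seq_len(nInterior) / (nInterior + 1L)
  out <- matrix(NA_real_, nInterior, 3L)
  for (k in seq_len(nInterior)) {
    j <- findInterval(target[k], s, all.inside = TRUE)
    w <- (target[k] - s[j]) / max(s[j + 1L] - s[j], 1e-12)
    out[k, ] <- (1 - w) * B[j, ] + w * B[j + 1L, ]
  }
  list(points = out, length = total)
}

bezierLength <- function(p0, p1, p2, nDense = 600L) {
  tt <- seq(0, 1, length.out = nDense)
  B <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) + outer(tt^2, p2)
  sum(sqrt(rowSums((B[-1L, , drop = FALSE] - B[-nDense, , drop = FALSE])^2)))
}

# Approximate backbone atoms threaded through a fixed C-alpha path.
loopAtomsFromCA <- function(caPath, caPrev, caNext, bulgeDir, aa, firstResno, chain = "A") {
  n <- nrow(caPath)
  pts <- rbind(caPrev, caPath, caNext)
  N <- C <- O <- matrix(NA_real_, n, 3L)
  CB <- matrix(NA_real_, n, 3L)
  aN <- sqrt(1.46^2 - 0.85^2)   # along-chain offsets giving standard bonds
  aC <- sqrt(1.52^2 - 0.85^2)
  for (i in seq_len(n)) {
    ca <- pts[i + 1L, ]
    d1 <- unitv(ca - pts[i, ])
    d2 <- unitv(pts[i + 2L, ] - ca)
    mkPerp <- function(d) {
      p <- bulgeDir - sum(bulgeDir * d) * d
      if (vnorm(p) < 1e-6) {
        p <- c(1, 0, 0) - d[1L] * d
        if (vnorm(p) < 1e-6) p <- c(0, 1, 0) - d[2L] * d
      }
      unitv(p)
    }
    p1 <- mkPerp(d1)
    p2 <- mkPerp(d2)
    N[i, ] <- ca - aN * d1 + 0.85 * p1
    C[i, ] <- ca + aC * d2 + 0.85 * p2
    O[i, ] <- C[i, ] + 1.23 * unitv(cross3(d2, p2))
    if (aa[i] != "G") CB[i, ] <- ca - 1.53 * mkPerp(unitv(d1 + d2))
  }
  assembleAtoms(aa, N, caPath, C, O, CB, chain = chain, firstResno = firstResno)
}

#' Build an idealized antiparallel three-helix bundle
#'
#' Helices are constructed by internal-coordinate chain extension at ideal
#' alpha-helical torsions (phi = -57, psi = -47 degrees) and packed rigidly
#' on an equilateral triangle of side `interHelixDistance`, alternating
#' direction; loops follow an arc-length-matched path with approximate
#' backbone geometry so consecutive C-alpha spacing stays near 3.8 Angstrom
#' throughout. Side chains are truncated at C-beta (Gly has none).
#'
#' @param spec a [bundleSpec()].
#' @return an [SRStructure-class] whose `meta` records the segment label
#'   ("H1","L1","H2","L2","H3") of every residue and the helix axis frames.
#' @examples
#' s <- buildBundle(bundleSpec())
#' nResidues(s)  # 58 for the default spec
#' @export
buildBundle <- function(spec = bundleSpec()) {
  stopifnot(inherits(spec, "bundleSpec"))
  hl <- spec$helixLengths
  ll <- spec$loopLengths
  d <- spec$interHelixDistance
  aa <- bundleSequence(spec)
  segs <- rep(c("H1", "L1", "H2", "L2", "H3"), times = c(hl[1L], ll[1L], hl[2L], ll[2L], hl[3L]))

  centres <- list(c(0, 0, 0), c(d, 0, 0), c(d / 2, d * sqrt(3) / 2, 0))
  updown <- if (spec$antiparallel) c(1, -1, 1) else c(1, 1, 1)
  dirs <- lapply(updown, function(s) c(0, 0, s))

  offs <- c(0L, cumsum(c(hl[1L], ll[1L], hl[2L], ll[2L])))
  helixAA <- list(aa[seq_len(hl[1L])],
                  aa[offs[3L] + seq_len(hl[2L])],
                  aa[offs[5L] + seq_len(hl[3L])])
  helices <- lapply(1:3, function(k) {
    at <- buildChainAtoms(helixAA[[k]], -57, -47, chain = "A",
                          firstResno = 1L)
    alignHelix(at, dirs[[k]], centres[[k]])
  })

  bundleCentroid <- Reduce(`+`, centres) / 3

  for (attempt in 0:10) {
    scale <- 1 + 0.08 * attempt
    atoms <- helices[[1L]]
    ok <- TRUE
    for (li in 1:2) {
      prevH <- helices[[li]]
      nextH <- helices[[li + 1L]]
      caPrevAll <- atomMatrix(prevH, "CA")
      caNextAll <- atomMatrix(nextH, "CA")
      p0 <- caPrevAll[nrow(caPrevAll), ]
      p2 <- caNextAll[1L, ]
      nloop <- ll[li]
      need <- (nloop + 1L) * 3.8
      straight <- vnorm(p2 - p0)
      if (straight / (nloop + 1L) > 4.1) {
        stop(sprintf(
          "loop %d cannot span %.1f A with %d residues; increase loopLengths",
          li, straight, nloop))
      }
      need <- max(need, straight * 1.0001)
      mid <- (p0 + p2) / 2
      zsign <- sign(mid[3L])
      if (zsign == 0) zsign <- 1
      outward <- mid - bundleCentroid
      outward[3L] <- 0
      outward <- if (vnorm(outward) > 1e-6) unitv(outward) else c(1, 0, 0)
      bulgeDir <- unitv(c(0, 0, zsign) + 0.35 * outward)
      # bisect bulge height so the arc length matches (nloop+1)*3.8, scaled
      # up slightly on clash-retry attempts
      f <- function(h) bezierLength(p0, mid + h * bulgeDir, p2) - need * scale
      hi <- 1
      while (f(hi) < 0 && hi < 64) hi <- hi * 2
      h <- stats::uniroot(f, c(0, hi), tol = 1e-4)$root
      path <- bezierPath(p0, mid + h * bulgeDir, p2, nloop)
      aaLoop <- aa[offs[2L * li] + seq_len(nloop)]
      loopAt <- loopAtomsFromCA(path$points, p0, p2, bulgeDir, aaLoop, firstResno = 1L)
      atoms <- rbind(atoms, loopAt, nextH)
    }
    atoms <- renumberAtoms(atoms)
    ca <- atomMatrix(atoms, "CA")
    dmat <- as.matrix(stats::dist(ca))
    diag(dmat) <- Inf
    n <- nrow(ca)
    bonded <- abs(outer(seq_len(n), seq_len(n), "-")) <= 1L
    if (min(dmat[!bonded]) >= 3.0) { ok <- TRUE; break } else ok <- FALSE
  }
  if (!ok) stop("could not build a clash-free bundle after 10 retries")

  s <- new("SRStructure", atoms = atoms,
           title = sprintf("synthetic three-helix bundle (%d/%d/%d)", hl[1L], hl[2L], hl[3L]),
           meta = list(segments = segs, centres = centres, directions = dirs,
                       spec = spec))
  stopifnot(nResidues(s) == length(segs))
  s
}

# Reassign contiguous seqIndex/resno in current atom order (atoms are
# concatenated segment by segment; every residue's first atom is its N).
renumberAtoms <- function(atoms) {
  starts <- atoms$elety == "N"
  idx <- cumsum(starts) - 1L
  atoms$seqIndex <- idx
  atoms$resno <- idx + 1L
  atoms
}

#' Which face of the bundle does each residue point to?
#'
#' Uses the generator's metadata: for helix residues the radial direction of
#' the C-alpha from its helix axis is compared with the direction towards
#' the bundle centroid.
#'
#' @param s a structure built by [buildBundle()].
#' @return character vector per residue: "interface", "outward" or "loop".
#' @export
bundleFacing <- function(s) {
  stopifnot(is(s, "SRStructure"), !is.null(s@meta$segments))
  segs <- s@meta$segments
  centres <- s@meta$centres
  centroid <- Reduce(`+`, centres) / 3
  ca <- caCoords(s)
  out <- rep("loop", length(segs))
  for (k in 1:3) {
    hk <- paste0("H", k)
    sel <- which(segs == hk)
    ax <- centres[[k]]
    for (i in sel) {
      radial <- c(ca[i, 1L] - ax[1L], ca[i, 2L] - ax[2L])
      toCentre <- c(centroid[1L] - ax[1L], centroid[2L] - ax[2L])
      out[i] <- if (sum(radial * toCentre) > 0) "interface" else "outward"
    }
  }
  out
}

#' Plant a conserved surface cluster into a conservation grade table
#'
#' Emulates the grade structure the patch detector assumes: a cluster of
#' highly conserved (grade >= 7) residues on the solvent-exposed surface
#' within `radius` of a centre, over a variable background (grades 1..
#' `backgroundMax`). Only exposed residues are ever planted.
#'
#' @param s an [SRStructure-class].
#' @param sasa the structure's [SasaResult-class] (burial classes).
#' @param centre seqIndex of the cluster centre; must be exposed. `NULL`
#'   (default) picks the exposed residue with the most exposed neighbours
#'   within `radius` (ties: lowest seqIndex).
#' @param radius planting radius around the centre C-alpha, Angstrom.
#' @param plantedGrades grades sampled for planted residues (>= 7).
#' @param backgroundMax maximum background grade (<= 6).
#' @param seed RNG seed; same seed, same table.
#' @return named integer grade vector (names = seqIndex), plus attribute
#'   `planted` holding the planted seqIndex set.
#' @export
plantConservation <- function(s, sasa, centre = NULL, radius = 10,
                              plantedGrades = 7:9, backgroundMax = 6L,
                              seed = 1L) {
  stopifnot(is(s, "SRStructure"), is(sasa, "SasaResult"))
  if (any(plantedGrades < 7L)) stop("plantedGrades must be >= 7")
  if (backgroundMax > 6L) stop("backgroundMax must be <= 6")
  ca <- caCoords(s)
  si <- as.integer(rownames(ca))
  exposed <- si[sasa@burialClass[as.character(si)] == "exposed"]
  if (!length(exposed)) stop("structure has no exposed residues")
  if (is.null(centre)) {
    expCa <- ca[as.character(exposed), , drop = FALSE]
    dmat <- as.matrix(stats::dist(expCa))
    counts <- rowSums(dmat <= radius) - 1L
    centre <- exposed[which.max(counts)]
  }
  if (!(centre %in% exposed)) stop("planting centre must be an exposed residue")
  dc <- sqrt(rowSums(sweep(ca, 2L, ca[as.character(centre), ])^2))
  planted <- si[si %in% exposed & dc <= radius]
  if (!(centre %in% planted)) planted <- c(centre, planted)
  set.seed(seed)
  grades <- stats::setNames(
    sample(seq_len(backgroundMax), length(si), replace = TRUE), si)
  grades[as.character(planted)] <-
    sample(plantedGrades, length(planted), replace = TRUE)
  attr(grades, "planted") <- sort(planted)
  attr(grades, "centre") <- centre
  grades
}

#' Build a synthetic coordinate ensemble with planted collective modes
#'
#' Frames are the reference C-alpha coordinates plus sinusoidal excursions
#' along orthonormal 3N-modes plus isotropic Gaussian noise:
#' `frame_t = ref + sum_m amp_m * sin(2 pi t / nFrames + phase_m) * mode_m
#' + N(0, noiseSigma)` per coordinate. Phases are drawn from `seed`.
#'
#' @param s an [SRStructure-class] providing the reference C-alpha coordinates.
#' @param modes 3N x m matrix of orthonormal mode vectors (m = 0 allowed).
#' @param amplitudes excursion amplitudes, Angstrom (length m).
#' @param noiseSigma isotropic noise s.d. per coordinate, Angstrom.
#' @param nFrames number of frames (>= 2).
#' @param seed RNG seed.
#' @return an [SREnsemble-class].
#' @export
buildEnsemble <- function(s, modes = NULL, amplitudes = numeric(),
                          noiseSigma = 0.1, nFrames = 200L, seed = 1L) {
  stopifnot(is(s, "SRStructure"), nFrames >= 2L)
  ca <- caCoords(s)
  ref <- as.numeric(t(ca))
  n3 <- length(ref)
  if (is.null(modes)) modes <- matrix(numeric(), n3, 0L)
  if (ncol(modes) != length(amplitudes))
    stop("need one amplitude per mode")
  if (ncol(modes) > 0L) {
    if (nrow(modes) != n3) stop("modes must have 3N rows")
    g <- crossprod(modes)
    if (max(abs(g - diag(ncol(modes)))) > 1e-6)
      stop("modes must be pairwise orthonormal")
  }
  set.seed(seed)
  phases <- stats::runif(ncol(modes), 0, 2 * pi)
  tt <- seq_len(nFrames)
  xyz <- matrix(rep(ref, each = nFrames), nFrames, n3)
  for (m in seq_len(ncol(modes))) {
    amp <- amplitudes[m] * sin(2 * pi * tt / nFrames + phases[m])
    xyz <- xyz + outer(amp, modes[, m])
  }
  if (noiseSigma > 0)
    xyz <- xyz + matrix(stats::rnorm(nFrames * n3, 0, noiseSigma), nFrames, n3)
  new("SREnsemble", xyz = xyz, reference = ref,
      seqIndex = as.integer(rownames(ca)))
}

#' Write an ensemble as a multi-MODEL C-alpha PDB file
#'
#' @param e an [SREnsemble-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnsemblePDB <- function(e, path) {
  stopifnot(is(e, "SREnsemble"))
  n <- length(e@seqIndex)
  bio3d::write.pdb(pdb = NULL, file = path, xyz = e@xyz,
                   resno = e@seqIndex + 1L, resid = rep("ALA", n),
                   elety = rep("CA", n), chain = rep("A", n),
                   o = rep(1, n), b = rep(0, n), elesy = rep("C", n))
  invisible(path)
}

# Orthonormal basis of the 6 rigid-body modes (3 translations, 3
# infinitesimal rotations about the centroid) of a C-alpha coordinate set.
rigidBodyModes <- function(ca) {
  n <- nrow(ca)
  cc <- sweep(ca, 2L, colMeans(ca))
  M <- matrix(0, 3L * n, 6L)
  for (d in 1:3) M[seq(d, 3L * n, by = 3L), d] <- 1
  ax <- diag(3)
  for (d in 1:3) {
    v <- t(apply(cc, 1L, function(r) cross3(ax[d, ], r)))
    M[, 3L + d] <- as.numeric(t(v))
  }
  qr.Q(qr(M))
}

#' Random internal modes orthogonal to rigid-body motion
#'
#' Draws `m` random orthonormal 3N-vectors and projects out the six
#' rigid-body modes (translations and rotations), so ensembles planted
#' along them survive superposition unchanged. Use these to plant
#' collective modes whose recovery by [covariancePCA()] can be asserted
#' exactly.
#'
#' @param s an [SRStructure-class].
#' @param m number of modes.
#' @param seed RNG seed.
#' @return 3N x m matrix with orthonormal columns.
#' @export
randomInternalModes <- function(s, m = 1L, seed = 1L) {
  ca <- caCoords(s)
  n3 <- 3L * nrow(ca)
  if (m > n3 - 6L) stop("too many modes requested")
  R <- rigidBodyModes(ca)
  set.seed(seed)
  X <- matrix(stats::rnorm(n3 * m), n3, m)
  X <- X - R %*% crossprod(R, X)
  qr.Q(qr(X))[, seq_len(m), drop = FALSE]
}

#' Hinge-bending mode about a pivot residue
#'
#' Returns the normalized displacement field of a small rigid rotation of
#' every residue past `pivot` about an axis through the pivot C-alpha —
#' the bending of one spectrin repeat relative to the next about the
#' inter-repeat linker.
#'
#' @param s an [SRStructure-class].
#' @param pivot seqIndex of the hinge; must not be the first or last residue.
#' @return unit 3N-vector (N = number of C-alpha residues).
#' @export
makeHingeMode <- function(s, pivot) {
  ca <- caCoords(s)
  si <- as.integer(rownames(ca))
  if (!(pivot %in% si)) stop("pivot has no C-alpha")
  k <- match(pivot, si)
  if (k <= 1L || k >= nrow(ca)) stop("pivot must be interior, not a terminus")
  origin <- ca[k, ]
  armDir <- unitv(colMeans(ca[(k + 1L):nrow(ca), , drop = FALSE]) - origin)
  axis <- cross3(armDir, c(0, 0, 1))
  if (vnorm(axis) < 1e-6) axis <- cross3(armDir, c(1, 0, 0))
  axis <- unitv(axis)
  v <- matrix(0, nrow(ca), 3L)
  for (i in (k + 1L):nrow(ca)) v[i, ] <- cross3(axis, ca[i, ] - origin)
  vec <- as.numeric(t(v))
  if (vnorm(vec) < 1e-9) stop("degenerate hinge mode")
  vec / vnorm(vec)
}
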