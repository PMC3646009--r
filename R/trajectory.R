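#' Kabsch superposition of two coordinate sets
#'
#' Least-squares rigid superposition via SVD, constrained to a proper
#' rotation (determinant +1).
#'
#' @param mobile,ref n x 3 coordinate matrices, n >= 3, non-collinear.
#' @return list: `R` (3x3 rotation applied to centred mobile), `t`
#'   (translation such that `mobile %*% t(R)` + t superposes onto ref),
#'   `rmsd` (Angstrom), `coords` (the superposed mobile coordinates).
#' @export
kabschSuperpose <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (!all(dim(mobile) == dim(ref))) stop("coordinate sets differ in size")
  if (nrow(mobile) < 3L) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2L, cm); B <- sweep(ref, 2L, cr)
  if (min(svd(A)$d) < 1e-9 * max(svd(A)$d, 1))
    stop("degenerate (collinear) geometry")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  coords <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((coords - B)^2)))
  coords <- sweep(coords, 2L, cr, "+")
  list(R = R, t = cr - as.numeric(R %*% cm), rmsd = rmsd, coords = coords)
}

# Superpose every frame onto the iterated mean structure (two passes,
# C-alpha, mass-unweighted). Returns the ensemble with aligned frames.
superposeEnsemble <- function(e) {
  stopifnot(is(e, "SREnsemble"))
  xyz <- e@xyz
  n <- ncol(xyz) / 3L
  toMat <- function(v) matrix(v, n, 3L, byrow = TRUE)
  refc <- toMat(e@reference)
  for (pass in 1:2) {
    for (f in seq_len(nrow(xyz)))
      xyz[f, ] <- as.numeric(t(kabschSuperpose(toMat(xyz[f, ]), refc)$coords))
    refc <- toMat(colMeans(xyz))
  }
  methods::initialize(e, xyz = xyz, reference = as.numeric(t(refc)))
}

#' Root-mean-square fluctuation per residue
#'
#' Frames are first superposed onto the iterated mean structure (two
#' passes); RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2).
#'
#' @param e an [SREnsemble-class] (>= 2 frames).
#' @param superpose superpose frames first (default TRUE).
#' @return named numeric vector, Angstrom, by seqIndex.
#' @export
rmsf <- function(e, superpose = TRUE) {
  stopifnot(is(e, "SREnsemble"))
  if (nrow(e@xyz) < 2L) stop("RMSF needs at least 2 frames")
  if (superpose) e <- superposeEnsemble(e)
  dev <- sweep(e@xyz, 2L, colMeans(e@xyz))
  msd3 <- colMeans(dev^2)                   # per coordinate
  n <- ncol(e@xyz) / 3L
  out <- sqrt(msd3[3L * seq_len(n) - 2L] + msd3[3L * seq_len(n) - 1L] +
              msd3[3L * seq_len(n)])
  stats::setNames(out, e@seqIndex)
}

#' Essential-dynamics PCA of a C-alpha ensemble
#'
#' Eigen-decomposition of the 3N x 3N covariance matrix of superposed
#' C-alpha coordinates. Leading eigenvectors describe the dominant
#' collective motions; eigenvalues (Angstrom^2) are returned in descending
#' order. Rank-deficient covariances simply yield (near-)zero trailing
#' eigenvalues.
#'
#' @param e an [SREnsemble-class] with more than 3 frames.
#' @param superpose superpose frames first (default TRUE).
#' @return a [PCAResult-class].
#' @export
covariancePCA <- function(e, superpose = TRUE) {
  stopifnot(is(e, "SREnsemble"))
  if (nrow(e@xyz) <= 3L) stop("PCA needs more than 3 frames")
  if (superpose) e <- superposeEnsemble(e)
  C <- stats::cov(e@xyz)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  new("PCAResult", values = vals, vectors = eg$vectors,
      mean = colMeans(e@xyz), seqIndex = e@seqIndex)
}

#' Subspace overlap between two essential subspaces
#'
#' The average square projection of the first `k` eigenvectors of `a` onto
#' the first `k` of `b`: pair matrix P[i,j] = (a_i . b_j)^2 and
#' overlap = sum(P) / k. Equals 1 when the two k-subspaces coincide
#' (regardless of eigenvector order or sign) and ~k/3N for unrelated
#' random subspaces.
#'
#' @param a,b [PCAResult-class] objects of the same dimensionality.
#' @param k subspace size (default 10).
#' @return an [OverlapResult-class].
#' @export
subspaceOverlap <- function(a, b, k = 10L) {
  stopifnot(is(a, "PCAResult"), is(b, "PCAResult"))
  if (length(a@mean) != length(b@mean)) stop("dimension mismatch")
  k <- as.integer(k)
  if (k > ncol(a@vectors) || k > ncol(b@vectors))
    stop("k exceeds the number of available eigenvectors")
  A <- a@vectors[, seq_len(k), drop = FALSE]
  B <- b@vectors[, seq_len(k), drop = FALSE]
  P <- crossprod(A, B)^2
  dimnames(P) <- list(paste0("a", seq_len(k)), paste0("b", seq_len(k)))
  new("OverlapResult", pairMatrix = P,
      averageSquareProjection = min(sum(P) / k, 1),
      bestMatches = as.integer(apply(P, 1L, which.max)))
}

#' Correlated motions between residues
#'
#' Normalised covariance of C-alpha displacement vectors,
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>). Pairs with
#' |i - j| > 1 and |C_ij| above the threshold are reported (the absolute
#' value is used so anti-correlated pairs are included; the signed value
#' is retained in the output).
#'
#' @param e an [SREnsemble-class].
#' @param threshold correlation magnitude cutoff (default 0.8).
#' @param superpose superpose frames first (default TRUE).
#' @return data.frame: `i`, `j` (seqIndex, i < j), `correlation` (signed).
#' @export
correlatedMotions <- function(e, threshold = 0.8, superpose = TRUE) {
  stopifnot(is(e, "SREnsemble"))
  if (superpose) e <- superposeEnsemble(e)
  xyz <- sweep(e@xyz, 2L, colMeans(e@xyz))
  n <- ncol(xyz) / 3L
  # <dr_i . dr_j> for all pairs via blockwise crossprod
  F <- nrow(xyz)
  dots <- matrix(0, n, n)
  for (d in 1:3) {
    Xd <- xyz[, seq(d, 3L * n, by = 3L), drop = FALSE]
    dots <- dots + crossprod(Xd) / F
  }
  mag <- diag(dots)
  zero <- mag < 1e-12
  if (any(zero)) warning(sum(zero), " zero-variance residue(s) skipped")
  denom <- sqrt(outer(mag, mag))
  Cmat <- dots / denom
  Cmat[!is.finite(Cmat)] <- 0
  si <- e@seqIndex
  sep <- abs(outer(si, si, "-")) > 1L
  hit <- which(upper.tri(Cmat) & sep & abs(Cmat) > threshold & !outer(zero, zero, "|"),
               arr.ind = TRUE)
  data.frame(i = si[hit[, 1L]], j = si[hit[, 2L]],
             correlation = Cmat[hit])
}

#' Export a porcupine representation of one eigenvector
#'
#' Writes a two-MODEL C-alpha PDB file: MODEL 1 is the ensemble mean
#' structure, MODEL 2 is the mean displaced by `scale` times the selected
#' eigenvector, so each C-alpha pair defines the arrow of the motion along
#' that mode.
#'
#' @param p a [PCAResult-class].
#' @param mode eigenvector index (1-based).
#' @param scale displacement scale, Angstrom per unit component.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
porcupineExport <- function(p, mode = 1L, scale = 5, path) {
  stopifnot(is(p, "PCAResult"))
  if (mode < 1L || mode > ncol(p@vectors)) stop("mode out of range")
  disp <- p@mean + scale * p@vectors[, mode]
  xyz <- rbind(p@mean, disp)
  n <- length(p@seqIndex)
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = p@seqIndex + 1L, resid = rep("ALA", n),
                   elety = rep("CA", n), chain = rep("A", n),
                   o = rep(1, n), b = rep(0, n), elesy = rep("C", n))
  invisible(path)
}
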