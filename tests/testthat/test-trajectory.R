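test_that("Kabsch superposition recovers rigid motions exactly", {
  s <- fixtureBundle()
  ca <- caCoords(s)
  fit0 <- kabschSuperpose(ca, ca)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$R, diag(3), tolerance = 1e-9)

  R <- srpatch:::rotationAboutAxis(c(1, -2, 0.5), 77.7)
  moved <- sweep(ca %*% t(R), 2, c(4, -3, 12), "+")
  fit <- kabschSuperpose(moved, ca)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
})

test_that("superposition RMSD equals the independent quaternion oracle", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 2
  set.seed(55)
  for (k in 1:20) {
    mob <- tet
    mob[1, ] <- mob[1, ] + c(1, 0, 0)          # one vertex displaced by 1 A
    R <- srpatch:::rotationAboutAxis(rnorm(3), runif(1, 0, 360))
    mob <- sweep(mob %*% t(R), 2, rnorm(3, sd = 5), "+")
    expect_equal(kabschSuperpose(mob, tet)$rmsd, quaternionRmsd(mob, tet),
                 tolerance = 1e-9)
  }
  expect_error(kabschSuperpose(tet[1:2, ], tet[1:2, ]), "at least 3")
})

test_that("RMSF: zero for static ensembles, closed form for isotropic noise", {
  s <- fixtureBundle()
  ca <- caCoords(s)
  ref <- as.numeric(t(ca))
  static <- new("SREnsemble", xyz = rbind(ref, ref, ref), reference = ref,
                seqIndex = as.integer(rownames(ca)))
  expect_true(all(rmsf(static) < 1e-12))

  e <- buildEnsemble(s, noiseSigma = 0.5, nFrames = 2000L, seed = 8)
  r <- rmsf(e)
  expect_equal(mean(r), 0.5 * sqrt(3), tolerance = 0.05)

  # a single frame is not an ensemble
  expect_error(new("SREnsemble", xyz = matrix(ref, 1), reference = ref,
                   seqIndex = as.integer(rownames(ca))), "2 frames")
})

test_that("hinge-bending ensembles fluctuate most far from the pivot", {
  s <- fixtureBundle()
  hm <- makeHingeMode(s, 30L)
  n <- nResidues(s)
  expect_equal(sum(hm[1:(3 * 30)]^2), 0)        # residues before the pivot
  expect_equal(sqrt(sum(hm^2)), 1)
  e <- buildEnsemble(s, cbind(hm), amplitudes = 3, noiseSigma = 0.02,
                     nFrames = 400L, seed = 9)
  r <- rmsf(e)
  moving <- 32:n
  expect_gt(cor(moving, r[moving], method = "spearman"), 0.5)
  expect_gt(mean(r[40:n]), mean(r[1:25]))
  expect_error(makeHingeMode(s, 0L), "terminus")
})

test_that("PCA recovers a planted mode and conserves total variance", {
  s <- fixtureBundle()
  m <- randomInternalModes(s, 1L, seed = 3)
  e <- buildEnsemble(s, m, amplitudes = 3, noiseSigma = 0.05,
                     nFrames = 1000L, seed = 4)
  p <- covariancePCA(e)
  expect_gt(abs(sum(eigenVectors(p)[, 1] * m)), 0.99)
  expect_lt(eigenValues(p)[2] / eigenValues(p)[1], 0.01)

  sup <- srpatch:::superposeEnsemble(e)
  expect_equal(sum(eigenValues(p)), sum(apply(sup@xyz, 2, var)),
               tolerance = 1e-6)
})

test_that("isotropic noise gives a near-flat eigenvalue spectrum", {
  s <- fixtureBundle()
  e <- buildEnsemble(s, noiseSigma = 0.4, nFrames = 3000L, seed = 6)
  v <- eigenValues(covariancePCA(e))
  # superposition removes ~6 rigid degrees of freedom; compare within the
  # internal subspace
  v <- v[v > 1e-8]
  k <- length(v)
  expect_lt(v[1] / v[k - 6], 3)
})

test_that("subspace overlap: identity, orthogonal complement, permutation invariance", {
  s <- fixtureBundle()
  e <- buildEnsemble(s, noiseSigma = 0.3, nFrames = 300L, seed = 10)
  p <- covariancePCA(e)
  self <- subspaceOverlap(p, p, k = 10L)
  expect_equal(self@averageSquareProjection, 1, tolerance = 1e-12)

  q <- p
  q@vectors <- p@vectors[, c(11:20, 1:10)]     # orthogonal complement first
  expect_equal(subspaceOverlap(p, q, k = 10L)@averageSquareProjection, 0,
               tolerance = 1e-12)

  swap <- p
  swap@vectors[, 1:2] <- p@vectors[, 2:1]
  ov <- subspaceOverlap(p, swap, k = 10L)
  expect_equal(ov@averageSquareProjection, 1, tolerance = 1e-12)
  expect_equal(ov@pairMatrix[1, 1], 0, tolerance = 1e-12)
  expect_equal(ov@pairMatrix[1, 2], 1, tolerance = 1e-12)

  # symmetry
  e2 <- buildEnsemble(s, noiseSigma = 0.3, nFrames = 300L, seed = 12)
  p2 <- covariancePCA(e2)
  expect_equal(subspaceOverlap(p, p2)@averageSquareProjection,
               subspaceOverlap(p2, p)@averageSquareProjection,
               tolerance = 1e-12)
})

test_that("random independent k-subspaces overlap near k / 3N", {
  set.seed(123)
  n3 <- 300L; k <- 10L
  rnd <- function() qr.Q(qr(matrix(rnorm(n3 * k), n3, k)))
  mk <- function(Q) new("PCAResult", values = rep(1, k), vectors = Q,
                        mean = numeric(n3), seqIndex = seq_len(n3 / 3L) - 1L)
  ov <- replicate(20, subspaceOverlap(mk(rnd()), mk(rnd()), k = k)@averageSquareProjection)
  expect_lt(mean(ov), 3 * k / n3)
  expect_gt(mean(ov), k / n3 / 3)
})

test_that("correlated motions: perfect, anti-phase and null cases", {
  s <- fixtureBundle()
  ca <- caCoords(s)
  n <- nrow(ca)
  ref <- as.numeric(t(ca))
  set.seed(31)
  amp <- rnorm(500)
  xyz <- matrix(rep(ref, each = 500), 500, 3 * n)
  # residues 5 and 20 move with the same vector, residue 40 anti-phase
  for (i in c(5L, 20L)) xyz[, (3 * i - 2):(3 * i)] <-
    xyz[, (3 * i - 2):(3 * i)] + outer(amp, c(1, 0.5, -0.2))
  xyz[, (3 * 40 - 2):(3 * 40)] <- xyz[, (3 * 40 - 2):(3 * 40)] - outer(amp, c(1, 0.5, -0.2))
  xyz <- xyz + matrix(rnorm(length(xyz), sd = 1e-3), nrow(xyz))
  e <- new("SREnsemble", xyz = xyz, reference = ref,
           seqIndex = as.integer(rownames(ca)))
  cm <- correlatedMotions(e, threshold = 0.8, superpose = FALSE)
  key <- paste(cm$i, cm$j)
  expect_true(paste(4, 19) %in% key)           # seqIndex = row - 1
  expect_true(paste(4, 39) %in% key)
  expect_lt(cm$correlation[key == paste(4, 39)], -0.9)

  eNull <- buildEnsemble(s, noiseSigma = 0.3, nFrames = 2000L, seed = 14)
  cmNull <- correlatedMotions(eNull, threshold = 0.8, superpose = FALSE)
  expect_equal(nrow(cmNull), 0L)
})

test_that("porcupine export writes mean + displaced MODELs that round-trip", {
  s <- fixtureBundle()
  m <- randomInternalModes(s, 1L, seed = 17)
  e <- buildEnsemble(s, m, amplitudes = 2, noiseSigma = 0.05,
                     nFrames = 300L, seed = 18)
  p <- covariancePCA(e)
  f <- withr::local_tempfile(fileext = ".pdb")
  porcupineExport(p, mode = 1L, scale = 5, path = f)
  frames <- readPDB(f, modelPolicy = "all")
  expect_length(frames, 2L)
  c1 <- caCoords(frames[[1]]); c2 <- caCoords(frames[[2]])
  disp <- as.numeric(t(c2 - c1))
  v <- p@vectors[, 1]
  expect_gt(abs(sum(disp * v)) / sqrt(sum(disp^2)), 0.999)
  expect_equal(disp, 5 * v, tolerance = 0.02)  # PDB 3-decimal precision

  # zero-vector mode: both MODELs identical
  p0 <- p
  p0@vectors <- cbind(p@vectors[, 1] * 0)
  p0@values <- 0
  expect_error(porcupineExport(p0, mode = 2L, scale = 5, path = f), "out of range")
})

test_that("RMSF and PCA are invariant under a global rigid motion of all frames", {
  s <- fixtureBundle()
  m <- randomInternalModes(s, 2L, seed = 19)
  e <- buildEnsemble(s, m, amplitudes = c(2, 1), noiseSigma = 0.1,
                     nFrames = 400L, seed = 20)
  R <- srpatch:::rotationAboutAxis(c(0.3, 1, -0.7), 33.3)
  xyz2 <- t(apply(e@xyz, 1, function(fr) {
    mat <- matrix(fr, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(mat %*% t(R), 2, c(5, 6, 7), "+")))
  }))
  e2 <- new("SREnsemble", xyz = xyz2, reference = e@reference,
            seqIndex = e@seqIndex)
  expect_equal(rmsf(e2), rmsf(e), tolerance = 1e-6)
  expect_equal(eigenValues(covariancePCA(e2)), eigenValues(covariancePCA(e)),
               tolerance = 1e-6)
})

test_that("PCA and RMSF agree with bio3d on the same superposed frames", {
  s <- fixtureBundle()
  m <- randomInternalModes(s, 2L, seed = 23)
  e <- buildEnsemble(s, m, amplitudes = c(2, 1), noiseSigma = 0.1,
                     nFrames = 300L, seed = 24)
  sup <- srpatch:::superposeEnsemble(e)
  bp <- bio3d::pca.xyz(sup@xyz)
  p <- covariancePCA(e)
  expect_equal(eigenValues(p)[1:10], bp$L[1:10], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_gt(abs(sum(eigenVectors(p)[, 1] * bp$U[, 1])), 0.9999)
  br <- bio3d::rmsf(sup@xyz)   # bio3d uses the n-1 denominator
  nf <- nFrames(e)
  expect_equal(unname(rmsf(e)) * sqrt(nf / (nf - 1)), br,
               tolerance = 1e-6, ignore_attr = TRUE)
})
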