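# Shared fixtures, computed lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixtureBundle <- function() {
  if (is.null(.fixtures$bundle)) .fixtures$bundle <- buildBundle(bundleSpec())
  .fixtures$bundle
}

# 240-point SASA is used wherever the quadrature resolution is not itself
# under test; classifications are stable well below this resolution.
fixtureSasa <- function() {
  if (is.null(.fixtures$sasa))
    .fixtures$sasa <- computeSasa(fixtureBundle(), sasaParams(nSpherePoints = 240L))
  .fixtures$sasa
}

# A bare structure from explicit C-alpha positions (one atom per residue).
caOnlyStructure <- function(coords) {
  n <- nrow(coords)
  atoms <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                      resid = "ALA", elety = "CA", element = "C",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      o = 1, seqIndex = seq_len(n) - 1L,
                      stringsAsFactors = FALSE)
  new("SRStructure", atoms = atoms, title = "ca-only")
}

# Independent O(n^2) recount of the pbs rule, straight from its definition.
bruteForcePbs <- function(ca, conserved, exposed, radius = 10, minNeighbours = 5L) {
  n <- nrow(ca)
  centres <- integer(0)
  counts <- integer(0)
  for (i in seq_len(n)) {
    if (!(conserved[i] && exposed[i])) next
    cnt <- 0L
    for (j in seq_len(n)) {
      if (j == i || abs(i - j) <= 1L) next
      if (!(conserved[j] && exposed[j])) next
      if (sqrt(sum((ca[i, ] - ca[j, ])^2)) <= radius) cnt <- cnt + 1L
    }
    counts <- c(counts, stats::setNames(cnt, i - 1L))
    if (cnt > minNeighbours) centres <- c(centres, i - 1L)
  }
  list(centres = centres, counts = counts)
}

# Horn quaternion method for optimal superposition RMSD: an independent
# route to the quantity kabschSuperpose() computes by SVD.
quaternionRmsd <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  M <- crossprod(A, B)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lmax) / nrow(A)
  sqrt(max(msd, 0))
}
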