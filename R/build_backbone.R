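# Internal-coordinate backbone construction (NeRF chain extension).
# Bond lengths/angles are standard peptide values; side chains are truncated
# at C-beta (absent for Gly) so that SASA numerator and denominator use the
# same reduced representation.

BB <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_CACB = 1.530,
  a_NCAC = 111.0, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.5,
  a_CCACB = 110.1, t_NCCACB = -122.6)

#' Build a chain from per-residue (phi, psi) torsions
#'
#' @param aa character vector of one-letter codes.
#' @param phi,psi torsions in degrees, recycled to length(aa).
#' @param omega peptide torsion, degrees.
#' @param chain chain identifier.
#' @param firstResno author number of the first residue.
#' @return atoms data.frame in SRStructure layout.
#' @noRd
buildChainAtoms <- function(aa, phi, psi, omega = 180, chain = "A", firstResno = 1L) {
  n <- length(aa)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  CB <- matrix(NA_real_, n, 3L)

  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(BB$b_NCA, 0, 0)
  th <- deg2rad(180 - BB$a_NCAC)
  C[1L, ] <- CA[1L, ] + BB$b_CAC * c(cos(th), sin(th), 0)

  for (i in seq_len(n)) {
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], BB$b_CO, BB$a_CACO, psi[i] + 180)
    if (aa[i] != "G")
      CB[i, ] <- placeAtom(N[i, ], C[i, ], CA[i, ], BB$b_CACB, BB$a_CCACB, BB$t_NCCACB)
    if (i < n) {
      N[i + 1L, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], BB$b_CN, BB$a_CACN, psi[i])
      CA[i + 1L, ] <- placeAtom(CA[i, ], C[i, ], N[i + 1L, ], BB$b_NCA, BB$a_CNCA, omega)
      C[i + 1L, ] <- placeAtom(C[i, ], N[i + 1L, ], CA[i + 1L, ], BB$b_CAC, BB$a_NCAC, phi[i + 1L])
    }
  }
  assembleAtoms(aa, N, CA, C, O, CB, chain = chain, firstResno = firstResno)
}

assembleAtoms <- function(aa, N, CA, C, O, CB, chain = "A", firstResno = 1L) {
  n <- length(aa)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    names_i <- c("N", "CA", "C", "O")
    elem_i <- c("N", "C", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (!any(is.na(CB[i, ]))) {
      names_i <- c(names_i, "CB")
      elem_i <- c(elem_i, "C")
      xyz <- rbind(xyz, CB[i, ])
    }
    rows[[i]] <- data.frame(
      chain = chain, resno = firstResno + i - 1L, insert = "",
      resid = aaOneToThree(aa[i]), elety = names_i, element = elem_i,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1,
      seqIndex = i - 1L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Extract an n x 3 coordinate matrix of one atom type per residue, NA rows
# where missing.
atomMatrix <- function(atoms, elety) {
  n <- max(atoms$seqIndex) + 1L
  m <- matrix(NA_real_, n, 3L)
  sel <- atoms$elety == elety
  m[atoms$seqIndex[sel] + 1L, ] <- as.matrix(atoms[sel, c("x", "y", "z")])
  m
}

# Rigidly transform all atom coordinates: x -> R x + t.
transformAtoms <- function(atoms, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1L] + t[1L]
  atoms$y <- xyz[, 2L] + t[2L]
  atoms$z <- xyz[, 3L] + t[3L]
  atoms
}

# Align a helix's principal axis with `direction`, centre its CAs at `centre`.
alignHelix <- function(atoms, direction, centre) {
  ca <- atomMatrix(atoms, "CA")
  mid <- colMeans(ca)
  cc <- sweep(ca, 2L, mid)
  ax <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1L]
  if (sum(ax * (ca[nrow(ca), ] - ca[1L, ])) < 0) ax <- -ax
  R <- rotationBetween(ax, direction)
  atoms <- transformAtoms(atoms, R, -as.numeric(R %*% mid))
  transformAtoms(atoms, diag(3), centre)
}
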