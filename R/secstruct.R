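# Kabsch-Sander secondary-structure assignment.
#
# Hydrogen bonds are detected with the electrostatic model
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol,
# bond iff E < -0.5, with the amide H reconstructed 1.0 A from N opposing
# the preceding peptide's C=O direction (inputs lack hydrogens). n-turn
# patterns (i -> i+3/4/5) then yield G/H/I stretches with the canonical
# precedence H > G > I; a minimal two-bridge ladder rule yields E.

KS_Q <- 0.084 * 332   # kcal/mol * Angstrom
KS_HBOND_CUTOFF <- -0.5

# Backbone geometry of one chain: N/CA/C/O matrices plus reconstructed H.
backboneFrames <- function(s, chain = NULL) {
  a <- s@atoms
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  n <- max(a$seqIndex) + 1L
  N <- atomMatrix(a, "N"); CA <- atomMatrix(a, "CA")
  C <- atomMatrix(a, "C"); O <- atomMatrix(a, "O")
  H <- matrix(NA_real_, n, 3L)
  aa <- rep("X", n)
  rt <- a[!duplicated(a$seqIndex), c("seqIndex", "resid")]
  aa[rt$seqIndex + 1L] <- aaThreeToOne(rt$resid)
  for (i in 2:n) {
    if (aa[i] == "P") next  # proline has no amide H
    if (any(is.na(N[i, ])) || any(is.na(C[i - 1L, ])) || any(is.na(O[i - 1L, ]))) next
    d <- C[i - 1L, ] - O[i - 1L, ]
    if (vnorm(d) < 1e-6) next
    H[i, ] <- N[i, ] + unitv(d)
  }
  list(N = N, CA = CA, C = C, O = O, H = H, aa = aa, n = n)
}

#' Kabsch-Sander hydrogen-bond energy between two residues
#'
#' Energy of the putative hydrogen bond donated by the backbone NH of
#' `donor` to the backbone CO of `acceptor`. A bond is present when the
#' energy is below -0.5 kcal/mol. Pairs with |donor - acceptor| <= 1 are
#' excluded from bonding by rule, and residues with missing backbone atoms
#' (or a donor with no reconstructable H) give `NA`.
#'
#' @param s an [SRStructure-class].
#' @param donor,acceptor seqIndex values (0-based) on the first chain.
#' @param chain chain identifier (default: first chain).
#' @return energy in kcal/mol, or `NA` if not evaluable.
#' @export
hbondEnergy <- function(s, donor, acceptor, chain = NULL) {
  bb <- backboneFrames(s, chain)
  ksEnergy(bb, donor + 1L, acceptor + 1L)
}

ksEnergy <- function(bb, di, ai) {
  if (di < 1L || di > bb$n || ai < 1L || ai > bb$n) stop("residue index out of range")
  N <- bb$N[di, ]; H <- bb$H[di, ]
  C <- bb$C[ai, ]; O <- bb$O[ai, ]
  if (any(is.na(c(N, H, C, O)))) return(NA_real_)
  rON <- vnorm(O - N); rCH <- vnorm(C - H)
  rOH <- vnorm(O - H); rCN <- vnorm(C - N)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(Inf)  # clashing geometry, no bond
  KS_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# Logical hbond[d, a]: NH of d donates to CO of a.
hbondMatrix <- function(bb) {
  n <- bb$n
  hb <- matrix(FALSE, n, n)
  ok <- !apply(is.na(bb$CA), 1L, any)
  cad <- as.matrix(stats::dist(bb$CA))
  for (d in seq_len(n)) {
    if (!ok[d] || any(is.na(bb$H[d, ]))) next
    cand <- which(ok & cad[d, ] < 9 & abs(seq_len(n) - d) > 1L)
    for (a in cand) {
      e <- ksEnergy(bb, d, a)
      if (!is.na(e) && e < KS_HBOND_CUTOFF) hb[d, a] <- TRUE
    }
  }
  hb
}

#' Assign secondary structure to a chain
#'
#' @param s an [SRStructure-class].
#' @param chain chain identifier (default: first chain).
#' @param helixClasses labels counted as helical for the summary fraction.
#' @return an [SSAssignment-class] with labels H/G/I/E/T/C per residue.
#' @examples
#' helix <- buildBundle(bundleSpec())   # three-helix bundle
#' ss <- assignSS(helix)
#' helicalContent(ss)
#' @export
assignSS <- function(s, chain = NULL, helixClasses = c("H", "G", "I")) {
  stopifnot(is(s, "SRStructure"))
  bb <- backboneFrames(s, chain)
  n <- bb$n
  labels <- rep("C", n)
  if (n < 5L) {
    warning("chain shorter than 5 residues; all residues assigned coil")
  } else {
    hb <- hbondMatrix(bb)
    # turn_k[i] : hbond from NH(i+k) to CO(i)
    turn <- list()
    for (k in 3:5) {
      tk <- rep(FALSE, n)
      idx <- seq_len(n - k)
      tk[idx] <- hb[cbind(idx + k, idx)]
      turn[[as.character(k)]] <- tk
    }
    mark <- function(labels, k, lab) {
      tk <- turn[[as.character(k)]]
      for (i in 2:(n - k)) {
        if (tk[i - 1L] && tk[i]) {
          span <- i:(i + k - 1L)
          if (lab == "H" || all(labels[span] %in% c("C", "T")))
            labels[span] <- lab
        }
      }
      labels
    }
    labels <- mark(labels, 4L, "H")
    labels <- mark(labels, 3L, "G")
    labels <- mark(labels, 5L, "I")
    # minimal beta-bridge/ladder rule (SR structures are helical; sheet
    # accuracy is not a contract)
    bridge <- matrix(FALSE, n, n)
    for (i in 2:(n - 1L)) {
      for (j in 2:(n - 1L)) {
        if (abs(i - j) <= 2L) next
        parallel <- (hb[j, i - 1L] && hb[i + 1L, j]) || (hb[i, j - 1L] && hb[j + 1L, i])
        anti <- (hb[i, j] && hb[j, i]) || (hb[j + 1L, i - 1L] && hb[i + 1L, j - 1L])
        if (parallel || anti) bridge[i, j] <- TRUE
      }
    }
    inBridge <- rowSums(bridge) > 0L
    ladder <- inBridge & (c(FALSE, inBridge[-n]) | c(inBridge[-1L], FALSE))
    labels[ladder & labels == "C"] <- "E"
    # turns not already in a helix
    for (k in 3:5) {
      tk <- turn[[as.character(k)]]
      for (i in which(tk)) {
        span <- (i + 1L):(i + k - 1L)
        span <- span[span <= n]
        labels[span][labels[span] == "C"] <- "T"
      }
    }
  }
  names(labels) <- seq_len(n) - 1L
  new("SSAssignment", labels = labels,
      helicalContent = helicalContentFromLabels(labels, helixClasses))
}

helicalContentFromLabels <- function(labels, classes = c("H", "G", "I")) {
  if (!length(labels)) stop("empty secondary-structure assignment")
  mean(labels %in% classes)
}

#' Write a secondary-structure assignment as TSV
#'
#' @param ss an [SSAssignment-class].
#' @param path output path (columns seq_index, label).
#' @return `path`, invisibly.
#' @export
writeSSTSV <- function(ss, path) {
  utils::write.table(
    data.frame(seq_index = as.integer(names(ss@labels)), label = ss@labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
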