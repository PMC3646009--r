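# Internal 3-D geometry helpers shared by the builders and the trajectory code.

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Place an atom from internal coordinates (NeRF).
#'
#' Given positions of three previously placed atoms A, B, C, returns the
#' position D with bond length |C-D|, bond angle B-C-D and torsion A-B-C-D.
#'
#' @param a,b,c numeric 3-vectors, Angstrom.
#' @param bond bond length C-D, Angstrom.
#' @param angle bond angle B-C-D, degrees.
#' @param torsion dihedral A-B-C-D, degrees.
#' @return numeric 3-vector.
#' @noRd
placeAtom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  d_local <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(c + rot %*% d_local)
}

# Rotation matrix sending unit vector `from` onto unit vector `to`
# (Rodrigues); identity when already aligned, a 180-degree flip about any
# perpendicular axis when anti-aligned.
rotationBetween <- function(from, to) {
  f <- unitv(from)
  t <- unitv(to)
  v <- cross3(f, t)
  s <- vnorm(v)
  c_ <- sum(f * t)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # pick any axis perpendicular to f
    ax <- if (abs(f[1L]) < 0.9) unitv(cross3(f, c(1, 0, 0))) else unitv(cross3(f, c(0, 1, 0)))
    K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L], ax[2L], -ax[1L], 0), 3L, 3L)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# Rotation by `angle` degrees about unit axis `ax` (Rodrigues).
rotationAboutAxis <- function(ax, angle) {
  ax <- unitv(ax)
  th <- deg2rad(angle)
  K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L], ax[2L], -ax[1L], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Deterministic generalized-spiral (Fibonacci) point set on the unit sphere.
fibonacciSphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
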