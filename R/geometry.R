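# Basic vector geometry: distances, angles, dihedrals and their Cartesian
# gradients. Gradients are needed analytically by the torsion-grid and base
# force-field terms.

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product for n x 3 matrices
.crossm <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(m) sqrt(rowSums(m * m))

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle p1-p2-p3-p4 with the IUPAC sign convention:
#' looking down the p2->p3 axis, a clockwise rotation from the p1 side to the
#' p4 side is positive. The result lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @examples
#' dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   # 0 (cis)
#' dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1 * b1) == 0 || sum(b2 * b2) == 0 || sum(b3 * b3) == 0)
    stop("consecutive points coincide; dihedral undefined")
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  if (sum(n1 * n1) < 1e-20 || sum(n2 * n2) < 1e-20)
    stop("collinear points; dihedral undefined")
  m1 <- .cross(n1, b2 / sqrt(sum(b2 * b2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Vectorized dihedrals: p1..p4 are n x 3 matrices; returns degrees in
# (-180, 180]. NA for degenerate rows rather than an error (callers skip).
.dihedrals <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .crossm(b1, b2); n2 <- .crossm(b2, b3)
  b2n <- b2 / .rownorm(b2)
  m1 <- .crossm(n1, b2n)
  ang <- -atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  bad <- .rownorm(n1) < 1e-10 | .rownorm(n2) < 1e-10
  ang[bad] <- NA_real_
  ang[!is.na(ang) & ang <= -180] <- ang[!is.na(ang) & ang <= -180] + 360
  ang
}

# Gradient of the dihedral (in radians) with respect to the four atom
# positions. Returns a list of four n x 3 matrices for n dihedrals given as
# n x 3 point matrices. Standard result: with b1 = p2-p1, b2 = p3-p2,
# b3 = p4-p3, n1 = b1 x b2, n2 = b2 x b3,
#   dphi/dp1 = -|b2|/|n1|^2 n1,  dphi/dp4 = |b2|/|n2|^2 n2,
# and the inner atoms follow from translation/rotation invariance.
.dihedral_grad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .crossm(b1, b2); n2 <- .crossm(b2, b3)
  b2l <- .rownorm(b2)
  g1 <- -n1 * (b2l / rowSums(n1 * n1))
  g4 <- n2 * (b2l / rowSums(n2 * n2))
  c12 <- rowSums(b1 * b2) / (b2l * b2l)
  c32 <- rowSums(b3 * b2) / (b2l * b2l)
  g2 <- -g1 * (1 + c12) + g4 * c32
  g3 <- -g4 * (1 + c32) + g1 * c12
  list(g1, g2, g3, g4)
}

# Gradient of the angle i-j-k (radians, apex j) wrt the three positions.
# n x 3 matrices in, list of three n x 3 matrices out.
.angle_grad <- function(pi_, pj, pk) {
  u <- pi_ - pj; v <- pk - pj
  lu <- .rownorm(u); lv <- .rownorm(v)
  uh <- u / lu; vh <- v / lv
  ct <- pmin(1, pmax(-1, rowSums(uh * vh)))
  st <- sqrt(pmax(1e-12, 1 - ct * ct))
  gi <- (uh * ct - vh) / (lu * st)
  gk <- (vh * ct - uh) / (lv * st)
  list(gi, -(gi + gk), gk)
}

.angles <- function(pi_, pj, pk) {
  u <- pi_ - pj; v <- pk - pj
  ct <- rowSums(u * v) / (.rownorm(u) * .rownorm(v))
  acos(pmin(1, pmax(-1, ct)))
}

# all pairwise distances between two coordinate sets (na x nb)
.cdist <- function(a, b) {
  a2 <- rowSums(a * a); b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
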