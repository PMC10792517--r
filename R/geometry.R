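# Low-level 3D geometry: dihedrals, internal-coordinate atom placement,
# and least-squares rigid superposition.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle for the atom path a-b-c-d, using the IUPAC sign
#' convention (cis = 0, angles in (-180, 180]).
#'
#' @param a,b,c,d Numeric 3-vectors (Angstroms).
#' @return Angle in degrees, or `NA` when the geometry is degenerate
#'   (collinear consecutive atoms).
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) return(NA_real_)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# NeRF: place atom D given reference atoms A, B, C, bond length |C-D|,
# bond angle B-C-D (deg) and torsion A-B-C-D (deg).
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- deg2rad(angle)
  ta <- deg2rad(torsion)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(th), sin(th) * cos(ta), -sin(th) * sin(ta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Smallest circular difference between two angles in degrees, in [0, 180].
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Rotation matrix about a (unit) axis by angle degrees (Rodrigues).
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping point set `b` onto point
#' set `a`, reflection-free, with optional weights.
#'
#' @param a,b n x 3 matrices of corresponding points (rows are pairs).
#' @param weights Optional non-negative weights of length n.
#' @return Object of class `mc_superposition`: list with `rotation` (3x3),
#'   `translation` (3-vector), `rmsd` (unweighted RMSD over the fitted
#'   pairs after transformation) and `fitted_pairs` (row indices used).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' s <- kabsch(a, a)
#' s$rmsd  # 0
#' @export
kabsch <- function(a, b, weights = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b))
  n <- nrow(a)
  if (n < 3) stop("kabsch needs at least 3 point pairs")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)
  ca <- colSums(a * w)
  cb <- colSums(b * w)
  aa <- sweep(a, 2, ca)
  bb <- sweep(b, 2, cb)
  h <- t(bb * w) %*% aa
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (abs(det(h)) < 1e-12 && qr(aa, tol = 1e-9)$rank < 2) {
    stop("degenerate geometry: points are collinear")
  }
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ca - as.numeric(rot %*% cb)
  bt <- t(rot %*% t(b)) + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((bt - a)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 fitted_pairs = seq_len(n)),
            class = "mc_superposition")
}

# Apply an mc_superposition (or rotation/translation) to an n x 3 matrix.
apply_superposition <- function(sup, xyz) {
  xyz <- as.matrix(xyz)
  t(sup$rotation %*% t(xyz)) + matrix(sup$translation, nrow(xyz), 3, byrow = TRUE)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

# Evenly distributed unit sphere points (golden-spiral); deterministic.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
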