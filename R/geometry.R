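# Internal 3D geometry helpers shared by the mutant builder, the toy-complex
# generator and the feature code. All coordinates are in Angstrom.

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_unit <- function(v) v / sqrt(sum(v^2))

#' @noRd
#' Place atom D from three reference atoms using internal coordinates
#' (NeRF construction): |c-d| = bond, angle(b,c,d) = angle_deg, and
#' torsion(a,b,c,d) = dihedral_deg.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- -dihedral_deg * pi / 180  # sign so that torsion_angle(a,b,c,d) == dihedral_deg
  bc <- vec_unit(c - b)
  n <- vec_unit(vec_cross(b - a, bc))
  m <- vec_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

# Torsion angle a-b-c-d in degrees, matching place_atom's convention.
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vec_cross(b1, b2); n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, vec_unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Least-squares rigid transform (rotation + translation) mapping the rows of
# `from` onto the rows of `to` (Kabsch). Returns a function on n x 3 matrices.
rigid_transform <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  h <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  function(x) sweep(sweep(x, 2, cf) %*% t(rot), 2, ct, `+`)
}

# All pairwise Euclidean distances between the rows of two n x 3 matrices.
cross_dist <- function(xa, xb) {
  sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb), 0))
}

coords_matrix <- function(df) cbind(df$x, df$y, df$z)

# Deterministic, approximately uniform points on the unit sphere
# (golden-spiral lattice); used by the SASA engine.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

random_rotation <- function() {
  # QR of a Gaussian matrix; determinant fixed to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
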