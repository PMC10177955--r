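# Cartesian geometry primitives shared by internal-coordinate evaluation
# and the synthetic trajectory builder.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

.GEOM_EPS <- 1e-10

#' Bond angle at a vertex
#'
#' Angle i-j-k in degrees at vertex `p_j`, computed as the arc cosine of
#' the normalized dot product of the two arms, with the cosine clamped to
#' \[-1, 1\] so collinear arms return exactly 0 or 180 despite rounding.
#'
#' @param p_i,p_j,p_k Cartesian triples (Angstrom); `p_j` is the vertex.
#' @return angle in degrees, in \[0, 180\].
#' @export
bond_angle <- function(p_i, p_j, p_k) {
  u <- p_i - p_j
  v <- p_k - p_j
  nu <- vnorm(u)
  nv <- vnorm(v)
  if (nu < .GEOM_EPS || nv < .GEOM_EPS)
    stopf("degenerate geometry: zero-length arm at angle vertex")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

#' Signed dihedral (torsion) angle
#'
#' Torsion a-b-c-d about the b-c axis via the atan2 cross-product
#' construction.  Positive sense: looking from `b` toward `c`, the far
#' bond c-d rotated counterclockwise relative to the near bond b-a.
#'
#' @param p_a,p_b,p_c,p_d Cartesian triples (Angstrom).
#' @return signed angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p_a, p_b, p_c, p_d) {
  b1 <- p_b - p_a
  b2 <- p_c - p_b
  b3 <- p_d - p_c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < .GEOM_EPS || vnorm(n2) < .GEOM_EPS)
    stopf("degenerate geometry: collinear atoms in dihedral backbone")
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# NeRF-style placement: return the position D with |D - p| = r,
# angle(D, p, q) = theta (degrees) and dihedral(D, p, q, s) = phi
# (degrees).  p is the bonded reference, q its angle reference, s the
# dihedral reference.
place_nerf <- function(p, q, s, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  e1 <- q - p
  ne1 <- vnorm(e1)
  if (ne1 < .GEOM_EPS) stopf("degenerate placement: coincident references")
  e1 <- e1 / ne1
  n <- cross3(s - q, e1)
  nn <- vnorm(n)
  if (nn < .GEOM_EPS) stopf("degenerate placement: collinear references")
  n <- n / nn
  e2 <- cross3(n, e1)
  # D - p has angle theta to e1; azimuth phi measured so that
  # dihedral(D, p, q, s) == phi (verified by round-trip construction).
  p + r * (cos(th) * e1 - sin(th) * (cos(ph) * e2 + sin(ph) * n))
}

# Kabsch superposition: rotate/translate the rows of `mob` (n x 3) onto
# `ref` (n x 3) with a proper rotation minimizing RMSD.
kabsch_align <- function(mob, ref) {
  cm <- colMeans(mob)
  cr <- colMeans(ref)
  A <- sweep(mob, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A %*% t(R), 2, cr, `+`)
}
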