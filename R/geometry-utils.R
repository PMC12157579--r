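# Low-level vector geometry shared by the builder, the torsion code and the
# validation stage.  All angles are in degrees; positions are 3-vectors in
# Angstroms.  These are internal helpers and operate on plain numeric
# vectors/matrices for speed.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle at `b` formed by points `a`-`b`-`c`, in degrees.
#' @noRd
vec_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u)
  nv <- vnorm(v)
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * .rad2deg
}

#' Signed dihedral a-b-c-d in (-180, 180], degrees.  Returns NA for
#' degenerate (collinear) quadruples.
#' @noRd
vec_dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * .rad2deg
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Natural-extension (NeRF) placement: position of atom D bonded to C, given
#' the three previously placed atoms A-B-C, the C-D bond length, the B-C-D
#' bond angle and the A-B-C-D torsion.
#' @noRd
nerf_place <- function(a, b, c, length, angle, torsion) {
  ang <- angle * .deg2rad
  tor <- torsion * .deg2rad
  # local displacement in the frame where C is origin, -BC is x
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          -length * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  nn <- vnorm(n)
  if (nn < 1e-12) {
    # collinear support frame: pick any perpendicular
    ref <- if (abs(bc[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- vcross(ref, bc)
    nn <- vnorm(n)
  }
  n <- n / nn
  m <- vcross(n, bc)
  rot <- cbind(bc, m, n)
  c(rot %*% d2) + c
}
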