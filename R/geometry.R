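# Internal geometry helpers: vectors are length-3 numerics, coordinates in A,
# angles in degrees unless noted.

.deg2rad <- pi / 180
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
.norm <- function(v) sqrt(sum(v * v))
.unit <- function(v) {
  n <- .norm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

# torsion angle p1-p2-p3-p4, IUPAC sign convention, in (-180, 180]
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  if (.norm(n1) < 1e-9 || .norm(n2) < 1e-9)
    stop("undefined dihedral: collinear atoms")
  m1 <- .cross(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) / .deg2rad
  if (ang <= -180) ang <- ang + 360
  ang
}

# bond angle at b (degrees)
.bond_angle <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) / .deg2rad
}

# NeRF placement: position D given A-B-C, bond |C-D|, angle B-C-D, torsion
# A-B-C-D (degrees)
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * .deg2rad
  ph <- torsion * .deg2rad
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph),
          -bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# rotation matrix about a unit axis by angle degrees (right-handed, acts on
# row vectors as x %*% R)
.rotation_matrix <- function(axis, angle) {
  u <- .unit(axis)
  th <- angle * .deg2rad
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) * ct + st * K + (1 - ct) * (u %o% u)
  t(R)  # transpose so that rows transform as x %*% R
}

# deterministic near-uniform unit sphere points (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# circular difference of two angles in degrees, result in [0, 180]
.circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
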