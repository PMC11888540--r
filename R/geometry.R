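# Vector geometry shared by the energy oracle, DSSP and the fixture
# builders. Coordinates are N x 3 matrices in nm; angles in degrees.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
.norm3 <- function(v) sqrt(sum(v * v))
.unit3 <- function(v) v / .norm3(v)

#' Measure a proper dihedral angle from four points
#'
#' Signed torsion a-b-c-d in degrees, in (-180, 180], using the
#' atan2 convention (IUPAC sign).
#'
#' @param a,b,c,d Numeric length-3 coordinates (nm).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit3(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place point D given A, B, C with bond |CD|, angle B-C-D and torsion
# A-B-C-D (NeRF construction).
.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- .unit3(c - b)
  n <- .unit3(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Uniform random rotation matrix (Haar measure) from a random quaternion.
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Sample a unit vector uniformly within a cone of semi-angle theta (rad)
# about the unit axis u (equilibrium distribution of diffusion-in-cone).
.sample_in_cone <- function(u, theta) {
  z <- stats::runif(1, cos(theta), 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  v <- c(s * cos(phi), s * sin(phi), z)
  # rotate z-axis onto u
  if (abs(u[3] - 1) < 1e-12) return(v)
  if (abs(u[3] + 1) < 1e-12) return(c(v[1], -v[2], -v[3]))
  ax <- .unit3(.cross3(c(0, 0, 1), u))
  ang <- acos(u[3])
  ca <- cos(ang); sa <- sin(ang)
  v * ca + .cross3(ax, v) * sa + ax * sum(ax * v) * (1 - ca)
}
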