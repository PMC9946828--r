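# Low-level vector geometry shared by the geometry, structio and fixtures modules.
# All coordinates in Angstrom, all angles in degrees at module boundaries.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

#' Planar angle at vertex b, in degrees in [0, 180]
#' @param a,b,c 3-vectors
#' @return angle in degrees
#' @keywords internal
#' @noRd
planar_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  d <- sum(u * v)
  d <- max(-1, min(1, d))
  acos(d) * DEG
}

#' Dihedral angle a-b-c-d in degrees in (-180, 180]
#'
#' IUPAC sign convention: looking from b to c, the angle is positive when d is
#' rotated clockwise relative to a.
#' @keywords internal
#' @noRd
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(pracma_cross(n1, n2) * unit(b2))
  ang <- atan2(y, x) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# cross product; tiny helper kept local so geometry has no heavy deps
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Place an atom from internal coordinates (NeRF extension)
#'
#' Given positions of atoms a, b, c, place d such that |c-d| = bond,
#' angle(b,c,d) = angle_deg and dihedral(a,b,c,d) = torsion_deg.
#' @keywords internal
#' @noRd
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg / DEG
  tor <- torsion_deg / DEG
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  # local displacement in the (bc, m, n) frame
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

wrap_dihedral <- function(x) {
  # wrap to (-180, 180]
  y <- ((x + 180) %% 360) - 180
  y[y <= -180] <- y[y <= -180] + 360
  # values exactly at -180 map to +180 (the final bin owns the seam)
  y[abs(y + 180) < 1e-12] <- 180
  y
}
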