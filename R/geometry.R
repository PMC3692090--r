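#' Internal-coordinate geometry: frames, atom placement and measurement
#'
#' New atoms are positioned from internal coordinates (bond length r, bond
#' angle theta, dihedral phi) against three reference atoms A-B-C: the bond
#' anchor C, the angle reference B and the dihedral reference A.  A local
#' right-handed frame is erected at C from the B->C bond and the A-B-C plane,
#' and the new atom D is placed so that |D-C| = r, angle(B,C,D) = theta and
#' dihedral(A,B,C,D) = phi.
#'
#' Sign convention: phi > 0 when, sighting along B->C, D is rotated
#' counter-clockwise (right-hand rule about B->C) from the component of A
#' perpendicular to B->C.  Templates and placement share this one definition;
#' `measure_internal()` is its exact inverse.
#'
#' All lengths are in nanometres, all angles in degrees.
#'
#' @name geometry
NULL

.vnorm <- function(v) sqrt(sum(v * v))

.cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Build a local right-handed orthonormal frame at a bond anchor
#'
#' @param a,b,c numeric 3-vectors: dihedral reference, angle reference and
#'   bond anchor.  The frame origin is `c`; the first axis points along the
#'   b->c bond; the second lies in the a-b-c plane; the third completes a
#'   right-handed set.
#' @return list with `origin` (3-vector) and `axes` (3x3 matrix, rows are the
#'   axis vectors).
#' @examples
#' fr <- build_frame(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
#' fr$axes %*% t(fr$axes)  # identity
#' @export
build_frame <- function(a, b, c) {
  stopifnot(length(a) == 3L, length(b) == 3L, length(c) == 3L)
  e1 <- c - b
  n1 <- .vnorm(e1)
  if (n1 < 1e-8) stop("degenerate frame: coincident angle reference and bond anchor")
  e1 <- e1 / n1
  w <- a - b
  nw <- .vnorm(w)
  if (nw < 1e-8) stop("degenerate frame: coincident dihedral and angle references")
  w <- w / nw
  # component of (a - b) perpendicular to the bond axis
  perp <- w - sum(w * e1) * e1
  np <- .vnorm(perp)
  if (np < 1e-8) stop("degenerate frame: reference atoms are collinear")
  e2 <- perp / np
  e3 <- .cross(e1, e2)
  axes <- rbind(e1, e2, e3)
  dimnames(axes) <- NULL
  structure(list(origin = c, axes = axes), class = "ptm_frame")
}

#' Place an atom from internal coordinates
#'
#' @inheritParams build_frame
#' @param r bond length to the anchor `c`, nm (> 0).
#' @param theta bond angle B-C-D, degrees, in (0, 180).
#' @param phi dihedral angle A-B-C-D, degrees, in (-180, 180].
#' @return numeric 3-vector, the position of the placed atom D.
#' @examples
#' place_atom(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), r = 1, theta = 90, phi = 0)
#' @export
place_atom <- function(a, b, c, r, theta, phi) {
  if (!is.finite(r) || r <= 0) stop("bond length r must be positive")
  if (!is.finite(theta) || theta <= 0 || theta >= 180)
    stop("bond angle theta must lie strictly between 0 and 180 degrees")
  if (!is.finite(phi) || phi <= -180 || phi > 180)
    stop("dihedral phi must lie in (-180, 180]")
  fr <- build_frame(a, b, c)
  th <- .deg2rad(theta)
  ph <- .deg2rad(phi)
  # Local coordinates: the B->C axis carries cos(pi - theta) = -cos(theta)
  # so that theta is the interior angle at C; phi rotates about that axis
  # starting from the in-plane (e2) direction.
  local <- c(r * cos(pi - th),
             r * sin(th) * cos(ph),
             r * sin(th) * sin(ph))
  as.numeric(fr$origin + drop(local %*% fr$axes))
}

#' Measure internal coordinates of a point against three references
#'
#' Inverse of [place_atom()]: returns the (r, theta, phi) that would place
#' `d` against references `a`, `b`, `c`.
#'
#' @inheritParams build_frame
#' @param d numeric 3-vector, the atom to measure.
#' @return named numeric vector `c(r =, theta =, phi =)` (nm, degrees,
#'   degrees; phi in (-180, 180]).
#' @export
measure_internal <- function(a, b, c, d) {
  u <- b - c
  v <- d - c
  r <- .vnorm(v)
  if (r < 1e-8 || .vnorm(u) < 1e-8) stop("degenerate geometry: coincident points")
  cth <- sum(u * v) / (.vnorm(u) * r)
  cth <- max(-1, min(1, cth))
  theta <- .rad2deg(acos(cth))
  # signed dihedral a-b-c-d about the b->c axis
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  nb2 <- .vnorm(b2)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10)
    stop("degenerate geometry: dihedral undefined for collinear references")
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * b2) / nb2
  phi <- .rad2deg(atan2(y, x))
  if (phi <= -180) phi <- phi + 360
  c(r = r, theta = theta, phi = phi)
}

# Signed dihedral for four stacked positions; used by the force field and
# the fixtures builder.  Returns radians.
.dihedral_rad <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  atan2(sum(.cross(n1, n2) * b2) / .vnorm(b2), sum(n1 * n2))
}
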