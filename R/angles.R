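#' Wrap angles to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  # floor maps 180 -> -180; fold back to the closed upper end
  y[y == -180] <- 180
  y
}

#' Minimal signed periodic difference a - b
#'
#' @param a,b angles in degrees.
#' @return signed difference in (-180, 180].
#' @export
periodic_diff <- function(a, b) {
  wrap_angle(a - b)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Returns the torsion p1-p2-p3-p4 in degrees, IUPAC sign convention:
#' looking along p2 -> p3, a clockwise rotation of the far bond relative to
#' the near bond is positive. cis = 0, trans = 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(b1^2)) < 1e-8 || nb2 < 1e-8 || sqrt(sum(b3^2)) < 1e-8)
    stop("dihedral: coincident consecutive points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("dihedral: collinear triple, torsion undefined")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  wrap_angle(atan2(y, x) * 180 / pi)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
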