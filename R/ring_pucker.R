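#' Six-membered ring conformer
#'
#' Bundles the six ordered ring atoms of a pyranose (convention
#' O5, C1, C2, C3, C4, C5) with their Cartesian coordinates. All
#' Cremer-Pople puckering quantities in the package are computed on
#' rings in this atom order; the mean-plane normal is chosen so that
#' the 4C1 chair maps to theta = 0 and the 1C4 chair to theta = 180.
#'
#' @param coords 6 x 3 numeric matrix of coordinates (Angstrom), rows in
#'   ring order.
#' @param atom_labels character vector of six unique atom names; default
#'   the pyranose convention.
#' @param source_tag free-text provenance (snapshot index, model id, ...).
#' @return object of class `ring_conformer`.
#' @export
ring_conformer <- function(coords,
                           atom_labels = c("O5", "C1", "C2", "C3", "C4", "C5"),
                           source_tag = "") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || nrow(coords) != 6 || ncol(coords) != 3)
    stop("ring_conformer: coords must be a 6 x 3 numeric matrix")
  if (length(atom_labels) != 6 || anyDuplicated(atom_labels))
    stop("ring_conformer: need six unique atom labels")
  if (any(!is.finite(coords)))
    stop("ring_conformer: non-finite coordinates")
  d <- sqrt(rowSums((coords - coords[c(2:6, 1), , drop = FALSE])^2))
  if (any(d < 0.5) || any(d > 2.5))
    stop(sprintf(
      "ring_conformer: consecutive ring atoms must be 0.5-2.5 Angstrom apart (got %s)",
      paste(sprintf("%.2f", d), collapse = ", ")))
  structure(list(atom_labels = atom_labels, coords = coords,
                 source_tag = source_tag),
            class = "ring_conformer")
}

#' @export
print.ring_conformer <- function(x, ...) {
  cat("ring_conformer:", paste(x$atom_labels, collapse = "-"),
      if (nzchar(x$source_tag)) paste0("[", x$source_tag, "]"), "\n")
  invisible(x)
}

#' Cremer-Pople puckering parameters of a six-membered ring
#'
#' Computes the puckering amplitude Q (Angstrom) and the spherical-polar
#' puckering direction (theta, phi) (degrees) from the displacements of
#' the six ring atoms perpendicular to the Cremer-Pople mean plane.
#' With atoms ordered O5, C1..C5 the 4C1 chair gives theta ~ 0, the 1C4
#' chair theta ~ 180, 2SO ~ (90, 150) and B3,O ~ (90, 180).
#'
#' phi is reported in [0, 360) and is undefined (NA, `phi_defined = FALSE`)
#' at the poles (theta = 0 or 180, i.e. pure chairs).
#'
#' @param conformer a [ring_conformer()].
#' @param planarity_tol rings with Q below this amplitude (Angstrom) are
#'   rejected as planar.
#' @return object of class `pucker_params`: list with `Q`, `theta`, `phi`,
#'   `phi_defined`.
#' @export
cremer_pople <- function(conformer, planarity_tol = 1e-4) {
  if (!inherits(conformer, "ring_conformer"))
    conformer <- ring_conformer(conformer)
  r <- conformer$coords
  r <- sweep(r, 2, colMeans(r))
  j <- 0:5
  s <- sin(2 * pi * j / 6)
  co <- cos(2 * pi * j / 6)
  R1 <- colSums(r * s)
  R2 <- colSums(r * co)
  n <- cross3(R1, R2)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("cremer_pople: degenerate ring geometry")
  n <- n / nn
  z <- as.numeric(r %*% n)
  Q <- sqrt(sum(z^2))
  if (Q < planarity_tol)
    stop("cremer_pople: planar ring, undefined pucker direction")
  a <- 2 * pi * 2 * j / 6
  qx <- sqrt(2 / 6) * sum(z * cos(a))
  qy <- -sqrt(2 / 6) * sum(z * sin(a))
  q2 <- sqrt(qx^2 + qy^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  theta <- rad2deg(atan2(q2, q3))
  if (q2 < planarity_tol) {
    phi <- NA_real_
    phi_defined <- FALSE
  } else {
    phi <- rad2deg(atan2(qy, qx)) %% 360
    phi_defined <- TRUE
  }
  pucker_params(Q, theta, phi, phi_defined)
}

#' Construct pucker parameters
#'
#' @param Q puckering amplitude, Angstrom (>= 0).
#' @param theta polar puckering angle, degrees in [0, 180].
#' @param phi azimuthal puckering angle, degrees (stored modulo 360), or NA.
#' @param phi_defined logical; FALSE for pure chairs/planar direction.
#' @return object of class `pucker_params`.
#' @export
pucker_params <- function(Q, theta, phi = NA_real_,
                          phi_defined = !is.na(phi)) {
  if (Q < 0) stop("pucker_params: Q must be >= 0")
  if (theta < -1e-9 || theta > 180 + 1e-9)
    stop("pucker_params: theta must lie in [0, 180]")
  theta <- min(max(theta, 0), 180)
  if (phi_defined) phi <- phi %% 360
  structure(list(Q = Q, theta = theta, phi = phi, phi_defined = phi_defined),
            class = "pucker_params")
}

#' @export
print.pucker_params <- function(x, ...) {
  cat(sprintf("pucker_params: Q = %.3f A, theta = %.2f deg, phi = %s\n",
              x$Q, x$theta,
              if (x$phi_defined) sprintf("%.2f deg", x$phi) else "undefined"))
  invisible(x)
}

#' Build ring coordinates with prescribed Cremer-Pople parameters
#'
#' Places the six ring atoms on a regular hexagon (radius 1.46 Angstrom,
#' typical pyranose) in the xy-plane and adds out-of-plane displacements
#' carrying only the m = 2 and m = 3 puckering harmonics, so the
#' Cremer-Pople mean plane is exactly the xy-plane and
#' `cremer_pople()` recovers (Q, theta, phi) to floating-point accuracy.
#' The hexagon winds so that ring dihedral signs match the pyranose
#' convention (1C4 at theta = 180 has Phi1 = O5-C1-C2-C3 < 0).
#'
#' @param Q puckering amplitude, Angstrom (> 0).
#' @param theta,phi Cremer-Pople direction, degrees. `phi` is ignored at
#'   the poles.
#' @param radius hexagon radius in the mean plane, Angstrom.
#' @param atom_labels passed to [ring_conformer()].
#' @param source_tag passed to [ring_conformer()].
#' @return a [ring_conformer()].
#' @export
inverse_cremer_pople <- function(Q, theta, phi = 0, radius = 1.46,
                                 atom_labels = c("O5", "C1", "C2", "C3",
                                                 "C4", "C5"),
                                 source_tag = "") {
  if (!is.finite(Q) || Q <= 0) stop("inverse_cremer_pople: Q must be > 0")
  if (is.na(phi)) phi <- 0
  j <- 0:5
  q2 <- Q * sin(deg2rad(theta))
  q3 <- Q * cos(deg2rad(theta))
  z <- sqrt(2 / 6) * q2 * cos(deg2rad(phi) + 2 * pi * 2 * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  ang <- -2 * pi * j / 6  # clockwise winding pins the dihedral sign convention
  coords <- cbind(radius * cos(ang), radius * sin(ang), z)
  ring_conformer(coords, atom_labels = atom_labels, source_tag = source_tag)
}

#' The 38 canonical pyranose ring conformers
#'
#' IUPAC canonical forms at their standard Cremer-Pople vertices for a
#' ring ordered O5, C1..C5: the two chairs at the poles, six boats and
#' six twist-boats (skews) alternating every 30 degrees on the equator,
#' and six envelopes plus six half-chairs on each tropic
#' (theta = 54.74 / 125.26 degrees). Names are ASCII: superscripts
#' first, e.g. "2SO" for the C2(up)/O5(down) skew-boat, "B3O" for the
#' C3,O5(down) boat, "OE"/"EO" for the O5-up/-down envelopes.
#'
#' @return data.frame with columns `name`, `theta`, `phi`, `chair`.
#' @export
pucker_catalog <- function() {
  eq <- data.frame(
    name = c("3OB", "3S1", "B14", "5S1", "25B", "2SO",
             "B3O", "1S3", "14B", "1S5", "B25", "OS2"),
    theta = 90, phi = seq(0, 330, by = 30), chair = FALSE)
  t_n <- rad2deg(acos(1 / sqrt(3)))   # 54.7356
  north <- data.frame(
    name = c("OE", "OH1", "E1", "2H1", "2E", "2H3",
             "E3", "4H3", "4E", "4H5", "E5", "OH5"),
    theta = t_n, phi = seq(0, 330, by = 30), chair = FALSE)
  south <- data.frame(
    name = c("3E", "3H4", "E4", "5H4", "5E", "5HO",
             "EO", "1HO", "1E", "1H2", "E2", "3H2"),
    theta = 180 - t_n, phi = seq(0, 330, by = 30), chair = FALSE)
  chairs <- data.frame(name = c("4C1", "1C4"), theta = c(0, 180),
                       phi = NA_real_, chair = TRUE)
  rbind(chairs, eq, north, south)
}

## great-circle distance (degrees) between two (theta, phi) points on the
## Cremer-Pople sphere; phi may be NA at the poles.
cp_distance <- function(theta1, phi1, theta2, phi2) {
  if (is.na(phi1)) phi1 <- 0
  if (is.na(phi2)) phi2 <- 0
  t1 <- deg2rad(theta1); t2 <- deg2rad(theta2)
  dphi <- deg2rad(phi1 - phi2)
  cosd <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dphi)
  rad2deg(acos(min(max(cosd, -1), 1)))
}

#' Name the nearest canonical pucker state
#'
#' Maps Cremer-Pople parameters to the nearest of the 38 canonical
#' conformers by great-circle distance on the puckering sphere. Ties are
#' broken by the fixed catalogue order (chairs, then equator, tropics).
#'
#' @param params a [pucker_params()].
#' @return canonical name, e.g. "1C4", "2SO", "B3O", "4C1".
#' @export
pucker_name <- function(params) {
  stopifnot(inherits(params, "pucker_params"))
  cat <- pucker_catalog()
  if (!params$phi_defined) {
    # only the two chairs can be resolved without an azimuth
    if (params$theta < 45) return("4C1")
    if (params$theta > 135) return("1C4")
    stop("pucker_name: phi undefined with theta near 90; cannot disambiguate equatorial forms")
  }
  d <- vapply(seq_len(nrow(cat)), function(i)
    cp_distance(params$theta, params$phi, cat$theta[i], cat$phi[i]),
    numeric(1))
  cat$name[which.min(d)]
}

#' Reference pucker states for alpha-iduronate
#'
#' The four targets used to restrain the iduronate ring: the ideal
#' (theta, phi) definitions (1C4: theta = 180; 2SO: (90, 150);
#' B3O: (90, 180); 4C1: theta = 0), the near-ideal Cremer-Pople values
#' (theta0, phi0) of the reference coordinates, and their six ring
#' dihedrals Phi0 (Phi1 = O5-C1-C2-C3, then cyclic).
#'
#' @param name optional single state name ("1C4", "2SO", "B3O", "4C1");
#'   when given, that one `pucker_state` is returned.
#' @return a named list of `pucker_state` objects, or one of them.
#' @export
ido_pucker_states <- function(name = NULL) {
  states <- list(
    "1C4" = pucker_state("1C4", theta_ideal = 180, phi_ideal = NA,
                         theta0 = 179.72, phi0 = NA,
                         Phi0 = c(-61.4, 57.4, -58.2, 65.5, -65.1, 61.6)),
    "2SO" = pucker_state("2SO", theta_ideal = 90, phi_ideal = 150,
                         theta0 = 89.92, phi0 = 149.87,
                         Phi0 = c(27.7, -56.4, 26.5, 29.5, -60.1, 29.1)),
    "B3O" = pucker_state("B3O", theta_ideal = 90, phi_ideal = 180,
                         theta0 = 90.07, phi0 = 180.03,
                         Phi0 = c(-2.6, -53.9, 54.7, 0.6, -60.8, 62.5)),
    "4C1" = pucker_state("4C1", theta_ideal = 0, phi_ideal = NA,
                         theta0 = 0.17, phi0 = NA,
                         Phi0 = c(68.1, -62.6, 66.2, -70.6, 67.3, -69.6)))
  if (is.null(name)) return(states)
  if (!name %in% names(states))
    stop("ido_pucker_states: unknown state ", name)
  states[[name]]
}

#' Construct a named canonical pucker state
#'
#' @param name canonical label.
#' @param theta_ideal,phi_ideal ideal Cremer-Pople direction, degrees;
#'   `phi_ideal = NA` for chairs.
#' @param theta0,phi0 near-ideal reference values extracted from an
#'   ensemble (optional; default the ideal values).
#' @param Phi0 six reference ring dihedrals, degrees in (-180, 180].
#' @return object of class `pucker_state`.
#' @export
pucker_state <- function(name, theta_ideal, phi_ideal = NA,
                         theta0 = theta_ideal, phi0 = phi_ideal,
                         Phi0 = NULL) {
  chair <- is.na(phi_ideal)
  if (!is.null(Phi0)) {
    stopifnot(length(Phi0) == 6)
    if (any(Phi0 <= -180 | Phi0 > 180))
      stop("pucker_state: Phi0 entries must lie in (-180, 180]")
  }
  structure(list(name = name, theta_ideal = theta_ideal,
                 phi_ideal = if (chair) NA_real_ else phi_ideal %% 360,
                 theta0 = theta0,
                 phi0 = if (is.na(phi0)) NA_real_ else phi0 %% 360,
                 Phi0 = Phi0, chair = chair),
            class = "pucker_state")
}

#' Closeness-to-idealness score of a pucker
#'
#' For chair targets (1C4, 4C1) the score is (theta - theta_ideal)^2;
#' for equatorial targets (2SO, B3O, and any other non-chair form) the
#' azimuthal term (phi - phi_ideal)^2 is added, with the phi difference
#' taken as the minimal image on the circle. Units: degrees squared.
#'
#' @param params a [pucker_params()].
#' @param target a [pucker_state()].
#' @return non-negative score, degrees^2.
#' @export
idealness_score <- function(params, target) {
  stopifnot(inherits(params, "pucker_params"),
            inherits(target, "pucker_state"))
  s <- (params$theta - target$theta_ideal)^2
  if (!target$chair) {
    if (!params$phi_defined)
      return(Inf)  # a pure chair can never be ideal for an equatorial target
    s <- s + periodic_diff(params$phi, target$phi_ideal)^2
  }
  s
}

#' Most ideal conformer in an ensemble
#'
#' Scans an ensemble of ring conformers and returns the one whose
#' Cremer-Pople parameters minimize [idealness_score()] against the
#' target pucker state; ties go to the lowest index.
#'
#' @param ensemble list of [ring_conformer()] objects.
#' @param target a [pucker_state()].
#' @return list with `index`, `conformer`, `params`, `score`.
#' @export
select_most_ideal <- function(ensemble, target) {
  if (length(ensemble) == 0)
    stop("select_most_ideal: empty ensemble")
  scores <- vapply(ensemble, function(cf)
    idealness_score(cremer_pople(cf), target), numeric(1))
  i <- which.min(scores)  # which.min takes the first (lowest-index) minimum
  list(index = i, conformer = ensemble[[i]],
       params = cremer_pople(ensemble[[i]]), score = scores[i])
}

#' Six ring dihedrals of a conformer
#'
#' Phi_i follows the cyclic quadruples Phi1 = O5-C1-C2-C3,
#' Phi2 = C1-C2-C3-C4, ..., Phi6 = C5-O5-C1-C2 (atoms in ring order).
#'
#' @param conformer a [ring_conformer()].
#' @return numeric vector of six dihedrals, degrees in (-180, 180].
#' @export
ring_dihedrals <- function(conformer) {
  if (!inherits(conformer, "ring_conformer"))
    conformer <- ring_conformer(conformer)
  r <- conformer$coords
  idx <- function(k) ((k - 1) %% 6) + 1
  vapply(1:6, function(i)
    dihedral(r[idx(i), ], r[idx(i + 1), ], r[idx(i + 2), ], r[idx(i + 3), ]),
    numeric(1))
}
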