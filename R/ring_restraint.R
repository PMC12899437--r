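#' Ring-dihedral restraint specification
#'
#' The harmonic ring restraining potential
#' E = 1/2 k sum_i ((Phi_i - Phi0_i) / w)^2 used to keep a pyranose ring
#' in a chosen pucker state during sampling. Defaults follow the
#' published protocol: k = 1 kcal/mol, w = 5 degrees, and the six
#' reference dihedrals Phi0 of the requested iduronate pucker state.
#'
#' @param Phi0 six reference dihedrals, degrees in (-180, 180], or a
#'   [pucker_state()] (its `Phi0` is used).
#' @param k force constant, kcal/mol (>= 0).
#' @param w width, degrees (> 0).
#' @return object of class `restraint_spec`.
#' @export
restraint_spec <- function(Phi0 = ido_pucker_states("1C4"), k = 1, w = 5) {
  if (inherits(Phi0, "pucker_state")) Phi0 <- Phi0$Phi0
  Phi0 <- as.numeric(Phi0)
  if (length(Phi0) != 6 || any(!is.finite(Phi0)))
    stop("restraint_spec: Phi0 must be six finite dihedrals")
  if (any(Phi0 <= -180 | Phi0 > 180))
    stop("restraint_spec: Phi0 entries must lie in (-180, 180]")
  if (w <= 0) stop("restraint_spec: w must be > 0")
  if (k < 0) stop("restraint_spec: k must be >= 0")
  structure(list(Phi0 = Phi0, k = k, w = w), class = "restraint_spec")
}

#' Ring restraint energy
#'
#' E = 1/2 k sum_{i=1..6} (Delta_i / w)^2 with
#' Delta_i = minimal-image difference Phi_i - Phi0_i. The wrap-aware
#' difference matters for reference dihedrals near +/-180.
#'
#' @param Phi six ring dihedrals, degrees.
#' @param spec a [restraint_spec()].
#' @return energy, kcal/mol.
#' @export
restraint_energy <- function(Phi, spec) {
  stopifnot(inherits(spec, "restraint_spec"), length(Phi) == 6)
  d <- periodic_diff(Phi, spec$Phi0)
  0.5 * spec$k * sum((d / spec$w)^2)
}

#' Ring restraint gradient
#'
#' Analytic derivative dE/dPhi_i = k Delta_i / w^2 of
#' [restraint_energy()].
#'
#' @inheritParams restraint_energy
#' @return six partial derivatives, kcal/mol/degree.
#' @export
restraint_gradient <- function(Phi, spec) {
  stopifnot(inherits(spec, "restraint_spec"), length(Phi) == 6)
  spec$k * periodic_diff(Phi, spec$Phi0) / spec$w^2
}

#' Emit the restraint as a Colvars-style harmonic block
#'
#' Text rendering of the equivalent collective-variables configuration
#' (six dihedral colvars plus one harmonic bias); a documentation aid
#' for transferring the restraint to an MD engine, not executed here.
#'
#' @param spec a [restraint_spec()].
#' @param atoms optional list of six atom-quadruple labels.
#' @return character vector of configuration lines.
#' @export
restraint_colvars_block <- function(spec, atoms = NULL) {
  stopifnot(inherits(spec, "restraint_spec"))
  if (is.null(atoms)) {
    ring <- c("O5", "C1", "C2", "C3", "C4", "C5")
    atoms <- lapply(1:6, function(i) ring[((i - 1 + 0:3) %% 6) + 1])
  }
  lines <- character(0)
  for (i in 1:6) {
    lines <- c(lines,
               sprintf("colvar {"),
               sprintf("  name ringPhi%d", i),
               sprintf("  dihedral { group1 { atomNames %s } group2 { atomNames %s } group3 { atomNames %s } group4 { atomNames %s } }",
                       atoms[[i]][1], atoms[[i]][2], atoms[[i]][3],
                       atoms[[i]][4]),
               "}")
  }
  c(lines,
    "harmonic {",
    sprintf("  colvars %s", paste(sprintf("ringPhi%d", 1:6), collapse = " ")),
    sprintf("  centers %s", paste(sprintf("%.1f", spec$Phi0), collapse = " ")),
    sprintf("  forceConstant %.6g", spec$k),
    sprintf("  width %.6g", spec$w),
    "}")
}

#' Fraction of a pucker series retained near a target state
#'
#' Fraction of (theta, phi) samples lying within a great-circle radius
#' of the target's ideal point on the Cremer-Pople sphere. For chair
#' targets the azimuth is irrelevant (pole), so the distance reduces to
#' the theta difference.
#'
#' @param theta_phi_series list of [pucker_params()], or a two-column
#'   matrix of (theta, phi) in degrees.
#' @param target a [pucker_state()].
#' @param radius retention radius on the sphere, degrees. The default
#'   30 separates the four iduronate restraint targets, the closest of
#'   which (2SO vs B3O) are 30 degrees apart.
#' @return fraction in [0, 1].
#' @export
pucker_retention <- function(theta_phi_series, target, radius = 30) {
  stopifnot(inherits(target, "pucker_state"))
  if (is.list(theta_phi_series) && !is.data.frame(theta_phi_series)) {
    m <- t(vapply(theta_phi_series,
                  function(p) c(p$theta, if (p$phi_defined) p$phi else NA),
                  numeric(2)))
  } else {
    m <- as.matrix(theta_phi_series)
  }
  if (nrow(m) == 0) stop("pucker_retention: empty series")
  d <- vapply(seq_len(nrow(m)), function(i)
    cp_distance(m[i, 1], m[i, 2], target$theta_ideal, target$phi_ideal),
    numeric(1))
  mean(d <= radius)
}

#' Metropolis sampler of the restrained pucker ensemble
#'
#' Samples (Q, theta, phi) from the Boltzmann distribution of the ring
#' restraint energy at the given temperature, evaluating the restraint
#' on the ring built by [inverse_cremer_pople()] at each proposal. The
#' stationary ensemble matches that of a restrained dynamics run over
#' the same coordinates and is used to check pucker retention.
#'
#' @param target a [pucker_state()] whose `Phi0` (with `k`, `w`) defines
#'   the restraint.
#' @param n number of retained samples.
#' @param temperature Kelvin.
#' @param k,w restraint force constant and width.
#' @param Q0 puckering amplitude at the start, Angstrom.
#' @param step_deg,step_Q proposal widths.
#' @param thin keep every `thin`-th sweep.
#' @param seed RNG seed.
#' @return matrix with columns theta, phi, Q (one row per sample).
#' @export
sample_restrained_pucker <- function(target, n = 500, temperature = 298,
                                     k = 1, w = 5, Q0 = 0.57,
                                     step_deg = 4, step_Q = 0.02,
                                     thin = 5, seed = 1) {
  stopifnot(inherits(target, "pucker_state"), !is.null(target$Phi0))
  spec <- restraint_spec(target, k = k, w = w)
  kT <- BOLTZMANN_KCAL * temperature
  set.seed(seed)
  th <- target$theta_ideal
  ph <- if (target$chair) 0 else target$phi_ideal
  Q <- Q0
  ener <- function(Q, th, ph) {
    if (Q <= 0.05 || th < 0 || th > 180) return(Inf)
    restraint_energy(ring_dihedrals(inverse_cremer_pople(Q, th, ph)), spec)
  }
  e <- ener(Q, th, ph)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("theta", "phi", "Q")))
  for (i in seq_len(n * thin)) {
    th2 <- th + stats::rnorm(1, 0, step_deg)
    ph2 <- (ph + stats::rnorm(1, 0, step_deg)) %% 360
    Q2 <- Q + stats::rnorm(1, 0, step_Q)
    e2 <- ener(Q2, th2, ph2)
    if (is.finite(e2) && stats::runif(1) < exp((e - e2) / kT)) {
      th <- th2; ph <- ph2; Q <- Q2; e <- e2
    }
    if (i %% thin == 0) out[i / thin, ] <- c(th, ph, Q)
  }
  out
}
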