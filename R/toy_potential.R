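#' Analytic periodic two-dimensional toy potential
#'
#' Smooth periodic landscape built from von-Mises-like wells,
#' U(x, y) = offset - sum_j depth_j * exp(kappa_j * (cos(x - x_j) +
#' cos(y - y_j) - 2)), with angles in degrees. Each well contributes a
#' basin of depth `depth` at its center; `kappa` controls how tightly
#' the basin is localized. Serves as analytic ground truth for the
#' free-energy estimation pipeline.
#'
#' @param wells data.frame with columns `phi`, `psi` (centers, degrees),
#'   `depth` (kcal/mol) and `kappa` (unitless concentration).
#' @param offset additive constant, kcal/mol.
#' @return object of class `toy_potential`.
#' @export
toy_potential <- function(wells, offset = 0) {
  wells <- as.data.frame(wells)
  need <- c("phi", "psi", "depth", "kappa")
  if (!all(need %in% names(wells)) || nrow(wells) < 1)
    stop("toy_potential: wells needs >= 1 row with columns phi, psi, depth, kappa")
  if (any(wells$kappa <= 0)) stop("toy_potential: kappa must be > 0")
  structure(list(wells = wells, offset = offset), class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("toy_potential: %d well(s), offset %.3g kcal/mol\n",
              nrow(x$wells), x$offset))
  print(x$wells)
  invisible(x)
}

#' Value and gradient of a toy potential
#'
#' Analytic, periodic in both axes. The gradient is returned in
#' kcal/mol/degree.
#'
#' @param p a [toy_potential()].
#' @param x,y coordinates, degrees (vectorized, recycled).
#' @return list with `U`, `dUdx`, `dUdy` (same length as inputs).
#' @export
potential_value_grad <- function(p, x, y) {
  stopifnot(inherits(p, "toy_potential"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  U <- rep(p$offset, n); gx <- numeric(n); gy <- numeric(n)
  r <- pi / 180
  for (w in seq_len(nrow(p$wells))) {
    dx <- (x - p$wells$phi[w]) * r
    dy <- (y - p$wells$psi[w]) * r
    e <- exp(p$wells$kappa[w] * (cos(dx) + cos(dy) - 2))
    U <- U - p$wells$depth[w] * e
    gx <- gx + p$wells$depth[w] * p$wells$kappa[w] * sin(dx) * e * r
    gy <- gy + p$wells$depth[w] * p$wells$kappa[w] * sin(dy) * e * r
  }
  list(U = U, dUdx = gx, dUdy = gy)
}

#' Evaluate a toy potential on a periodic grid
#'
#' @param p a [toy_potential()].
#' @param nbins grid bins per axis.
#' @return scalar [grid2d()] of U at bin centers.
#' @export
potential_grid <- function(p, nbins = 144) {
  g <- grid2d(nbins = nbins)
  xy <- expand.grid(x = g$centers, y = g$centers)
  g$values <- matrix(potential_value_grad(p, xy$x, xy$y)$U, nbins, nbins)
  g
}

#' Design a two-basin potential with a prescribed escape barrier
#'
#' Builds a two-well toy potential (a global well and a shallower
#' secondary well) whose minimax saddle, measured on a dense periodic
#' grid, gives the requested escape barrier from the chosen starting
#' basin to within 0.1 kcal/mol. The shared well concentration kappa is
#' tuned by bisection; for fixed depths a larger kappa narrows the
#' basins and raises the saddle towards the flat background, so the
#' escape barrier grows monotonically with kappa.
#'
#' @param barrier_target escape barrier, kcal/mol.
#' @param delta_secondary free-energy offset of the secondary minimum
#'   above the global minimum, kcal/mol. The default +1.3 mirrors a
#'   typical secondary-minimum depth in sulfated heparin disaccharides.
#' @param centers 2 x 2 matrix (rows: global, secondary) of well centers
#'   in degrees. Defaults place the global basin in the upper-left
#'   quadrant, (-77.5, 132.5), and the secondary basin in the
#'   lower-left quadrant, (-97.5, -80), as for IdoA2S-GlcNS-type
#'   linkages.
#' @param from basin the barrier is measured from: "secondary" (escape
#'   to the global basin) or "global".
#' @param depth_margin extra depth (kcal/mol) of the starting well below
#'   the requested barrier so the target stays attainable.
#' @param nbins grid resolution used for the saddle scan.
#' @param tol saddle tolerance, kcal/mol.
#' @return a [toy_potential()] with attributes `barrier` (achieved) and
#'   `kappa`.
#' @export
design_two_basin <- function(barrier_target,
                             delta_secondary = 1.3,
                             centers = rbind(global = c(-77.5, 132.5),
                                             secondary = c(-97.5, -80)),
                             from = c("secondary", "global"),
                             depth_margin = 1.5,
                             nbins = 144, tol = 0.1) {
  from <- match.arg(from)
  if (barrier_target <= 0) stop("design_two_basin: barrier_target must be > 0")
  if (delta_secondary < 0) stop("design_two_basin: delta_secondary must be >= 0")
  # depth of the well the escape starts from, with headroom above target
  d_start <- barrier_target + depth_margin
  if (from == "secondary") {
    d_sec <- d_start
    d_glob <- d_sec + delta_secondary
  } else {
    d_glob <- d_start
    d_sec <- d_glob - delta_secondary
    if (d_sec <= 0)
      stop("design_two_basin: delta_secondary too large for this target")
  }
  build <- function(kappa) {
    toy_potential(data.frame(phi = centers[, 1], psi = centers[, 2],
                             depth = c(d_glob, d_sec),
                             kappa = kappa))
  }
  measure <- function(p) {
    fes <- normalize_min_zero(potential_grid(p, nbins = nbins))
    mins <- find_local_minima(fes, ceiling = Inf)
    if (nrow(mins) < 2) return(NA_real_)
    dec <- segment_basins(fes, mins, ceiling = Inf)
    start <- if (from == "global") 1L else 2L
    other <- 3L - start
    barrier_height(dec, fes, start, other)
  }
  lo <- 0.5; hi <- 60
  b_lo <- measure(build(lo)); b_hi <- measure(build(hi))
  if (is.na(b_hi) || b_hi < barrier_target - tol)
    stop("design_two_basin: target barrier unattainable at these depths")
  if (!is.na(b_lo) && b_lo > barrier_target + tol)
    stop("design_two_basin: target barrier below attainable range")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    b <- measure(build(mid))
    if (is.na(b) || b < barrier_target) lo <- mid else hi <- mid
    if (!is.na(b) && abs(b - barrier_target) <= tol / 2) break
  }
  p <- build(mid)
  attr(p, "barrier") <- measure(p)
  attr(p, "kappa") <- mid
  attr(p, "from") <- from
  p
}
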