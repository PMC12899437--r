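#' Extended-system ABF accumulation state
#'
#' Per-bin statistics sufficient for the adaptive bias and for CZAR
#' free-energy-gradient estimation on a periodic (phi, psi) grid:
#' lambda-bin sample counts and summed spring forces (force exerted by
#' the extended-coordinate spring on the real coordinate) driving the
#' bias, and z-bin sample counts plus summed minimal-image spring
#' displacements (lambda - z) feeding the CZAR correction term.
#'
#' @param nbins grid bins per axis.
#' @param N_full bias ramp threshold: the bias in a lambda bin scales
#'   linearly with min(1, N/N_full).
#' @param k_ext extended-spring constant, kcal/mol/deg^2. The default
#'   0.01 gives a thermal spring fluctuation sqrt(kT/k_ext) of about
#'   7.7 degrees at 298 K, under two default grid bins.
#' @param temperature Kelvin.
#' @return object of class `eabf_state`.
#' @export
eabf_state <- function(nbins = 144, N_full = 200, k_ext = 0.01,
                       temperature = 298) {
  if (k_ext <= 0 || temperature <= 0 || N_full < 1)
    stop("eabf_state: k_ext, temperature and N_full must be positive")
  z <- function() matrix(0, nbins, nbins)
  structure(list(nbins = nbins, width = 360 / nbins,
                 N_full = as.integer(N_full), k_ext = k_ext,
                 temperature = temperature,
                 count_lambda = z(), sum_spring_phi = z(),
                 sum_spring_psi = z(),
                 count_z = z(), sum_dlambda_phi = z(),
                 sum_dlambda_psi = z()),
            class = "eabf_state")
}

#' @export
print.eabf_state <- function(x, ...) {
  cat(sprintf(
    "eabf_state: %d x %d bins, %d samples, N_full %d, k_ext %.3g kcal/mol/deg^2\n",
    x$nbins, x$nbins, sum(x$count_z), x$N_full, x$k_ext))
  invisible(x)
}

#' Merge eABF states from replicate runs
#'
#' @param ... `eabf_state` objects on identical grids.
#' @return pooled `eabf_state`.
#' @export
merge_eabf_states <- function(...) {
  states <- list(...)
  if (length(states) == 1 && is.list(states[[1]]) &&
      !inherits(states[[1]], "eabf_state"))
    states <- states[[1]]
  stopifnot(length(states) >= 1,
            all(vapply(states, inherits, logical(1), "eabf_state")))
  out <- states[[1]]
  for (s in states[-1]) {
    if (s$nbins != out$nbins || s$k_ext != out$k_ext)
      stop("merge_eabf_states: incompatible states")
    for (f in c("count_lambda", "sum_spring_phi", "sum_spring_psi",
                "count_z", "sum_dlambda_phi", "sum_dlambda_psi"))
      out[[f]] <- out[[f]] + s[[f]]
  }
  out
}

#' Adaptive bias force in a lambda bin
#'
#' F_bias = min(1, N/N_full) * (running mean spring force in the bin);
#' zero for empty bins. Applied to the extended coordinate, it cancels
#' the running mean of the coupling force so that lambda diffuses across
#' barriers once the bin estimate saturates.
#'
#' @param state an [eabf_state()].
#' @param i,j lambda bin indices (1-based).
#' @return c(F_phi, F_psi), kcal/mol/degree.
#' @export
abf_bias_force <- function(state, i, j) {
  n <- state$count_lambda[i, j]
  if (n == 0) return(c(0, 0))
  ramp <- min(1, n / state$N_full)
  ramp * c(state$sum_spring_phi[i, j], state$sum_spring_psi[i, j]) / n
}

#' CZAR estimate of the unbiased free-energy gradient
#'
#' Corrected z-averaged restraint estimator:
#' grad A(z) = -kT * grad ln rho~(z) + k_ext * (<lambda>_z - z),
#' where rho~ is the biased histogram of the real coordinate z and the
#' log-density gradient is taken by central differences on the periodic
#' grid. Bins without samples (or whose central-difference neighbors
#' lack samples) are returned as NA and flagged.
#'
#' @param state an [eabf_state()] with accumulated samples.
#' @return vector-valued [grid2d()] (nbins x nbins x 2) of the gradient
#'   in kcal/mol/degree, with attribute `missing` (logical matrix).
#' @export
czar_gradient <- function(state) {
  N <- state$count_z
  if (sum(N) == 0) stop("czar_gradient: state holds no samples")
  n <- state$nbins
  h <- state$width
  kT <- BOLTZMANN_KCAL * state$temperature
  lnr <- matrix(NA_real_, n, n)
  pos <- N > 0
  lnr[pos] <- log(N[pos])          # constant normalization drops in the gradient
  ip <- c(n, 1:(n - 1)); im <- c(2:n, 1)
  dln_phi <- (lnr[im, ] - lnr[ip, ]) / (2 * h)
  dln_psi <- (lnr[, im] - lnr[, ip]) / (2 * h)
  mean_dl_phi <- ifelse(pos, state$sum_dlambda_phi / pmax(N, 1), NA_real_)
  mean_dl_psi <- ifelse(pos, state$sum_dlambda_psi / pmax(N, 1), NA_real_)
  gphi <- -kT * dln_phi + state$k_ext * mean_dl_phi
  gpsi <- -kT * dln_psi + state$k_ext * mean_dl_psi
  g <- grid2d(nbins = n, values = array(c(gphi, gpsi), c(n, n, 2)))
  attr(g, "missing") <- !is.finite(gphi) | !is.finite(gpsi)
  g
}

## fill NA bins of a (possibly vector-valued) grid by iterative averaging of
## finite periodic 8-neighbors
fill_missing_bins <- function(values, max_iter = 1000) {
  n <- nrow(values)
  ip <- c(n, 1:(n - 1)); im <- c(2:n, 1)
  fill_one <- function(v) {
    for (it in seq_len(max_iter)) {
      bad <- !is.finite(v)
      if (!any(bad)) break
      acc <- matrix(0, n, n); cnt <- matrix(0, n, n)
      for (sh in list(v[ip, ], v[im, ], v[, ip], v[, im],
                      v[ip, ip], v[ip, im], v[im, ip], v[im, im])) {
        ok <- is.finite(sh)
        acc[ok] <- acc[ok] + sh[ok]
        cnt <- cnt + ok
      }
      upd <- bad & cnt > 0
      v[upd] <- acc[upd] / cnt[upd]
    }
    v
  }
  if (length(dim(values)) == 3) {
    values[, , 1] <- fill_one(values[, , 1])
    values[, , 2] <- fill_one(values[, , 2])
  } else values <- fill_one(values)
  values
}

#' Integrate a periodic gradient field into a free-energy surface
#'
#' Solves the discrete periodic Poisson problem div grad A = div G by
#' spectral inversion of the central-difference Laplacian (FFT), with
#' the null modes pinned to zero, then min-zero normalizes. Divergence
#' and Laplacian both use central differences, so when G is itself the
#' central-difference gradient of a surface the surface is recovered
#' exactly (up to the constant). For an inconsistent (noisy) G the
#' result is the least-squares potential; the root-mean-square residual
#' ||G - grad A|| is attached as attribute `residual`.
#'
#' @param grad vector-valued [grid2d()] (nbins x nbins x 2),
#'   kcal/mol/degree. NA bins are filled by iterative neighbor
#'   averaging (`fill = "neighbor"`) or left to invalidate the result
#'   (`fill = "none"`).
#' @param fill missing-bin policy.
#' @return scalar [grid2d()] free-energy surface, min-zero normalized,
#'   with attributes `residual` (kcal/mol/degree, RMS) and `argmin`.
#' @export
poisson_integrate <- function(grad, fill = c("neighbor", "none")) {
  fill <- match.arg(fill)
  stopifnot(inherits(grad, "grid2d"))
  if (length(dim(grad$values)) != 3)
    stop("poisson_integrate: need a vector-valued gradient grid")
  n <- grad$nbins
  h <- grad$width
  G <- grad$values
  if (any(!is.finite(G))) {
    if (fill == "none")
      stop("poisson_integrate: gradient grid has missing bins")
    G <- fill_missing_bins(G)
  }
  k <- 0:(n - 1)
  s <- 1i * sin(2 * pi * k / n) / h          # central-difference symbol
  Sx <- matrix(s, n, n)                      # varies along phi (rows)
  Sy <- t(Sx)
  L <- Sx^2 + Sy^2
  num <- Sx * stats::fft(G[, , 1]) + Sy * stats::fft(G[, , 2])
  Ahat <- matrix(0 + 0i, n, n)
  nz <- Mod(L) > 1e-12
  Ahat[nz] <- num[nz] / L[nz]
  A <- Re(stats::fft(Ahat, inverse = TRUE)) / n^2
  fes <- grid2d(nbins = n, values = A)
  ip <- c(n, 1:(n - 1)); im <- c(2:n, 1)
  rx <- (A[im, ] - A[ip, ]) / (2 * h) - G[, , 1]
  ry <- (A[, im] - A[, ip]) / (2 * h) - G[, , 2]
  fes <- normalize_min_zero(fes)
  attr(fes, "residual") <- sqrt(mean(c(rx, ry)^2))  # RMS over all components
  fes
}
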