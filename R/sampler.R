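#' Sampler configuration
#'
#' Parameters of the overdamped Langevin toy sampler. The real
#' coordinate pair z = (phi, psi) moves on the toy potential plus a
#' harmonic spring to the extended pair lambda; lambda moves on the
#' spring plus (for `bias = "eabf"`) the adaptive bias force. Both pairs
#' are thermostatted at `temperature` by the Euler-Maruyama noise term.
#'
#' Units: degrees, kcal/mol; time is measured in integration steps with
#' an arbitrary unit fixed by `dt` and `friction` (only the ratio
#' dt/friction and kT enter the discrete dynamics).
#'
#' @param n_steps number of integration steps.
#' @param dt integration step. The default 2 gives a root-mean-square
#'   thermal displacement of about 1.5 degrees per step at 298 K with
#'   unit friction -- well under one default grid bin -- while keeping
#'   the Euler-Maruyama stationary-distribution bias below a few
#'   percent for the well curvatures used here.
#' @param friction friction coefficient (sets the mobility dt/friction).
#' @param temperature Kelvin (kT = 0.5922 kcal/mol at the default 298).
#' @param k_ext extended-spring constant, kcal/mol/deg^2.
#' @param seed RNG seed; identical seeds give bit-identical trajectories.
#' @param bias "none" or "eabf".
#' @param nbins grid bins per axis for bias/CZAR accumulation.
#' @param N_full bias ramp threshold (samples per bin).
#' @param stride trajectory output stride (statistics accumulate every
#'   step regardless).
#' @param start c(phi, psi) starting point, degrees.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_steps = 2e5, dt = 2, friction = 1,
                           temperature = 298, k_ext = 0.01, seed = 1,
                           bias = c("none", "eabf"), nbins = 144,
                           N_full = 200, stride = 10, start = c(0, 0)) {
  bias <- match.arg(bias)
  if (dt <= 0 || friction <= 0 || temperature <= 0 || k_ext <= 0)
    stop("sampler_config: dt, friction, temperature, k_ext must be > 0")
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 friction = friction, temperature = temperature,
                 k_ext = k_ext, seed = as.integer(seed), bias = bias,
                 nbins = as.integer(nbins), N_full = as.integer(N_full),
                 stride = as.integer(stride), start = start),
            class = "sampler_config")
}

#' Run the overdamped Langevin sampler
#'
#' Integrates the coupled (z, lambda) overdamped Langevin equations on a
#' toy potential. With `cfg$bias = "eabf"` the adaptive bias force (the
#' ramped running mean of the spring force in the current lambda bin)
#' is applied to lambda, and all per-bin statistics are accumulated
#' into the returned eABF state. A fixed seed reproduces the trajectory
#' bit for bit.
#'
#' @param p a [toy_potential()].
#' @param cfg a [sampler_config()].
#' @param bias_state optional [eabf_state()] carrying statistics from
#'   earlier runs; samples from this run are added to a copy of it.
#' @return object of class `torsion_trajectory`: data.frame with
#'   columns step, phi, psi, lphi, lpsi, fphi, fpsi; the updated
#'   [eabf_state()] is attached as attribute `eabf_state`.
#' @export
run_langevin <- function(p, cfg, bias_state = NULL) {
  stopifnot(inherits(p, "toy_potential"), inherits(cfg, "sampler_config"))
  state <- if (is.null(bias_state))
    eabf_state(nbins = cfg$nbins, N_full = cfg$N_full, k_ext = cfg$k_ext,
               temperature = cfg$temperature)
  else bias_state
  if (state$nbins != cfg$nbins)
    stop("run_langevin: bias_state grid does not match cfg$nbins")
  wells <- as.matrix(p$wells[, c("phi", "psi", "depth", "kappa")])
  set.seed(cfg$seed)
  ## copies: the C++ kernel fills these in place
  cl <- matrix(as.integer(state$count_lambda), cfg$nbins, cfg$nbins)
  cz <- matrix(as.integer(state$count_z), cfg$nbins, cfg$nbins)
  ssp <- state$sum_spring_phi + 0
  sss <- state$sum_spring_psi + 0
  sdp <- state$sum_dlambda_phi + 0
  sds <- state$sum_dlambda_psi + 0
  res <- langevin_eabf_cpp(wells, p$offset,
                           cfg$start[1], cfg$start[2],
                           cfg$start[1], cfg$start[2],
                           cfg$n_steps, cfg$dt, cfg$friction,
                           cfg$temperature, cfg$k_ext,
                           cfg$bias == "eabf",
                           cfg$nbins, 360 / cfg$nbins, cfg$N_full,
                           cfg$stride,
                           cl, ssp, sss, cz, sdp, sds)
  state$count_lambda <- cl
  state$sum_spring_phi <- ssp
  state$sum_spring_psi <- sss
  state$count_z <- cz
  state$sum_dlambda_phi <- sdp
  state$sum_dlambda_psi <- sds
  traj <- as.data.frame(res$traj)
  names(traj) <- c("step", "phi", "psi", "lphi", "lpsi", "fphi", "fpsi")
  class(traj) <- c("torsion_trajectory", "data.frame")
  attr(traj, "config") <- cfg
  attr(traj, "eabf_state") <- state
  traj
}

#' Write a torsion trajectory as columnar text
#'
#' One-line `#`-prefixed header naming the columns (step, phi, psi,
#' lambda_phi, lambda_psi, f_lambda_phi, f_lambda_psi), then one row per
#' stored frame.
#'
#' @param traj a `torsion_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  header <- "# step phi psi lphi lpsi fphi fpsi"
  body <- apply(as.matrix(traj), 1, function(r)
    paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a columnar torsion trajectory
#'
#' @param path file written by [write_trajectory()].
#' @return a `torsion_trajectory` data.frame.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              ncol = 7, byrow = TRUE)
  traj <- as.data.frame(m)
  names(traj) <- c("step", "phi", "psi", "lphi", "lpsi", "fphi", "fpsi")
  class(traj) <- c("torsion_trajectory", "data.frame")
  traj
}

#' Count basin transitions along a trajectory
#'
#' Maps the real-coordinate series to basin labels and counts label
#' changes. Frames in unlabeled bins (above the segmentation ceiling)
#' keep the previous label. A dwell filter requires `dwell` consecutive
#' frames in the new basin before a transition registers, suppressing
#' rapid barrier recrossings; `dwell = 1` counts every change.
#'
#' @param traj a `torsion_trajectory` (or data.frame with phi, psi).
#' @param basins a [segment_basins()] decomposition.
#' @param fes the surface the decomposition was built on (provides the
#'   grid geometry).
#' @param dwell dwell filter length, frames.
#' @return list with `n_transitions`, `pairs` (matrix of counts from
#'   basin a to basin b), `visited` (basin ids occupied for at least
#'   `dwell` frames), `labels` (filtered per-frame labels).
#' @export
count_basin_transitions <- function(traj, basins, fes, dwell = 10) {
  stopifnot(inherits(basins, "basin_decomposition"))
  lab_raw <- basins$labels[cbind(bin_index(fes, traj$phi),
                                 bin_index(fes, traj$psi))]
  ## carry last label through unlabeled stretches
  for (t in seq_along(lab_raw)) {
    if (lab_raw[t] == 0L && t > 1) lab_raw[t] <- lab_raw[t - 1]
  }
  lab_raw <- lab_raw[lab_raw != 0L]
  nmin <- nrow(basins$minima)
  pairs <- matrix(0L, nmin, nmin)
  if (length(lab_raw) == 0)
    return(list(n_transitions = 0L, pairs = pairs, visited = integer(0),
                labels = integer(0)))
  cur <- lab_raw[1]
  run <- 0L
  pending <- cur
  filtered <- integer(length(lab_raw))
  visited <- cur
  for (t in seq_along(lab_raw)) {
    l <- lab_raw[t]
    if (l == pending) run <- run + 1L else { pending <- l; run <- 1L }
    if (pending != cur && run >= dwell) {
      pairs[cur, pending] <- pairs[cur, pending] + 1L
      cur <- pending
      visited <- union(visited, cur)
    }
    filtered[t] <- cur
  }
  list(n_transitions = sum(pairs), pairs = pairs,
       visited = sort(visited), labels = filtered)
}

#' Ring-conformer ensemble at a target pucker with thermal jitter
#'
#' Builds `n` rings by [inverse_cremer_pople()] with Gaussian jitter on
#' (theta, phi, Q) around the target's ideal point; jitter across a
#' pole is reflected (theta mirrored, phi advanced by 180). Seeded and
#' reproducible.
#'
#' @param target a [pucker_state()].
#' @param n ensemble size (>= 1).
#' @param jitter_deg standard deviation of the angular jitter, degrees.
#' @param seed RNG seed.
#' @param Q0 mean puckering amplitude, Angstrom.
#' @param jitter_Q standard deviation of the amplitude jitter.
#' @return list of [ring_conformer()] objects (source_tag = member
#'   index).
#' @export
make_ring_ensemble <- function(target, n, jitter_deg = 3, seed = 1,
                               Q0 = 0.57, jitter_Q = 0.01) {
  stopifnot(inherits(target, "pucker_state"), n >= 1)
  set.seed(seed)
  th0 <- target$theta_ideal
  ph0 <- if (target$chair) 0 else target$phi_ideal
  lapply(seq_len(n), function(i) {
    th <- th0 + stats::rnorm(1, 0, jitter_deg)
    ph <- ph0 + stats::rnorm(1, 0, jitter_deg)
    if (th > 180) { th <- 360 - th; ph <- ph + 180 }
    if (th < 0) { th <- -th; ph <- ph + 180 }
    Q <- abs(Q0 + stats::rnorm(1, 0, jitter_Q))
    inverse_cremer_pople(Q, th, ph %% 360, source_tag = sprintf("member %d", i))
  })
}
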