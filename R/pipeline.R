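#' Pipeline configuration
#'
#' Collects the knobs of the simulate -> estimate -> analyze pipeline:
#' grid resolution, sampler settings, replicate seeds (default
#' triplicate, the usual replication scheme), analysis thresholds and
#' the output directory. Can be read from / written to a YAML file.
#'
#' @param output_dir directory the commands write into.
#' @param seeds one RNG seed per replicate (1-16 replicates).
#' @param nbins grid bins per axis.
#' @param n_steps steps per replicate.
#' @param barrier designed escape barrier of the default two-basin toy
#'   landscape, kcal/mol.
#' @param temperature Kelvin.
#' @param k_ext extended-spring constant, kcal/mol/deg^2.
#' @param N_full bias ramp threshold.
#' @param dt,friction,stride sampler numerics, see [sampler_config()].
#' @param ceiling segmentation ceiling, kcal/mol.
#' @param minima_ceiling ceiling for reported local minima, kcal/mol.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "gagfes_out",
                            seeds = c(1, 2, 3), nbins = 144,
                            n_steps = 2e5, barrier = 4,
                            temperature = 298, k_ext = 0.01,
                            N_full = 200, dt = 2, friction = 1,
                            stride = 10, ceiling = 15,
                            minima_ceiling = 3) {
  if (length(seeds) < 1 || length(seeds) > 16)
    stop("pipeline_config: 1-16 replicate seeds")
  structure(list(output_dir = output_dir, seeds = as.integer(seeds),
                 nbins = as.integer(nbins), n_steps = as.integer(n_steps),
                 barrier = barrier, temperature = temperature,
                 k_ext = k_ext, N_full = as.integer(N_full), dt = dt,
                 friction = friction, stride = as.integer(stride),
                 ceiling = ceiling, minima_ceiling = minima_ceiling),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

provenance <- function(config, extra = list()) {
  tmp <- tempfile()
  yaml::write_yaml(unclass(config), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  c(list(package = "gagfes",
         version = as.character(utils::packageVersion("gagfes")),
         config_md5 = hash, seeds = config$seeds), extra)
}

ensure_outdir <- function(config) {
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  config$output_dir
}

#' Run the replicate toy eABF simulations
#'
#' Designs the two-basin landscape, runs one seeded eABF Langevin
#' replicate per configured seed, and writes per-replicate trajectory
#' files plus a provenance log. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param potential optional [toy_potential()]; by default
#'   [design_two_basin()] at the configured barrier.
#' @param force overwrite existing outputs.
#' @return invisible list with trajectory paths, the potential and the
#'   per-replicate eABF states.
#' @export
cmd_simulate <- function(config, potential = NULL, force = FALSE) {
  dir <- ensure_outdir(config)
  paths <- file.path(dir, sprintf("replicate_%d.traj", config$seeds))
  if (any(file.exists(paths)) && !force)
    stop("cmd_simulate: outputs exist; use force = TRUE to overwrite")
  if (is.null(potential))
    potential <- design_two_basin(config$barrier, nbins = config$nbins)
  states <- list()
  for (k in seq_along(config$seeds)) {
    cfg <- sampler_config(n_steps = config$n_steps, dt = config$dt,
                          friction = config$friction,
                          temperature = config$temperature,
                          k_ext = config$k_ext, seed = config$seeds[k],
                          bias = "eabf", nbins = config$nbins,
                          N_full = config$N_full, stride = config$stride,
                          start = as.numeric(potential$wells[1, c("phi", "psi")]))
    traj <- run_langevin(potential, cfg)
    write_trajectory(traj, paths[k])
    states[[k]] <- attr(traj, "eabf_state")
  }
  log <- provenance(config, list(command = "simulate",
                                 trajectories = basename(paths)))
  jsonlite::write_json(log, file.path(dir, "simulate_provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(trajectories = paths, potential = potential,
                 states = states))
}

#' Estimate free-energy surfaces from eABF states
#'
#' CZAR gradient estimation followed by periodic Poisson integration,
#' per replicate and pooled; grids are written in Colvars-style text.
#'
#' @param config a [pipeline_config()].
#' @param states list of [eabf_state()] objects (one per replicate),
#'   e.g. from [cmd_simulate()].
#' @return invisible list with `surfaces` (per replicate), `pooled`,
#'   and the written paths.
#' @export
cmd_estimate <- function(config, states) {
  if (length(states) < 1) stop("cmd_estimate: need at least one state")
  nb <- unique(vapply(states, function(s) s$nbins, numeric(1)))
  if (length(nb) != 1) stop("cmd_estimate: grid mismatch across replicates")
  dir <- ensure_outdir(config)
  surfaces <- list()
  paths <- character(0)
  for (k in seq_along(states)) {
    grad <- czar_gradient(states[[k]])
    fes <- poisson_integrate(grad)
    surfaces[[k]] <- fes
    gp <- file.path(dir, sprintf("replicate_%d.grad", k))
    fp <- file.path(dir, sprintf("replicate_%d.pmf", k))
    write_colvars_grid(grad, gp)
    write_colvars_grid(fes, fp)
    paths <- c(paths, gp, fp)
  }
  pooled_state <- merge_eabf_states(states)
  pooled <- poisson_integrate(czar_gradient(pooled_state))
  pp <- file.path(dir, "pooled.pmf")
  write_colvars_grid(pooled, pp)
  invisible(list(surfaces = surfaces, pooled = pooled,
                 paths = c(paths, pp)))
}

#' Analyze free-energy surfaces
#'
#' Minima, basin segmentation, pairwise saddle matrix, basin extents,
#' global-minimum shifts between replicates and the convergence
#' verdict; written as JSON and delimited text.
#'
#' @param config a [pipeline_config()].
#' @param surfaces list of scalar [grid2d()] surfaces (or paths to
#'   Colvars-style PMF files).
#' @return invisible report list.
#' @export
cmd_analyze <- function(config, surfaces) {
  if (length(surfaces) < 1) stop("cmd_analyze: need at least one surface")
  surfaces <- lapply(surfaces, function(s)
    if (is.character(s)) read_colvars_grid(s) else s)
  surfaces <- lapply(surfaces, normalize_min_zero)
  dir <- ensure_outdir(config)
  fes <- surfaces[[1]]
  mins <- find_local_minima(fes, ceiling = config$minima_ceiling)
  report <- list(minima = mins)
  if (nrow(mins) >= 1) {
    dec <- segment_basins(fes, mins, ceiling = config$ceiling)
    report$saddle <- dec$saddle
    report$quadrants <- quadrant(mins$phi, mins$psi)
    report$extent_global <- basin_extent(dec, fes, 1,
                                         level = mins$dG[1] + 1)
    if (nrow(mins) >= 2)
      report$escape_barriers <- vapply(2:nrow(mins), function(b)
        barrier_height(dec, fes, b, 1), numeric(1))
  }
  if (length(surfaces) >= 2) {
    report$convergence <- compare_replicates(surfaces,
                                             low_region = 5,
                                             argmin_tol = 15)
    report$min_shifts <- t(vapply(2:length(surfaces), function(k)
      min_shift(surfaces[[1]], surfaces[[k]]), numeric(2)))
  }
  jsonlite::write_json(report, file.path(dir, "analysis.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  utils::write.table(mins, file.path(dir, "minima.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(report)
}

#' Per-model pucker and linkage tables of a PDB file
#'
#' Parses a (multi-model) PDB file and reports, per model, every
#' residue's Cremer-Pople parameters and pucker name and every
#' glycosidic linkage's IUPAC (phi, psi).
#'
#' @param pdb_path PDB file.
#' @param output_dir optional directory for the delimited-text tables.
#' @return list with `puckers` and `linkages` data.frames (column
#'   `model` identifies the model).
#' @export
cmd_structure <- function(pdb_path, output_dir = NULL) {
  models <- read_pdb_models(pdb_path)
  if (length(models) == 0) stop("cmd_structure: no models in file")
  puckers <- do.call(rbind, lapply(models, function(m)
    cbind(model = m$model_id, classify_residue_puckers(m))))
  linkages <- do.call(rbind, lapply(models, function(m)
    cbind(model = m$model_id, linkage_table(m))))
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.table(puckers, file.path(output_dir, "puckers.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(linkages, file.path(output_dir, "linkages.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(puckers = puckers, linkages = linkages)
}
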