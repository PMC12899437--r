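#' Boltzmann constant in kcal/mol/K
#'
#' k_B = 0.0019872041 kcal/mol/K, so k_B T = 0.5922 kcal/mol at 298 K.
#' @export
BOLTZMANN_KCAL <- 0.0019872041

#' Regular periodic 2D grid over (phi, psi)
#'
#' Values on a regular grid covering the full torus
#' (phi, psi) in [-180, 180)^2, periodic in both axes. Bin centers sit
#' at -180 + j * width (j = 0..nbins-1), so with the default 2.5-degree
#' bins the reporting lattice (-77.5, 132.5, ...) consists of bin
#' centers; the lower cell edge is center - width/2.
#'
#' @param nbins bins per axis; `nbins * width` must equal 360.
#' @param width bin width, degrees.
#' @param values optional nbins x nbins matrix (phi along rows, psi
#'   along columns), or an nbins x nbins x 2 array for vector fields.
#' @return object of class `grid2d` with elements `nbins`, `width`,
#'   `centers`, `values`.
#' @export
grid2d <- function(nbins = 144, width = 360 / nbins, values = NULL) {
  if (abs(nbins * width - 360) > 1e-9)
    stop("grid2d: nbins * width must equal 360")
  centers <- -180 + (seq_len(nbins) - 1) * width
  if (is.null(values)) values <- matrix(0, nbins, nbins)
  dv <- dim(values)
  if (!(length(dv) %in% c(2, 3)) || dv[1] != nbins || dv[2] != nbins)
    stop("grid2d: values must be nbins x nbins (optionally x 2)")
  structure(list(nbins = nbins, width = width, centers = centers,
                 values = values),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("grid2d: %d x %d bins, width %.4g deg, %s\n",
              x$nbins, x$nbins, x$width,
              if (length(dim(x$values)) == 3) "vector-valued" else "scalar"))
  invisible(x)
}

#' Bin index of an angle
#'
#' Nearest-center binning: angle x maps to the bin whose center is
#' closest, respecting the wrap. Vectorized.
#'
#' @param g a [grid2d()].
#' @param x angles, degrees.
#' @return 1-based bin indices.
#' @export
bin_index <- function(g, x) {
  (round((x + 180) / g$width) %% g$nbins) + 1
}

#' Nearest-bin lookup on a surface
#'
#' Returns the stored value at the bin whose center is nearest to
#' (phi, psi), with both angles wrapped; no interpolation, matching how
#' free-energy values are reported on the 2.5-degree lattice.
#'
#' @param fes a scalar-valued [grid2d()] (e.g. a free-energy surface) or
#'   a view from [crop_phi_report()].
#' @param phi,psi angles, degrees.
#' @return value at the nearest bin.
#' @export
value_at <- function(fes, phi, psi) UseMethod("value_at")

#' @export
value_at.grid2d <- function(fes, phi, psi) {
  fes$values[cbind(bin_index(fes, phi), bin_index(fes, psi))]
}

#' Shift a surface so its minimum is exactly zero
#'
#' @param fes scalar [grid2d()].
#' @return the input grid with `values - min(values)`; the argmin bin is
#'   recorded in attribute `argmin` as c(phi, psi) of its center.
#' @export
normalize_min_zero <- function(fes) {
  v <- fes$values
  if (any(!is.finite(v))) stop("normalize_min_zero: non-finite values")
  i <- arrayInd(which.min(v), dim(v))
  fes$values <- v - min(v)
  attr(fes, "argmin") <- c(phi = fes$centers[i[1]], psi = fes$centers[i[2]])
  fes
}

#' Location of the surface minimum
#'
#' @param fes scalar [grid2d()].
#' @return c(phi, psi) of the bin-center argmin.
#' @export
argmin_location <- function(fes) {
  i <- arrayInd(which.min(fes$values), dim(fes$values))
  c(phi = fes$centers[i[1]], psi = fes$centers[i[2]])
}

#' Write a grid in Colvars-style multicolumn text
#'
#' Format: a first header line `# 2` (number of axes), then one line per
#' axis `# lower_edge width nbins 1` (1 = periodic), then one row per
#' bin: the two bin centers followed by the one (PMF) or two (gradient)
#' stored values, with a blank line between phi-blocks. Written with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param g a [grid2d()] (scalar or 2-vector values).
#' @param path output file.
#' @export
write_colvars_grid <- function(g, path) {
  stopifnot(inherits(g, "grid2d"))
  con <- file(path, "w")
  on.exit(close(con))
  lower <- -180 - g$width / 2
  writeLines("# 2", con)
  writeLines(sprintf("# %.17g %.17g %d 1", lower, g$width, g$nbins), con)
  writeLines(sprintf("# %.17g %.17g %d 1", lower, g$width, g$nbins), con)
  vec <- length(dim(g$values)) == 3
  for (i in seq_len(g$nbins)) {
    for (j in seq_len(g$nbins)) {
      vals <- if (vec) g$values[i, j, ] else g$values[i, j]
      writeLines(paste(c(sprintf("%.17g", g$centers[i]),
                         sprintf("%.17g", g$centers[j]),
                         sprintf("%.17g", vals)), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a Colvars-style multicolumn grid file
#'
#' Counterpart of [write_colvars_grid()]; accepts 3-column (scalar) and
#' 4-column (gradient) bodies.
#'
#' @param path file to read.
#' @return a [grid2d()].
#' @export
read_colvars_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 4 || trimws(lines[1]) != "# 2")
    stop("read_colvars_grid: not a 2D Colvars-style grid file")
  ax <- strsplit(trimws(sub("^#", "", lines[2])), "\\s+")[[1]]
  nbins <- as.integer(ax[3])
  width <- as.numeric(ax[2])
  body <- lines[!grepl("^\\s*#", lines)]
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || !(ncol %in% c(3, 4)))
    stop("read_colvars_grid: body rows must have 3 or 4 columns")
  m <- matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE)
  if (nrow(m) != nbins^2)
    stop("read_colvars_grid: expected ", nbins^2, " rows, got ", nrow(m))
  g <- grid2d(nbins = nbins, width = width,
              values = if (ncol == 3) matrix(0, nbins, nbins)
                       else array(0, c(nbins, nbins, 2)))
  i <- bin_index(g, m[, 1])
  j <- bin_index(g, m[, 2])
  if (ncol == 3) {
    g$values[cbind(i, j)] <- m[, 3]
  } else {
    g$values[cbind(i, j, 1L)] <- m[, 3]
    g$values[cbind(i, j, 2L)] <- m[, 4]
  }
  g
}
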