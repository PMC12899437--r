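## Periodic 8-neighborhood helpers. Bins are indexed (i, j) in 1..n with
## linear index (j - 1) * n + i (column-major, as R stores matrices);
## "lowest index" tie-breaks use the lexicographic (i, j) order, which for
## fixed n equals the row-major linear order used below.

lex_index <- function(i, j, n) (i - 1L) * n + j   # row-major lexicographic

neighbors8 <- function(i, j, n) {
  di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cbind(((i - 1L + di) %% n) + 1L, ((j - 1L + dj) %% n) + 1L)
}

#' Local minima of a periodic free-energy surface
#'
#' A bin is a local minimum when it lies strictly below all eight
#' periodic neighbors and below `ceiling`. Flat plateaus whose entire
#' boundary is strictly higher count as one minimum, represented by the
#' lexicographically smallest member bin. Results are sorted by
#' increasing free energy (ties by bin order).
#'
#' @param fes scalar [grid2d()], normally min-zero normalized.
#' @param ceiling only minima with value strictly below this are kept
#'   (kcal/mol).
#' @return data.frame with columns `phi`, `psi`, `dG`, `i`, `j`
#'   (possibly zero rows).
#' @export
find_local_minima <- function(fes, ceiling = 3) {
  v <- fes$values
  n <- fes$nbins
  ip <- c(n, 1:(n - 1)); im <- c(2:n, 1)
  ## min over the 8 shifted copies
  mn <- pmin(v[ip, ], v[im, ], v[, ip], v[, im],
             v[ip, ip], v[ip, im], v[im, ip], v[im, im])
  cand <- which(v <= mn & v < ceiling, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(phi = numeric(0), psi = numeric(0), dG = numeric(0),
                      i = integer(0), j = integer(0)))
  ## group candidates into equal-value 8-connected plateaus
  key <- paste(cand[, 1], cand[, 2])
  cand_set <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(key)) assign(key[k], k, envir = cand_set)
  seen <- logical(nrow(cand))
  mins <- list()
  for (s in seq_len(nrow(cand))) {
    if (seen[s]) next
    ## flood fill over equal-value candidate bins
    comp <- s
    queue <- s
    seen[s] <- TRUE
    val <- v[cand[s, 1], cand[s, 2]]
    ok <- TRUE
    has_boundary <- FALSE   # a true minimum needs strictly higher surroundings
    while (length(queue)) {
      b <- queue[1]; queue <- queue[-1]
      nb <- neighbors8(cand[b, 1], cand[b, 2], n)
      for (q in seq_len(8)) {
        vi <- v[nb[q, 1], nb[q, 2]]
        if (vi < val) { ok <- FALSE; next }
        if (vi > val) { has_boundary <- TRUE; next }
        if (vi == val) {
          kk <- get0(paste(nb[q, 1], nb[q, 2]), envir = cand_set)
          if (is.null(kk)) { ok <- FALSE } else if (!seen[kk]) {
            seen[kk] <- TRUE; comp <- c(comp, kk); queue <- c(queue, kk)
          }
        }
      }
    }
    if (!ok || !has_boundary) next  # leaks downhill, or covers the whole torus
    rows <- cand[comp, , drop = FALSE]
    rep_k <- which.min(lex_index(rows[, 1], rows[, 2], n))
    mins[[length(mins) + 1]] <- c(rows[rep_k, 1], rows[rep_k, 2], val)
  }
  if (length(mins) == 0)
    return(data.frame(phi = numeric(0), psi = numeric(0), dG = numeric(0),
                      i = integer(0), j = integer(0)))
  m <- do.call(rbind, mins)
  out <- data.frame(phi = fes$centers[m[, 1]], psi = fes$centers[m[, 2]],
                    dG = m[, 3], i = as.integer(m[, 1]),
                    j = as.integer(m[, 2]))
  out[order(out$dG, lex_index(out$i, out$j, n)), , drop = FALSE]
}

## Steepest-descent target of one bin: the neighbor minimizing
## (value, lexicographic index), considered only if it precedes the bin in
## that order; NULL when the bin is itself a (plateau-)representative.
descend_step <- function(v, n, i, j) {
  nb <- neighbors8(i, j, n)
  vals <- v[nb]
  here <- v[i, j]
  lex <- lex_index(nb[, 1], nb[, 2], n)
  cand <- which(vals < here | (vals == here & lex < lex_index(i, j, n)))
  if (length(cand) == 0) return(NULL)
  k <- cand[order(vals[cand], lex[cand])][1]
  nb[k, , drop = FALSE]
}

#' Basin decomposition of a free-energy surface
#'
#' Assigns every bin at or below `ceiling` to a minimum by steepest
#' descent: each bin follows its lowest periodic 8-neighbor (ties broken
#' lexicographically) until it reaches a minimum from `minima`. Also
#' computes the pairwise minimax saddle heights between the minima by a
#' sublevel-set union-find sweep: bins are activated in order of
#' increasing free energy and the saddle between two minima is the level
#' at which their basins first become connected.
#'
#' @param fes scalar [grid2d()].
#' @param minima data.frame from [find_local_minima()]; row order
#'   defines the basin ids.
#' @param ceiling segmentation ceiling, kcal/mol; bins above it stay
#'   unlabeled (label 0). Default 15, the usual contour-plot ceiling.
#' @return object of class `basin_decomposition`: list with `labels`
#'   (nbins x nbins integer matrix), `minima`, `saddle` (pairwise
#'   minimax crossing heights, kcal/mol), `ceiling`.
#' @export
segment_basins <- function(fes, minima, ceiling = 15) {
  v <- fes$values
  n <- fes$nbins
  if (nrow(minima) < 1) stop("segment_basins: need at least one minimum")
  labels <- matrix(0L, n, n)
  for (b in seq_len(nrow(minima))) labels[minima$i[b], minima$j[b]] <- b
  ## resolve each bin by iterative descent with memoization
  ord <- order(v, lex_index(row(v), col(v), n))
  for (lin in ord) {
    i <- ((lin - 1L) %% n) + 1L
    j <- ((lin - 1L) %/% n) + 1L
    if (v[i, j] > ceiling) next
    if (labels[i, j] != 0L) next
    path_i <- integer(0); path_j <- integer(0)
    ci <- i; cj <- j
    lab <- 0L
    repeat {
      if (labels[ci, cj] != 0L) { lab <- labels[ci, cj]; break }
      nxt <- descend_step(v, n, ci, cj)
      if (is.null(nxt)) break  # representative bin not in minima list
      path_i <- c(path_i, ci); path_j <- c(path_j, cj)
      ci <- nxt[1]; cj <- nxt[2]
    }
    if (lab != 0L && length(path_i))
      labels[cbind(path_i, path_j)] <- lab
    if (lab != 0L) labels[i, j] <- lab
  }
  saddle <- saddle_matrix(fes, minima)
  structure(list(labels = labels, minima = minima, saddle = saddle,
                 ceiling = ceiling),
            class = "basin_decomposition")
}

#' Pairwise minimax saddle heights between minima
#'
#' saddle[a, b] is the lowest level c such that minima a and b are
#' connected through bins with free energy <= c (periodic
#' 8-connectivity) -- the minimax crossing height over all paths.
#' Bins with non-finite values are impassable.
#'
#' @param fes scalar [grid2d()].
#' @param minima data.frame from [find_local_minima()].
#' @return symmetric matrix of crossing heights (kcal/mol); diagonal is
#'   the minima's own values; NA for pairs never connected.
#' @export
saddle_matrix <- function(fes, minima) {
  v <- fes$values
  n <- fes$nbins
  nb_total <- n * n
  nmin <- nrow(minima)
  S <- matrix(NA_real_, nmin, nmin)
  diag(S) <- minima$dG
  if (nmin < 2) return(S)
  min_lin <- (minima$j - 1L) * n + minima$i    # column-major linear index
  min_id_of <- integer(nb_total)
  min_id_of[min_lin] <- seq_len(nmin)
  finite <- is.finite(v)
  ord <- order(v, lex_index(row(v), col(v), n))
  ord <- ord[finite[ord]]
  parent <- seq_len(nb_total)
  uf_find <- function(x) {           # path-halving find over `parent`
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  active <- logical(nb_total)
  ## minima ids contained in each root's cluster
  members <- vector("list", nb_total)
  n_pairs_left <- nmin * (nmin - 1) / 2
  for (lin in ord) {
    i <- ((lin - 1L) %% n) + 1L
    j <- ((lin - 1L) %/% n) + 1L
    active[lin] <- TRUE
    if (min_id_of[lin] > 0) members[[lin]] <- min_id_of[lin]
    nb <- neighbors8(i, j, n)
    for (q in 1:8) {
      nlin <- (nb[q, 2] - 1L) * n + nb[q, 1]
      if (!active[nlin]) next
      ra <- uf_find(lin)
      rb <- uf_find(nlin)
      if (ra == rb) next
      ma <- members[[ra]]; mb <- members[[rb]]
      if (length(ma) && length(mb)) {
        for (a in ma) for (b in mb) {
          if (is.na(S[a, b])) {
            S[a, b] <- S[b, a] <- v[i, j]
            n_pairs_left <- n_pairs_left - 1
          }
        }
      }
      parent[rb] <- ra
      members[ra] <- list(c(ma, mb))   # list() guard: c() may be NULL
      members[rb] <- list(NULL)
    }
    if (n_pairs_left == 0) break
  }
  S
}

#' Escape barrier between two basins
#'
#' Directional barrier: (minimax crossing height along any periodic
#' 8-connected path between the two minima) minus the free energy of the
#' starting minimum. Zero within the same basin.
#'
#' @param decomp a [segment_basins()] result.
#' @param fes scalar [grid2d()] the decomposition came from.
#' @param basin_a starting basin id (row in `decomp$minima`).
#' @param basin_b destination basin id.
#' @return barrier, kcal/mol.
#' @export
barrier_height <- function(decomp, fes, basin_a, basin_b) {
  nmin <- nrow(decomp$minima)
  if (basin_a < 1 || basin_a > nmin || basin_b < 1 || basin_b > nmin)
    stop("barrier_height: basin id out of range")
  if (basin_a == basin_b) return(0)
  s <- decomp$saddle[basin_a, basin_b]
  if (is.na(s))
    stop("barrier_height: basins are not connected (masked bins?)")
  s - decomp$minima$dG[basin_a]
}

#' Quadrant of a (phi, psi) point
#'
#' Signs of the wrapped angles; zero counts as positive.
#'
#' @param phi,psi angles, degrees.
#' @return label such as "(-,+)".
#' @export
quadrant <- function(phi, psi) {
  sgn <- function(x) ifelse(wrap_angle(x) >= 0, "+", "-")
  paste0("(", sgn(phi), ",", sgn(psi), ")")
}

## tightest periodic interval covering a set of bin centers (degrees);
## returns c(lo, hi) with hi possibly > 180 when the interval crosses the
## +/-180 seam; c(NA, NA) for an empty set.
periodic_cover_interval <- function(centers, width) {
  u <- sort(unique(wrap_angle(centers)))
  if (length(u) == 0) return(c(NA_real_, NA_real_))
  if (length(u) == 1) return(c(u, u))
  gaps <- c(diff(u), u[1] + 360 - u[length(u)])
  k <- which.max(gaps)
  if (gaps[k] <= width + 1e-9) return(c(-180, 180))  # covers the full circle
  lo <- if (k == length(u)) u[1] else u[k + 1]
  hi <- u[k]
  if (hi < lo) hi <- hi + 360
  c(lo, hi)
}

#' Extent of a basin at a free-energy level
#'
#' Tightest periodic phi- and psi-intervals covering the basin's bins
#' with free energy at or below `level`.
#'
#' @param decomp a [segment_basins()] result.
#' @param fes the underlying surface.
#' @param basin basin id.
#' @param level contour level, kcal/mol.
#' @return list with `phi` and `psi`, each c(lo, hi) in degrees (hi may
#'   exceed 180 to denote an interval crossing the seam); NA when no bin
#'   qualifies.
#' @export
basin_extent <- function(decomp, fes, basin, level) {
  sel <- decomp$labels == basin & fes$values <= level
  idx <- which(sel, arr.ind = TRUE)
  list(phi = periodic_cover_interval(fes$centers[unique(idx[, 1])],
                                     fes$width),
       psi = periodic_cover_interval(fes$centers[unique(idx[, 2])],
                                     fes$width))
}

#' Shift of the global-minimum location between two surfaces
#'
#' Minimal-image difference of the argmin locations, surface b minus
#' surface a.
#'
#' @param fes_a,fes_b normalized scalar [grid2d()] surfaces.
#' @return c(dphi, dpsi), degrees.
#' @export
min_shift <- function(fes_a, fes_b) {
  a <- argmin_location(fes_a)
  b <- argmin_location(fes_b)
  c(dphi = periodic_diff(b[["phi"]], a[["phi"]]),
    dpsi = periodic_diff(b[["psi"]], a[["psi"]]))
}

#' Replicate convergence report
#'
#' Compares two or more surfaces on the same grid after min-zero
#' normalization: RMS deviation over the region where every surface is
#' at or below `low_region` kcal/mol, pairwise periodic distances
#' between the argmin locations, and a consistency verdict. Replicates
#' are "consistent" when all argmins are within `argmin_tol` degrees
#' (periodic Euclidean) of the first surface's argmin, or all fall in
#' one shared basin of the first surface.
#'
#' @param surfaces list of scalar [grid2d()] surfaces.
#' @param low_region region ceiling for the RMS, kcal/mol.
#' @param argmin_tol argmin agreement tolerance, degrees.
#' @return list with `rms` (pairwise matrix), `argmins`,
#'   `argmin_distance` (to first), `consistent`.
#' @export
compare_replicates <- function(surfaces, low_region = 5, argmin_tol = 15) {
  if (length(surfaces) < 2)
    stop("compare_replicates: need at least two surfaces")
  nb <- vapply(surfaces, function(s) s$nbins, numeric(1))
  if (length(unique(nb)) != 1)
    stop("compare_replicates: grid mismatch across surfaces")
  surfaces <- lapply(surfaces, normalize_min_zero)
  vals <- lapply(surfaces, function(s) s$values)
  low <- Reduce(`&`, lapply(vals, function(v) is.finite(v) & v <= low_region))
  k <- length(surfaces)
  rms <- matrix(0, k, k)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    d <- vals[[a]][low] - vals[[b]][low]
    rms[a, b] <- rms[b, a] <- sqrt(mean(d^2))
  }
  am <- t(vapply(surfaces, argmin_location, numeric(2)))
  dist1 <- vapply(seq_len(k), function(b)
    sqrt(periodic_diff(am[b, 1], am[1, 1])^2 +
         periodic_diff(am[b, 2], am[1, 2])^2), numeric(1))
  consistent <- all(dist1 <= argmin_tol)
  if (!consistent) {
    mins1 <- find_local_minima(surfaces[[1]], ceiling = Inf)
    dec1 <- segment_basins(surfaces[[1]], mins1, ceiling = Inf)
    labs <- vapply(seq_len(k), function(b)
      dec1$labels[bin_index(surfaces[[1]], am[b, 1]),
                  bin_index(surfaces[[1]], am[b, 2])], integer(1))
    consistent <- length(unique(labs)) == 1 && all(labs != 0L)
  }
  list(rms = rms, argmins = am, argmin_distance = dist1,
       consistent = consistent)
}

#' Crop a surface in phi for reporting
#'
#' Returns a view restricted to a phi-range, as used when plotting only
#' the low-free-energy half of the torus; analyses always operate on the
#' full periodic surface, the view only selects rows for display.
#'
#' @param fes scalar [grid2d()].
#' @param phi_range c(lo, hi) in degrees, lo <= hi within [-180, 180].
#' @return object of class `fes_view` with `phi_centers`, `psi_centers`,
#'   `values` (sub-matrix) and the parent surface.
#' @export
crop_phi_report <- function(fes, phi_range) {
  if (length(phi_range) != 2 || phi_range[1] > phi_range[2])
    stop("crop_phi_report: phi_range must be c(lo, hi)")
  keep <- fes$centers >= phi_range[1] & fes$centers <= phi_range[2]
  structure(list(phi_centers = fes$centers[keep], psi_centers = fes$centers,
                 values = fes$values[keep, , drop = FALSE], parent = fes),
            class = "fes_view")
}

#' @export
value_at.fes_view <- function(fes, phi, psi) value_at(fes$parent, phi, psi)
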