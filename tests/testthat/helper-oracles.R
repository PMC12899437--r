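# Independent oracles used to freeze expected values. These reimplement the
# checked quantities from their definitions, on code paths separate from the
# package implementation.

# direct-summation Cremer-Pople forward transform
oracle_cp <- function(coords) {
  r <- sweep(coords, 2, colMeans(coords))
  j <- 0:5
  R1 <- colSums(r * sin(2 * pi * j / 6))
  R2 <- colSums(r * cos(2 * pi * j / 6))
  n <- c(R1[2] * R2[3] - R1[3] * R2[2],
         R1[3] * R2[1] - R1[1] * R2[3],
         R1[1] * R2[2] - R1[2] * R2[1])
  n <- n / sqrt(sum(n^2))
  z <- as.numeric(r %*% n)
  qc <- sqrt(2 / 6) * sum(z * cos(4 * pi * j / 6))
  qs <- -sqrt(2 / 6) * sum(z * sin(4 * pi * j / 6))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(qc^2 + qs^2)
  list(Q = sqrt(sum(z^2)), theta = atan2(q2, q3) * 180 / pi,
       phi = (atan2(qs, qc) * 180 / pi) %% 360)
}

# dihedral via projection onto the plane perpendicular to the central bond
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  gagfes::wrap_angle(atan2(sum(cr * b), sum(u * v)) * 180 / pi)
}

# minimax crossing level between two cells of a periodic grid: the smallest
# level c (scanned over sorted cell values) at which a breadth-first search
# over cells with value <= c connects start and goal
oracle_minimax_level <- function(v, start, goal) {
  n <- nrow(v)
  for (c in sort(unique(as.numeric(v)))) {
    open <- v <= c
    if (!open[start[1], start[2]] || !open[goal[1], goal[2]]) next
    seen <- matrix(FALSE, n, n)
    queue <- list(start)
    seen[start[1], start[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (cur[1] == goal[1] && cur[2] == goal[2]) return(c)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- ((cur[1] - 1 + di) %% n) + 1
        jj <- ((cur[2] - 1 + dj) %% n) + 1
        if (open[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  NA_real_
}

# exhaustive simple-path enumeration (depth-first with an upper-bound prune)
# for the minimax crossing level on tiny periodic grids
oracle_minimax_paths <- function(v, start, goal) {
  n <- nrow(v)
  best <- Inf
  seen <- matrix(FALSE, n, n)
  rec <- function(i, j, mx) {
    mx <- max(mx, v[i, j])
    if (mx >= best) return()
    if (i == goal[1] && j == goal[2]) { best <<- mx; return() }
    seen[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- ((i - 1 + di) %% n) + 1
      jj <- ((j - 1 + dj) %% n) + 1
      if (!seen[ii, jj]) rec(ii, jj, mx)
    }
    seen[i, j] <<- FALSE
  }
  rec(start[1], start[2], -Inf)
  best
}

# steepest-descent basin assignment by explicit path following (the
# tie-break: lowest (value, lexicographic row-major index) neighbor)
oracle_descend <- function(v, i, j, minima) {
  n <- nrow(v)
  lex <- function(i, j) (i - 1) * n + j
  repeat {
    hit <- which(minima$i == i & minima$j == j)
    if (length(hit)) return(hit)
    best <- NULL
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- ((i - 1 + di) %% n) + 1
      jj <- ((j - 1 + dj) %% n) + 1
      if (v[ii, jj] < v[i, j] ||
          (v[ii, jj] == v[i, j] && lex(ii, jj) < lex(i, j))) {
        if (is.null(best) || v[ii, jj] < v[best[1], best[2]] ||
            (v[ii, jj] == v[best[1], best[2]] &&
             lex(ii, jj) < lex(best[1], best[2])))
          best <- c(ii, jj)
      }
    }
    if (is.null(best)) return(0L)
    i <- best[1]; j <- best[2]
  }
}

# designed toy landscapes are expensive; build once per session on demand
.toy_cache <- new.env(parent = emptyenv())
get_designed_toy <- function(barrier) {
  key <- paste0("b", barrier)
  if (is.null(.toy_cache[[key]]))
    .toy_cache[[key]] <- design_two_basin(barrier)
  .toy_cache[[key]]
}
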