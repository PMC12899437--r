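test_that("find_local_minima handles wells, plateaus and constants", {
  p <- toy_potential(data.frame(phi = 30, psi = -50, depth = 4, kappa = 6))
  fes <- normalize_min_zero(potential_grid(p, 72))
  mins <- find_local_minima(fes, ceiling = Inf)
  expect_equal(nrow(mins), 1)
  expect_equal(c(mins$phi, mins$psi), c(30, -50))
  ## constant surface: no strict minima
  const <- normalize_min_zero(grid2d(12, values = matrix(1, 12, 12)))
  expect_equal(nrow(find_local_minima(const, ceiling = Inf)), 0)
  ## plateau collapses to its lexicographically smallest bin
  v <- matrix(5, 12, 12)
  v[4:5, 7:8] <- 1
  fes2 <- grid2d(12, values = v)
  mins2 <- find_local_minima(fes2, ceiling = Inf)
  expect_equal(nrow(mins2), 1)
  expect_equal(c(mins2$i, mins2$j), c(4, 7))
  ## ceiling filters reported minima
  expect_equal(nrow(find_local_minima(fes, ceiling = 0)), 0)
})

test_that("two-basin landscapes yield two minima at the construction centers", {
  p <- get_designed_toy(4)
  fes <- normalize_min_zero(potential_grid(p))
  mins <- find_local_minima(fes, ceiling = 3)
  expect_equal(nrow(mins), 2)
  expect_equal(mins$phi, c(-77.5, -97.5))
  expect_equal(mins$psi, c(132.5, -80))
  expect_equal(mins$dG[1], 0)
  expect_equal(mins$dG[2], 1.3, tolerance = 0.05)
})

test_that("segment_basins matches explicit steepest-descent path following", {
  set.seed(14)
  v <- matrix(rnorm(144), 12, 12)
  fes <- normalize_min_zero(grid2d(12, values = v))
  mins <- find_local_minima(fes, ceiling = Inf)
  dec <- segment_basins(fes, mins, ceiling = Inf)
  for (i in 1:12) for (j in 1:12) {
    expect_equal(dec$labels[i, j],
                 as.integer(oracle_descend(fes$values, i, j, mins)),
                 info = sprintf("bin (%d,%d)", i, j))
  }
  ## symmetric double well splits the torus into two equal basins
  g <- grid2d(36)
  sym <- normalize_min_zero(grid2d(36, values = outer(
    g$centers, g$centers, function(x, y) -cos(2 * pi * x / 180))))
  mins_s <- find_local_minima(sym, ceiling = Inf)
  dec_s <- segment_basins(sym, mins_s, ceiling = Inf)
  expect_equal(nrow(mins_s), 2)
  expect_equal(sum(dec_s$labels == 1), sum(dec_s$labels == 2))
  ## bins above the ceiling stay unlabeled
  dec_c <- segment_basins(sym, mins_s, ceiling = 1)
  expect_true(all(dec_c$labels[sym$values > 1] == 0))
})

test_that("minimax saddles equal the exhaustive level/path oracles on small grids", {
  set.seed(15)
  for (n in 3:7) {
    for (rep in 1:3) {
      v <- matrix(sample(1:9, n * n, replace = TRUE) +
                  runif(n * n) / 10, n, n)
      fes <- normalize_min_zero(grid2d(n, values = v))
      mins <- find_local_minima(fes, ceiling = Inf)
      if (nrow(mins) < 2) next
      S <- saddle_matrix(fes, mins)
      for (a in 1:(nrow(mins) - 1)) for (b in (a + 1):nrow(mins)) {
        lev <- oracle_minimax_level(fes$values, c(mins$i[a], mins$j[a]),
                                    c(mins$i[b], mins$j[b]))
        expect_equal(S[a, b], lev, tolerance = 1e-12)
        if (n <= 4) {
          pth <- oracle_minimax_paths(fes$values,
                                      c(mins$i[a], mins$j[a]),
                                      c(mins$i[b], mins$j[b]))
          expect_equal(S[a, b], pth, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("escape barriers are directional and symmetric through the saddle", {
  p <- get_designed_toy(4)
  fes <- normalize_min_zero(potential_grid(p))
  mins <- find_local_minima(fes, ceiling = Inf)
  dec <- segment_basins(fes, mins, ceiling = Inf)
  b12 <- barrier_height(dec, fes, 1, 2)
  b21 <- barrier_height(dec, fes, 2, 1)
  expect_equal(barrier_height(dec, fes, 1, 1), 0)
  ## escape barriers differ by exactly the minimum offset
  expect_equal(b12 - b21, mins$dG[2] - mins$dG[1], tolerance = 1e-12)
  expect_lt(abs(b21 - 4), 0.1)
  expect_error(barrier_height(dec, fes, 1, 5), "out of range")
})

test_that("quadrant labels follow the sign convention", {
  expect_equal(quadrant(-77.5, 132.5), "(-,+)")
  expect_equal(quadrant(82.5, 95.0), "(+,+)")
  expect_equal(quadrant(-97.5, -80.0), "(-,-)")
  expect_equal(quadrant(30, -10), "(+,-)")
  expect_equal(quadrant(0, 0), "(+,+)")       # zero counts as positive
  expect_equal(quadrant(360, -360), "(+,+)")  # wrapped first
})

test_that("basin extents match analytic contours and handle wrap", {
  ## circular well: contour at half depth has a known analytic radius
  kT_depth <- 5; kap <- 6
  p <- toy_potential(data.frame(phi = 0, psi = 0, depth = kT_depth,
                                kappa = kap))
  fes <- normalize_min_zero(potential_grid(p, 144))
  mins <- find_local_minima(fes, ceiling = Inf)
  dec <- segment_basins(fes, mins, ceiling = Inf)
  ext <- basin_extent(dec, fes, 1, level = kT_depth / 2)
  ## 1D cut: depth*(1 - exp(kap*(cos x - 1))) = depth/2
  xr <- acos(1 + log(0.5) / kap) * 180 / pi
  expect_equal(ext$phi[2], xr, tolerance = fes$width + 1e-9)
  expect_equal(ext$phi[1], -xr, tolerance = fes$width + 1e-9)
  ## full-circle coverage at an unreachable level
  ext_all <- basin_extent(dec, fes, 1, level = Inf)
  expect_equal(ext_all$phi, c(-180, 180))
  ## wrap-straddling well reported as one interval crossing the seam
  pw <- toy_potential(data.frame(phi = 180, psi = 0, depth = 5, kappa = 6))
  fw <- normalize_min_zero(potential_grid(pw, 144))
  mw <- find_local_minima(fw, ceiling = Inf)
  dw <- segment_basins(fw, mw, ceiling = Inf)
  extw <- basin_extent(dw, fw, 1, level = 2.5)
  expect_lt(extw$phi[1], 180)
  expect_gt(extw$phi[2], 180)   # upper bound beyond +180 marks the crossing
  ## level below the basin minimum: empty interval
  expect_true(all(is.na(basin_extent(dec, fes, 1, level = -1)$phi)))
})

test_that("compare_replicates reports RMS and a consistency verdict", {
  p <- get_designed_toy(4)
  fes <- normalize_min_zero(potential_grid(p, 72))
  rep1 <- fes
  rep2 <- fes; rep2$values <- rep2$values + 3   # constant offset
  out <- compare_replicates(list(rep1, rep2))
  expect_equal(out$rms[1, 2], 0, tolerance = 1e-12)
  expect_true(out$consistent)
  ## argmin moved to another quadrant: inconsistent
  v3 <- fes$values
  v3[bin_index(fes, 100), bin_index(fes, -100)] <- -0.5
  rep3 <- grid2d(72, values = v3)
  out3 <- compare_replicates(list(rep1, rep3))
  expect_false(out3$consistent)
  expect_error(compare_replicates(list(rep1, normalize_min_zero(grid2d(36)))),
               "grid mismatch")
})

test_that("min_shift takes the minimal periodic image of the argmin difference", {
  mk <- function(phi, psi) {
    g <- grid2d(144)
    v <- matrix(0, 144, 144)
    v[bin_index(g, phi), bin_index(g, psi)] <- -1
    normalize_min_zero(grid2d(144, values = v))
  }
  expect_equal(min_shift(mk(-77.5, 132.5), mk(-77.5, 132.5)),
               c(dphi = 0, dpsi = 0))
  expect_equal(min_shift(mk(-77.5, 132.5), mk(-55.0, 135.0)),
               c(dphi = 22.5, dpsi = 2.5))
  expect_equal(min_shift(mk(-177.5, 0), mk(177.5, 0)),
               c(dphi = -5, dpsi = 0))
})

test_that("adding a constant before normalization changes no analysis output", {
  p <- get_designed_toy(4)
  f1 <- normalize_min_zero(potential_grid(p, 72))
  shifted <- potential_grid(p, 72)
  shifted$values <- shifted$values + 11.7
  f2 <- normalize_min_zero(shifted)
  m1 <- find_local_minima(f1, 3); m2 <- find_local_minima(f2, 3)
  expect_equal(m1, m2, tolerance = 1e-12)
  d1 <- segment_basins(f1, m1, 15); d2 <- segment_basins(f2, m2, 15)
  expect_identical(d1$labels, d2$labels)
  expect_equal(d1$saddle, d2$saddle, tolerance = 1e-12)
})

test_that("crop_phi_report is a view that leaves analysis untouched", {
  p <- get_designed_toy(4)
  fes <- normalize_min_zero(potential_grid(p, 72))
  crop <- crop_phi_report(fes, c(-180, 0))
  expect_true(all(crop$phi_centers <= 0))
  expect_equal(value_at(crop, -77.5, 132.5), value_at(fes, -77.5, 132.5))
  full <- crop_phi_report(fes, c(-180, 180))
  expect_equal(full$values, fes$values)
  ## a minimum outside the crop is still found by full analysis
  mins <- find_local_minima(fes, ceiling = 3)
  crop2 <- crop_phi_report(fes, c(0, 180))
  expect_true(all(mins$phi < 0))   # both minima lie outside this crop
  expect_equal(nrow(mins), 2)
  expect_error(crop_phi_report(fes, c(10, -10)), "lo, hi")
})
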