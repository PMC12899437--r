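test_that("grid construction, binning and lookup follow the center convention", {
  g <- grid2d(144)
  expect_equal(g$width, 2.5)
  expect_true(-77.5 %in% g$centers)    # reporting lattice is on bin centers
  expect_equal(bin_index(g, -180), bin_index(g, 180))
  v <- matrix(rnorm(144^2), 144, 144)
  fes <- grid2d(144, values = v)
  i <- bin_index(fes, -77.5); j <- bin_index(fes, 132.5)
  expect_equal(value_at(fes, -77.5, 132.5), v[i, j])
  expect_equal(value_at(fes, -77.5 + 360, 132.5 - 720), v[i, j])
  ## nearest-bin choice agrees with an exhaustive distance check
  set.seed(10)
  for (k in 1:50) {
    x <- runif(1, -180, 180)
    d <- abs(periodic_diff(rep(x, 144), g$centers))
    expect_equal(bin_index(g, x), which.min(d))
  }
  expect_error(grid2d(100, width = 2.5), "must equal 360")
})

test_that("min-zero normalization records the argmin and kills constants", {
  v <- matrix(rnorm(36^2, 10), 36, 36)
  fes <- normalize_min_zero(grid2d(36, values = v))
  expect_equal(min(fes$values), 0)
  i <- arrayInd(which.min(v), dim(v))
  expect_equal(attr(fes, "argmin"),
               c(phi = fes$centers[i[1]], psi = fes$centers[i[2]]))
  fes2 <- normalize_min_zero(grid2d(36, values = v + 7.3))
  expect_equal(fes2$values, fes$values, tolerance = 1e-12)
  const <- normalize_min_zero(grid2d(36, values = matrix(4, 36, 36)))
  expect_true(all(const$values == 0))
})

test_that("abf_bias_force ramps with bin occupancy", {
  st <- eabf_state(nbins = 8, N_full = 200)
  expect_equal(abf_bias_force(st, 3, 5), c(0, 0))
  st$count_lambda[3, 5] <- 100
  st$sum_spring_phi[3, 5] <- 100 * 0.4
  st$sum_spring_psi[3, 5] <- 100 * (-0.1)
  expect_equal(abf_bias_force(st, 3, 5), c(0.2, -0.05))   # half ramp
  st$count_lambda[3, 5] <- 350
  st$sum_spring_phi[3, 5] <- 350 * 0.4
  st$sum_spring_psi[3, 5] <- 350 * (-0.1)
  expect_equal(abf_bias_force(st, 3, 5), c(0.4, -0.1))    # saturated
})

test_that("czar gradient vanishes for uniform density with centered springs", {
  st <- eabf_state(nbins = 24)
  st$count_z[] <- 50
  st$count_lambda[] <- 50
  g <- czar_gradient(st)
  expect_equal(max(abs(g$values)), 0)
  expect_error(czar_gradient(eabf_state(nbins = 24)), "no samples")
})

test_that("czar recovers the potential gradient from direct Boltzmann samples", {
  ## z sampled from exp(-U/kT), lambda == z: the spring term vanishes and
  ## -kT grad ln rho must equal grad U
  p <- toy_potential(data.frame(phi = -60, psi = 40, depth = 3, kappa = 2))
  n <- 36
  g <- grid2d(n)
  kT <- BOLTZMANN_KCAL * 298
  U <- matrix(potential_value_grad(
    p, rep(g$centers, n), rep(g$centers, each = n))$U, n, n)
  w <- exp(-U / kT)
  set.seed(17)
  counts <- matrix(stats::rmultinom(1, 5e6, as.numeric(w / sum(w))), n, n)
  st <- eabf_state(nbins = n)
  st$count_z <- counts
  st$count_lambda <- counts
  grad <- czar_gradient(st)
  gx_true <- matrix(potential_value_grad(
    p, rep(g$centers, n), rep(g$centers, each = n))$dUdx, n, n)
  sel <- U - min(U) < 3        # well-populated region
  expect_lt(max(abs(grad$values[, , 1][sel] - gx_true[sel])), 0.05)
})

test_that("poisson_integrate exactly inverts a discrete gradient", {
  n <- 144
  g <- grid2d(n)
  A <- outer(g$centers, g$centers,
             function(x, y) cos(pi * x / 180) + 0.5 * cos(2 * pi * y / 180))
  ip <- c(n, 1:(n - 1)); im <- c(2:n, 1); h <- g$width
  G <- array(c((A[im, ] - A[ip, ]) / (2 * h),
               (A[, im] - A[, ip]) / (2 * h)), c(n, n, 2))
  fes <- poisson_integrate(grid2d(n, values = G))
  expect_lt(max(abs(fes$values - (A - min(A)))), 1e-9)
  expect_lt(attr(fes, "residual"), 1e-12)
  ## zero field integrates to a flat zero surface
  flat <- poisson_integrate(grid2d(12, values = array(0, c(12, 12, 2))))
  expect_true(all(flat$values == 0))
})

test_that("poisson_integrate is the least-squares potential for noisy gradients", {
  n <- 48
  g <- grid2d(n)
  A <- outer(g$centers, g$centers,
             function(x, y) 2 * cos(pi * x / 180) * sin(2 * pi * y / 180))
  ip <- c(n, 1:(n - 1)); im <- c(2:n, 1); h <- g$width
  set.seed(21)
  eps <- array(rnorm(2 * n^2, 0, 0.01), c(n, n, 2))
  G <- array(c((A[im, ] - A[ip, ]) / (2 * h),
               (A[, im] - A[, ip]) / (2 * h)), c(n, n, 2)) + eps
  fes <- poisson_integrate(grid2d(n, values = G))
  ## least-squares projection: the residual cannot exceed the perturbation
  expect_lte(attr(fes, "residual"), sqrt(mean(eps^2)))
  ## linearity: the noisy solution differs from the clean one by exactly the
  ## integrated noise field (up to the normalization constant)
  clean <- poisson_integrate(grid2d(n, values = G - eps))
  noise_only <- poisson_integrate(grid2d(n, values = eps))
  d <- fes$values - clean$values - noise_only$values
  expect_lt(max(d) - min(d), 1e-9)
  ## missing-bin filling: punch holes, expect a finite surface
  G[5, 7, ] <- NA
  fes2 <- poisson_integrate(grid2d(n, values = G))
  expect_true(all(is.finite(fes2$values)))
  expect_error(poisson_integrate(grid2d(n, values = G), fill = "none"),
               "missing")
})

test_that("the estimate is symmetric under joint axis relabeling", {
  p <- get_designed_toy(4)
  cfg <- sampler_config(n_steps = 2e5, seed = 31, bias = "eabf", nbins = 72,
                        start = c(-77.5, 132.5))
  st <- attr(run_langevin(p, cfg), "eabf_state")
  fes <- poisson_integrate(czar_gradient(st))
  ## transpose the accumulated statistics = swap phi and psi everywhere
  st_t <- st
  st_t$count_z <- t(st$count_z)
  st_t$count_lambda <- t(st$count_lambda)
  st_t$sum_dlambda_phi <- t(st$sum_dlambda_psi)
  st_t$sum_dlambda_psi <- t(st$sum_dlambda_phi)
  st_t$sum_spring_phi <- t(st$sum_spring_psi)
  st_t$sum_spring_psi <- t(st$sum_spring_phi)
  fes_t <- poisson_integrate(czar_gradient(st_t))
  expect_equal(fes_t$values, t(fes$values), tolerance = 1e-9)
})

test_that("doubling the sampling budget reduces the recovery error", {
  p <- get_designed_toy(4)
  truth <- normalize_min_zero(potential_grid(p, 72))
  err_at <- function(n_steps) {
    states <- lapply(1:2, function(s) {
      cfg <- sampler_config(n_steps = n_steps, seed = s, bias = "eabf",
                            nbins = 72, start = c(-77.5, 132.5))
      attr(run_langevin(p, cfg), "eabf_state")
    })
    fes <- poisson_integrate(czar_gradient(merge_eabf_states(states)))
    reg <- truth$values < 5
    sqrt(mean((fes$values[reg] - truth$values[reg])^2))
  }
  expect_lt(err_at(8e5), err_at(2e5))
})

test_that("colvars-style grid files round-trip bit-exactly", {
  set.seed(12)
  pmf <- grid2d(36, values = matrix(rnorm(36^2), 36, 36))
  f <- tempfile(fileext = ".pmf")
  write_colvars_grid(pmf, f)
  rd <- read_colvars_grid(f)
  expect_identical(rd$values, pmf$values)
  expect_equal(rd$width, pmf$width)
  grad <- grid2d(24, values = array(rnorm(2 * 24^2), c(24, 24, 2)))
  f2 <- tempfile(fileext = ".grad")
  write_colvars_grid(grad, f2)
  rd2 <- read_colvars_grid(f2)
  expect_identical(rd2$values, grad$values)
  ## and the header is the documented Colvars-style layout
  lines <- readLines(f)
  expect_identical(trimws(lines[1]), "# 2")
  expect_match(lines[2], "^# .* 36 1$")
  suppressWarnings(expect_error(read_colvars_grid(tempfile())))
})
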