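test_that("forward/inverse Cremer-Pople transforms are mutual inverses", {
  set.seed(42)
  for (k in 1:1000) {
    Q <- runif(1, 0.3, 0.9)
    th <- runif(1, 1, 179)   # away from the poles so phi is defined
    ph <- runif(1, 0, 360)
    p <- cremer_pople(inverse_cremer_pople(Q, th, ph))
    expect_lt(abs(p$Q - Q), 1e-9)
    expect_lt(abs(p$theta - th), 1e-6)
    expect_lt(abs(periodic_diff(p$phi, ph)), 1e-6)
  }
})

test_that("cremer_pople pins the pyranose anchor states", {
  expect_equal(cremer_pople(inverse_cremer_pople(0.55, 0, 0))$theta, 0,
               tolerance = 1e-9)
  chair <- cremer_pople(inverse_cremer_pople(0.57, 180, 0))
  expect_equal(chair$theta, 180, tolerance = 1e-9)
  expect_false(chair$phi_defined)
  so <- cremer_pople(inverse_cremer_pople(0.76, 90, 150))
  expect_equal(c(so$Q, so$theta, so$phi), c(0.76, 90, 150), tolerance = 1e-6)
  b3o <- cremer_pople(inverse_cremer_pople(0.76, 90, 180))
  expect_equal(c(b3o$theta, b3o$phi), c(90, 180), tolerance = 1e-6)
})

test_that("cremer_pople agrees with the direct-summation oracle", {
  set.seed(7)
  for (k in 1:50) {
    r <- inverse_cremer_pople(runif(1, 0.3, 0.9), runif(1, 5, 175),
                              runif(1, 0, 360))
    co <- r$coords + matrix(rnorm(18, 0, 0.02), 6, 3)  # break exactness
    got <- cremer_pople(ring_conformer(co))
    ref <- oracle_cp(co)
    expect_equal(got$Q, ref$Q, tolerance = 1e-9)
    expect_equal(got$theta, ref$theta, tolerance = 1e-9)
    expect_lt(abs(periodic_diff(got$phi, ref$phi)), 1e-9)
  }
})

test_that("degenerate rings are rejected with informative errors", {
  hex <- inverse_cremer_pople(0.5, 90, 0)$coords
  hex[, 3] <- 0
  expect_error(cremer_pople(ring_conformer(hex)), "planar")
  expect_error(ring_conformer(matrix(0, 5, 3)), "6 x 3")
  expect_error(inverse_cremer_pople(0, 90, 0), "Q must be > 0")
  expect_error(inverse_cremer_pople(-1, 90, 0), "Q must be > 0")
})

test_that("cremer_pople is invariant under rigid motion and flips under reversal", {
  r <- inverse_cremer_pople(0.6, 67, 123)
  p0 <- cremer_pople(r)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- r$coords %*% R + matrix(rep(c(3, -2, 5), each = 6), 6, 3)
  p1 <- cremer_pople(ring_conformer(moved))
  expect_equal(p1$Q, p0$Q, tolerance = 1e-9)
  expect_equal(p1$theta, p0$theta, tolerance = 1e-9)
  expect_equal(p1$phi, p0$phi, tolerance = 1e-9)
  ## reversing the traversal direction inverts the polar angle
  rev <- ring_conformer(r$coords[c(1, 6, 5, 4, 3, 2), ])
  expect_equal(cremer_pople(rev)$theta, 180 - p0$theta, tolerance = 1e-9)
})

test_that("pucker_name maps ideal vertices of all 38 canonical forms to themselves", {
  cat <- pucker_catalog()
  for (k in seq_len(nrow(cat))) {
    p <- pucker_params(0.57, cat$theta[k],
                       if (cat$chair[k]) NA else cat$phi[k])
    expect_identical(pucker_name(p), cat$name[k])
  }
})

test_that("pucker_name matches a brute-force distance scan off-vertex", {
  cat <- pucker_catalog()
  brute <- function(theta, phi) {
    d <- vapply(seq_len(nrow(cat)), function(i) {
      t2 <- cat$theta[i] * pi / 180
      p2 <- ifelse(is.na(cat$phi[i]), 0, cat$phi[i]) * pi / 180
      t1 <- theta * pi / 180; p1 <- phi * pi / 180
      acos(pmin(pmax(cos(t1) * cos(t2) +
                     sin(t1) * sin(t2) * cos(p1 - p2), -1), 1))
    }, numeric(1))
    cat$name[which.min(d)]
  }
  expect_identical(pucker_name(pucker_params(0.6, 89, 165)), brute(89, 165))
  set.seed(11)
  for (k in 1:100) {
    th <- runif(1, 2, 178); ph <- runif(1, 0, 360)
    expect_identical(pucker_name(pucker_params(0.6, th, ph)), brute(th, ph))
  }
  ## chairs resolvable without phi; equatorial region is not
  expect_identical(pucker_name(pucker_params(0.6, 178, NA)), "1C4")
  expect_identical(pucker_name(pucker_params(0.6, 3, NA)), "4C1")
  expect_error(pucker_name(pucker_params(0.6, 90, NA)), "disambiguate")
})

test_that("idealness_score follows the chair/equatorial two-term rule", {
  states <- ido_pucker_states()
  expect_equal(idealness_score(pucker_params(0.57, 180, NA), states[["1C4"]]), 0)
  expect_equal(idealness_score(pucker_params(0.57, 179.72, NA),
                               states[["1C4"]]), 0.0784)
  expect_equal(idealness_score(pucker_params(0.6, 89.92, 149.87),
                               states[["2SO"]]), 0.08^2 + 0.13^2)
  ## phi enters through the minimal image
  expect_equal(idealness_score(pucker_params(0.6, 90, 150 + 360),
                               states[["2SO"]]), 0)
})

test_that("reference pucker rows score minimal idealness against their own target", {
  states <- ido_pucker_states()
  for (nm in names(states)) {
    s <- states[[nm]]
    p <- pucker_params(0.57, s$theta0, s$phi0)
    scores <- vapply(states, function(t) idealness_score(p, t), numeric(1))
    expect_identical(names(which.min(scores)), nm)
  }
})

test_that("select_most_ideal returns the exhaustive-scan minimizer", {
  target <- ido_pucker_states("2SO")
  ens <- make_ring_ensemble(target, 100, jitter_deg = 4, seed = 3)
  got <- select_most_ideal(ens, target)
  scores <- vapply(ens, function(cf)
    idealness_score(cremer_pople(cf), target), numeric(1))
  expect_identical(got$index, which.min(scores))
  expect_equal(got$score, min(scores))
  ## an exact-ideal member wins with score 0
  ens2 <- c(ens, list(inverse_cremer_pople(0.57, 90, 150)))
  got2 <- select_most_ideal(ens2, target)
  expect_identical(got2$index, 101L)
  expect_equal(got2$score, 0, tolerance = 1e-18)
  expect_error(select_most_ideal(list(), target), "empty")
})

test_that("ring_dihedrals follows the cyclic quadruple convention", {
  chair <- inverse_cremer_pople(0.57, 180, 0)
  Phi <- ring_dihedrals(chair)
  expect_true(all(sign(Phi) == c(-1, 1, -1, 1, -1, 1)))
  expect_identical(ring_dihedrals(chair), Phi)  # deterministic
  ## against the independent dihedral oracle
  r <- inverse_cremer_pople(0.6, 80, 200)$coords
  idx <- function(k) ((k - 1) %% 6) + 1
  ref <- vapply(1:6, function(i)
    oracle_dihedral(r[idx(i), ], r[idx(i + 1), ], r[idx(i + 2), ],
                    r[idx(i + 3), ]), numeric(1))
  expect_equal(ring_dihedrals(ring_conformer(r)), ref, tolerance = 1e-9)
})

test_that("reference ring dihedral sign patterns match the pucker states", {
  ## the near-ideal reference rings reproduce the stored Phi0 sign patterns
  for (nm in c("1C4", "2SO", "B3O", "4C1")) {
    s <- ido_pucker_states(nm)
    ring <- inverse_cremer_pople(0.57, s$theta0,
                                 if (is.na(s$phi0)) 0 else s$phi0)
    Phi <- ring_dihedrals(ring)
    agree <- sign(Phi) == sign(s$Phi0) | abs(s$Phi0) < 5
    expect_true(all(agree), info = nm)
  }
})
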