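# MBAR, overlap diagnostics, TI integration, repeat aggregation and the
# thermodynamic-cycle combination

test_that("equilibration discard follows the floor rule", {
  mk <- function(n) new_trajectory(array(rnorm(n * 2 * 3), c(n, 2, 3)),
                                   boxes = rep(10, n), volumes = rep(1000, n),
                                   state_index = 1L, seed = 1L)
  saisolv_ns <- asNamespace("saisolv")
  expect_equal(discard_equilibration(mk(10000), 0.25)$n_frames, 7500L)
  expect_equal(discard_equilibration(mk(7), 0.25)$n_frames, 6L)
  expect_equal(discard_equilibration(mk(12), 0)$n_frames, 12L)
  expect_error(discard_equilibration(mk(5), 1), "fraction")
})

test_that("reduced-potential matrix: constant rows for identical states, pair-sum differences", {
  sys <- make_small_system(n_heavy = 2, n_h = 1, n_waters = 6, seed = 51)
  st <- toy_settings()
  sch <- build_schedule(sys$solute)
  tr <- mc_sample(sys, sch$states[[1]], st, n_sweeps = 40, n_tune = 20,
                  save_every = 4, seed = 3)
  # duplicated physical state: identical columns
  fake <- sch; fake$states <- sch$states[c(1, 1)]
  em <- reduced_potential_matrix(list(tr, tr), fake, sys, st)
  expect_equal(em$u[, 1], em$u[, 2])
  expect_equal(sum(em$N_k), nrow(em$u))
  # two states differing by one dummied atom: u difference = beta * that
  # atom's pair-energy sum (brute-force oracle)
  st2 <- sch$states[[1]]
  st2$lj_scale[2] <- 0; st2$charge_scale[2] <- 0
  # build the explicitly dummied system for the oracle
  sys2 <- sys; sys2$solute <- make_dummy_parameters(sys$solute, 2L)
  one <- sys
  one$solute_xyz <- tr$frames[1, 1:3, ]
  one$water_xyz <- tr$frames[1, 4:dim(tr$frames)[2], ]
  sys2$solute_xyz <- one$solute_xyz; sys2$water_xyz <- one$water_xyz
  fake2 <- sch; fake2$states <- list(sch$states[[1]], st2)
  tr1 <- tr; tr1$frames <- tr$frames[1, , , drop = FALSE]
  tr1$boxes <- tr$boxes[1]; tr1$volumes <- tr$volumes[1]; tr1$n_frames <- 1L
  em2 <- reduced_potential_matrix(list(tr1, tr1), fake2, sys, st)
  beta <- 1 / (kB_test * st$temperature)
  e_full <- sum(oracle_total_energy(one, NULL, st))
  e_dummy <- sum(oracle_total_energy(sys2, NULL, st))
  expect_equal(em2$u[1, 1] - em2$u[1, 2], beta * (e_full - e_dummy),
               tolerance = 1e-8)
  expect_error(reduced_potential_matrix(list(tr), sch, sys, st),
               "one trajectory per state")
})

test_that("MBAR: identical states give zero, harmonic pairs give log-ratio / 2", {
  # two identical states
  set.seed(4)
  x <- rnorm(500)
  u <- cbind(0.5 * x^2, 0.5 * x^2)
  fit <- mbar_solve(energy_matrix(u, c(250, 250)))
  expect_lt(abs(fit$f[2]), 1e-10)
  # harmonic states k and 4k: delta f = log(2) within 3 SE
  set.seed(11)
  n <- 3000
  x <- c(rnorm(n, 0, 1), rnorm(n, 0, 0.5))
  u <- cbind(0.5 * x^2, 0.5 * 4 * x^2)
  em <- energy_matrix(u, c(n, n))
  fit <- mbar_solve(em)
  se <- mbar_bootstrap_stderr(em, B = 30, seed = 2)
  expect_lt(abs(fit$f[2] - log(2)), 3 * se)
})

test_that("MBAR agrees with an independent objective-minimisation solution to 1e-6", {
  for (seed in 1:5) {
    em <- random_gaussian_matrix(K = 4, n_per = 400, seed = seed)
    fit <- mbar_solve(em)
    ref <- oracle_mbar(em$u, em$N_k)
    expect_lt(max(abs(fit$f - ref)), 1e-6)
  }
})

test_that("MBAR antisymmetry and cycle closure hold by construction", {
  em <- random_gaussian_matrix(K = 5, n_per = 300, seed = 9)
  fit <- mbar_solve(em)
  expect_equal(mbar_delta_f(fit, 2, 4), -mbar_delta_f(fit, 4, 2))
  loop <- mbar_delta_f(fit, 1, 3) + mbar_delta_f(fit, 3, 5) +
    mbar_delta_f(fit, 5, 2) + mbar_delta_f(fit, 2, 1)
  expect_equal(loop, 0)
})

test_that("MBAR harmonic recovery across random force-constant pairs", {
  set.seed(2024)
  for (rep in 1:4) {
    k1 <- runif(1, 0.5, 4); k2 <- k1 * runif(1, 1.2, 6)
    n <- 2500
    x <- c(rnorm(n, 0, sqrt(1 / k1)), rnorm(n, 0, sqrt(1 / k2)))
    u <- cbind(0.5 * k1 * x^2, 0.5 * k2 * x^2)
    em <- energy_matrix(u, c(n, n))
    fit <- mbar_solve(em)
    se <- mbar_bootstrap_stderr(em, B = 40, seed = rep)
    expect_lt(abs(fit$f[2] - 0.5 * log(k2 / k1)), 3 * max(se, 2e-3))
  }
})

test_that("overlap matrix is row-stochastic and flags disjoint states", {
  # identical states: uniform mixing structure
  set.seed(5)
  x <- rnorm(800)
  u <- cbind(0.5 * x^2, 0.5 * x^2)
  fit <- mbar_solve(energy_matrix(u, c(400, 400)))
  O <- overlap_matrix(fit)
  expect_equal(rowSums(O), c(1, 1), tolerance = 1e-8)
  expect_equal(O[1, 1], 0.5, tolerance = 1e-6)
  # non-overlapping harmonic states (means 10 sigma apart): off-diagonal
  # ~ 0 and a warning
  set.seed(6)
  y <- c(rnorm(400, 0, 1), rnorm(400, 10, 1))
  u2 <- cbind(0.5 * y^2, 0.5 * (y - 10)^2)
  fit2 <- mbar_solve(energy_matrix(u2, c(400, 400)))
  expect_warning(O2 <- overlap_matrix(fit2), "overlap")
  expect_lt(O2[1, 2], 1e-6)
  # random matrices: rows sum to one
  for (seed in 1:3) {
    em <- random_gaussian_matrix(K = 4, n_per = 200, seed = seed + 40)
    O3 <- suppressWarnings(overlap_matrix(mbar_solve(em)))
    expect_equal(rowSums(O3), rep(1, 4), tolerance = 1e-8)
  }
})

test_that("TI spline integration: constants exact, smooth profiles vs oracles", {
  lam <- seq(0, 1, length.out = 21)
  # constant dU/dl = c integrates to c exactly
  expect_equal(ti_estimate(ti_profile(lam, rep(2.5, 21)))$delta_g, 2.5)
  # cubic profile: analytic integral of 3 l^2 is 1; the natural spline is
  # accurate to O(h^2) at the boundary, not exact
  est <- ti_estimate(ti_profile(lam, 3 * lam^2))
  expect_equal(est$delta_g, 1, tolerance = 1e-4)
  # cross-check against the independent natural-spline oracle
  for (prof in list(3 * lam^2, sin(pi * lam), lam^3 - 2 * lam)) {
    sf <- splinefun(lam, prof, method = "natural")
    want <- integrate(sf, 0, 1, rel.tol = 1e-12)$value
    expect_equal(ti_estimate(ti_profile(lam, prof))$delta_g, want,
                 tolerance = 1e-8)
  }
  # quadratic data vs Simpson (both quadrature rules agree closely)
  quad <- lam^2
  h <- lam[2] - lam[1]
  simpson <- h / 3 * (quad[1] + quad[21] + 4 * sum(quad[seq(2, 20, 2)]) +
                        2 * sum(quad[seq(3, 19, 2)]))
  expect_equal(ti_estimate(ti_profile(lam, quad))$delta_g, simpson,
               tolerance = 1e-4)
  # error propagation is linear in the ordinates
  est_se <- ti_estimate(ti_profile(lam, quad, rep(0.1, 21)))
  expect_gt(est_se$stderr, 0)
  expect_error(ti_profile(c(0, 0.5, 0.5, 1), rep(1, 4)), "duplicate|increasing")
  expect_error(ti_estimate(ti_profile(c(0, 1), c(1, 1))), "at least 4")
})

test_that("repeat aggregation and the thermodynamic-cycle combination", {
  expect_equal(aggregate_repeats(c(1, 1, 1, 1)), list(mean = 1, sd = 0))
  expect_equal(aggregate_repeats(c(0, 2))$sd, sqrt(2))
  expect_error(aggregate_repeats(3), "at least 2")
  vac <- free_energy_result(5, 0.1, leg = "vacuum")
  aq <- free_energy_result(10, 0.2, leg = "aqueous")
  est <- combine_asfe(vac, aq, NULL)
  expect_equal(est$asfe, -5)
  expect_equal(est$stderr, sqrt(0.1^2 + 0.2^2))
  # identical legs: ASFE equals the LRC
  same <- free_energy_result(3.3, 0, leg = "vacuum")
  same2 <- free_energy_result(3.3, 0, leg = "aqueous")
  lrc <- saisolv:::lrc_result(-0.4, 0, "analytic")
  expect_equal(combine_asfe(same, same2, lrc)$asfe, -0.4)
})

test_that("repeat SD is commensurate with the within-run bootstrap SE", {
  # four repeats of the harmonic toy: SD over repeats within a factor 3
  # of the bootstrap SE of a single run
  k1 <- 1; k2 <- 3; n <- 1500
  reps <- sapply(1:4, function(r) {
    set.seed(100 + r)
    x <- c(rnorm(n, 0, sqrt(1 / k1)), rnorm(n, 0, sqrt(1 / k2)))
    em <- energy_matrix(cbind(0.5 * k1 * x^2, 0.5 * k2 * x^2), c(n, n))
    mbar_solve(em)$f[2]
  })
  set.seed(100 + 1)
  x <- c(rnorm(n, 0, sqrt(1 / k1)), rnorm(n, 0, sqrt(1 / k2)))
  em <- energy_matrix(cbind(0.5 * k1 * x^2, 0.5 * k2 * x^2), c(n, n))
  se <- mbar_bootstrap_stderr(em, B = 40, seed = 1)
  expect_lt(sd(reps) / se, 3)
  expect_gt(sd(reps) / se, 1 / 3)
})
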