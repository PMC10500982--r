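# Toy engine: switching functions, LJ treatments, pair sums, soft-core,
# Monte Carlo sampling properties

test_that("switching factors match the closed forms and boundary values", {
  st_omm <- toy_settings("OMM_VSWI")
  st_vswi <- toy_settings("VSWI")
  # boundaries: 1 at r_on, 0 at r_off for both potential switches
  expect_equal(switching_factor(4, st_omm), 1)
  expect_equal(switching_factor(4, st_vswi), 1)
  expect_equal(switching_factor(5, st_omm), 0)
  expect_equal(switching_factor(5, st_vswi), 0)
  # smoothstep symmetry: 0.5 at the midpoint
  expect_equal(switching_factor(4.5, st_omm), 0.5)
  # independent formula oracle across the switching region
  r <- seq(3.8, 5.2, by = 0.037)
  expect_equal(switching_factor(r, st_omm),
               sapply(r, oracle_switch, ron = 4, roff = 5, kind = "OMM_VSWI"),
               tolerance = 1e-12)
  expect_equal(switching_factor(r, st_vswi),
               sapply(r, oracle_switch, ron = 4, roff = 5, kind = "VSWI"),
               tolerance = 1e-12)
  # force switch has no multiplier: sentinel
  expect_true(is.na(switching_factor(4.5, toy_settings("VFSW"))))
  expect_error(nonbonded_settings(r_on = 5, r_off = 4), "r_on")
})

test_that("LJ energy: well depth, cutoff zeroing, independent treatment oracle", {
  for (kind in c("NONE", "VSWI", "OMM_VSWI", "VFSW")) {
    st <- toy_settings(kind)
    # U(r_min) = -eps exactly for the unshifted treatments (r_min is below
    # r_on so the potential switches do not taper there; the force switch
    # is energy-shifted below r_on by construction)
    if (kind != "VFSW") expect_equal(lj_energy(3.5, 3.5, 0.12, st), -0.12)
    expect_equal(lj_energy(3.5, 3.5, 0.12, st, cutoff = FALSE), -0.12)
    # zero at and beyond the cutoff
    expect_equal(lj_energy(c(5, 5.7, 8), 3.5, 0.12, st), c(0, 0, 0))
    # oracle agreement over the whole range
    r <- seq(3.0, 5.5, by = 0.05)
    expect_equal(lj_energy(r, 3.4, 0.15, st),
                 sapply(r, oracle_lj, rm = 3.4, eps = 0.15, ron = 4,
                        roff = 5, kind = kind),
                 tolerance = 1e-12)
  }
})

test_that("potential-switch energies are continuous at r_on and r_off", {
  h <- 1e-9
  for (kind in c("VSWI", "OMM_VSWI", "VFSW")) {
    st <- toy_settings(kind)
    for (r0 in c(4, 5)) {
      jump <- lj_energy(r0 - h, 3.4, 0.15, st) - lj_energy(r0 + h, 3.4, 0.15, st)
      expect_lt(abs(jump), 1e-8)
    }
  }
})

test_that("VFSW force is continuous and vanishes at the cutoff", {
  st <- toy_settings("VFSW")
  h <- 1e-6
  force <- function(r) -(lj_energy(r + h, 3.4, 0.15, st) -
                           lj_energy(r - h, 3.4, 0.15, st)) / (2 * h)
  # analytic force of the plain potential (valid below r_on)
  plain_force <- function(r) {
    eps <- 0.15; rm <- 3.4
    12 * eps * (rm^12 / r^13 - rm^6 / r^7)
  }
  # continuity across r_on: numerical force just below matches just above
  expect_equal(force(4 - 1e-4), force(4 + 1e-4), tolerance = 1e-3)
  # below r_on the force equals the plain LJ force
  r <- seq(3.7, 3.95, by = 0.05)
  expect_equal(sapply(r, force), sapply(r, plain_force), tolerance = 1e-6)
  # force goes to zero at the cutoff
  expect_lt(abs(force(5 - 1e-4)), 1e-3)
})

test_that("total_energy matches an independent O(N^2) brute-force sum", {
  for (kind in c("OMM_VSWI", "VFSW", "VSWI", "NONE")) {
    st <- toy_settings(kind)
    sys <- make_small_system(n_heavy = 3, n_h = 2, n_waters = 10, seed = 21)
    sch <- build_schedule(sys$solute)
    for (k in c(1L, 3L, 7L, length(sch$states))) {
      got <- total_energy(sys, sch$states[[k]], st)
      want <- oracle_total_energy(sys, sch$states[[k]], st)
      expect_equal(got[["solute_solvent"]], want[["solute_solvent"]],
                   tolerance = 1e-8)
      expect_equal(got[["intra_solute"]], want[["intra_solute"]],
                   tolerance = 1e-8)
      expect_equal(got[["solvent_solvent"]], want[["solvent_solvent"]],
                   tolerance = 1e-8)
      # bookkeeping: components sum to the total
      expect_equal(got[["total"]],
                   got[["solute_solvent"]] + got[["intra_solute"]] +
                     got[["solvent_solvent"]] + got[["bonded"]],
                   tolerance = 1e-10)
    }
  }
  # two neutral dummy atoms: zero
  dd <- solvated_system(
    solute_topology(data.frame(element = c("C", "C"), charge = c(0, 0),
                               r_min = c(3.5, 3.5), epsilon = c(0, 0)),
                    rbind(c(1, 2)), xyz = rbind(c(5, 5, 5), c(6.5, 5, 5))),
    box_edge = 12, periodic = TRUE)
  expect_equal(total_energy(dd, settings = toy_settings())[["intra_solute"]], 0)
  # box-edge guard
  small <- make_small_system(n_waters = 3, box = 10.5, seed = 2)
  expect_error(total_energy(small, settings = nonbonded_settings(r_on = 9,
                                                                 r_off = 11)),
               "box edge")
})

test_that("translation invariance under rigid shifts with wrapping", {
  st <- toy_settings()
  sys <- make_small_system(n_heavy = 2, n_h = 2, n_waters = 8, seed = 33)
  e0 <- total_energy(sys, settings = st)[["total"]]
  for (shift in list(c(1.3, -2.2, 0.7), c(25, 3, -14))) {
    moved <- sys
    moved$solute_xyz <- sweep(sys$solute_xyz, 2, shift, "+")
    moved$water_xyz <- sweep(sys$water_xyz, 2, shift, "+")
    expect_equal(total_energy(moved, settings = st)[["total"]], e0,
                 tolerance = 1e-9)
  }
})

test_that("soft-core LJ: endpoint identity, zero at lam = 0", {
  st <- toy_settings()
  r <- seq(0.5, 6, by = 0.25)
  # lam = 1 recovers plain LJ exactly
  expect_equal(softcore_lj_energy(r, 1, 3.4, 0.15, alpha = 5),
               sapply(r, oracle_lj, rm = 3.4, eps = 0.15, ron = 4, roff = 5,
                      kind = "NONE", cutoff = FALSE),
               tolerance = 1e-12)
  # lam = 0 gives zero everywhere, including r = 0
  expect_equal(softcore_lj_energy(c(0, r), 0, 3.4, 0.15), rep(0, length(r) + 1))
  # finite at r = 0 for intermediate lam (the singularity is removed)
  expect_true(is.finite(softcore_lj_energy(0, 0.5, 3.4, 0.15)))
})

test_that("soft-core path dU/dlambda matches finite differences", {
  sys <- make_small_system(n_heavy = 3, n_h = 2, n_waters = 8, seed = 13)
  st <- toy_settings()
  flat <- saisolv:::flatten_system(sys)
  sc <- saisolv:::settings_cpp(st)
  E <- function(l) saisolv:::cpp_total_energy(
    flat, sc, list(mode = 1L, lambda = l, alpha = 5))[["total"]]
  fr <- array(flat$coords, c(1, nrow(flat$coords), 3))
  for (l in c(0.05, 0.3, 0.5, 0.8, 0.95)) {
    h <- 1e-6
    fd <- (E(l + h) - E(l - h)) / (2 * h)
    an <- saisolv:::cpp_dudl_frames(fr, sys$box_edge, flat, sc, l, 5)
    expect_equal(an[1], fd, tolerance = 1e-5)
  }
})

test_that("Metropolis sampler is deterministic and Boltzmann-consistent", {
  sys <- make_small_system(n_heavy = 2, n_h = 1, n_waters = 6, seed = 41)
  st <- toy_settings()
  t1 <- mc_sample(sys, settings = st, n_sweeps = 60, n_tune = 20, seed = 99)
  t2 <- mc_sample(sys, settings = st, n_sweeps = 60, n_tune = 20, seed = 99)
  expect_identical(t1$frames, t2$frames)
  t3 <- mc_sample(sys, settings = st, n_sweeps = 60, n_tune = 20, seed = 100)
  expect_false(identical(t1$frames, t3$frames))

  # ideal-gas limit: a fully decoupled solute atom distributes uniformly
  ig <- solvated_system(
    solute_topology(data.frame(element = "C", charge = 0, r_min = 3.5,
                               epsilon = 0),
                    matrix(integer(0), 0, 2), xyz = rbind(c(6, 6, 6))),
    box_edge = 12, periodic = TRUE)
  tr <- mc_sample(ig, settings = st, n_sweeps = 6000, n_tune = 200,
                  save_every = 3, seed = 7)
  xs <- tr$frames[, 1, 1]
  se <- 12 / sqrt(12) / sqrt(200)  # uniform sd = L/sqrt(12); ~200 indep frames
  expect_lt(abs(mean(xs) - 6), 3 * se * 3) # generous: frames correlate
})

test_that("zero-temperature Metropolis only goes downhill", {
  sys <- make_small_system(n_heavy = 2, n_h = 1, n_waters = 6, seed = 47)
  st0 <- nonbonded_settings(r_on = 4, r_off = 5, temperature = 1e-4)
  tr <- mc_sample(sys, settings = st0, n_sweeps = 200, n_tune = 0,
                  save_every = 10, seed = 3)
  flat <- saisolv:::flatten_system(sys)
  u <- saisolv:::cpp_energy_frames(
    tr$frames, tr$boxes, flat, saisolv:::settings_cpp(st0),
    list(saisolv:::state_coupling(NULL, flat$ns)))
  expect_true(all(diff(u[, 1]) <= 1e-9))
})

test_that("single-particle harmonic well: sampled variance matches kB T / k", {
  # a lone solute atom bonded to a fixed partner is awkward; instead use a
  # 2-atom molecule in vacuum: the bond spring has k = 300 kcal/mol/A^2 and
  # the bond-length fluctuation variance should be kB T / (2k) per the
  # effective 1-dof radial spring U = k (r - r0)^2
  top <- make_toy_solute(2, 0, "chain", seed = 3)
  top$atoms$charge[] <- 0; top$atoms$epsilon[] <- 0
  sysv <- solvated_system(top, box_edge = 30, periodic = FALSE)
  st <- nonbonded_settings(r_on = 10, r_off = 12, temperature = 303.15)
  tr <- mc_sample(sysv, settings = st, n_sweeps = 8000, n_tune = 500,
                  save_every = 2, seed = 17)
  bl <- sqrt(rowSums((tr$frames[, 1, ] - tr$frames[, 2, ])^2))
  v <- var(bl)
  want <- kB_test * 303.15 / (2 * 300)
  expect_lt(abs(v - want) / want, 0.35)
})

test_that("harmonic reference free energies follow the closed form", {
  expect_equal(harmonic_reference(2) - harmonic_reference(2), 0)
  expect_equal(harmonic_reference(4) - harmonic_reference(1), log(2))
  expect_equal(harmonic_reference(exp(2)) - harmonic_reference(1), 1)
  expect_error(harmonic_reference(-1), "> 0")
})
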