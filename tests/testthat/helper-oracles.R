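# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals: the energy oracle is a plain-R
# O(N^2) pair sum written from the formulas, and the MBAR oracle minimises
# the convex MBAR objective with optim/BFGS instead of self-consistent
# iteration.

kB_test <- 0.0019872041
kcoul_test <- 332.0637

toy_settings <- function(kind = "OMM_VSWI")
  nonbonded_settings(r_on = 4, r_off = 5, switch_kind = kind)

# potential-switch factor, written independently from the formulas
oracle_switch <- function(r, ron, roff, kind) {
  if (r >= roff) return(0)
  if (r <= ron) return(1)
  if (kind == "OMM_VSWI") {
    x <- (r - ron) / (roff - ron)
    1 - 10 * x^3 + 15 * x^4 - 6 * x^5
  } else {
    (roff^2 - r^2)^2 * (roff^2 + 2 * r^2 - 3 * ron^2) / (roff^2 - ron^2)^3
  }
}

oracle_lj <- function(r, rm, eps, ron, roff, kind, cutoff = TRUE) {
  if (eps == 0 || rm <= 0) return(0)
  plain <- function(rr) eps * ((rm / rr)^12 - 2 * (rm / rr)^6)
  if (!cutoff) return(plain(r))
  if (r >= roff) return(0)
  if (kind == "NONE") return(plain(r))
  if (kind == "VFSW") {
    A <- eps * rm^12; B <- 2 * eps * rm^6
    if (r <= ron)
      return(A * (r^-12 - (ron * roff)^-6) - B * (r^-6 - (ron * roff)^-3))
    a12 <- roff^6 / (roff^6 - ron^6); a6 <- roff^3 / (roff^3 - ron^3)
    return(A * a12 * (r^-6 - roff^-6)^2 - B * a6 * (r^-3 - roff^-3)^2)
  }
  plain(r) * oracle_switch(r, ron, roff, kind)
}

oracle_coul <- function(r, qq, ron, roff, kind, cutoff = TRUE) {
  if (qq == 0) return(0)
  if (!cutoff) return(kcoul_test * qq / r)
  if (r >= roff) return(0)
  if (kind == "NONE") return(kcoul_test * qq / r)
  k <- if (kind == "OMM_VSWI") "OMM_VSWI" else "VSWI"
  kcoul_test * qq / r * oracle_switch(r, ron, roff, k)
}

# full nonbonded pair sum over a solvated_system under a schedule state,
# minimum image, 1-2/1-3 intra-solute exclusions; returns the components
oracle_total_energy <- function(system, state = NULL, settings) {
  top <- system$solute
  ns <- nrow(top$atoms)
  w <- system$water
  nw <- system$n_waters
  coords <- rbind(system$solute_xyz, system$water_xyz)
  q <- c(top$atoms$charge, rep(c(w$q_o, w$q_h, w$q_h), nw))
  rmin <- c(top$atoms$r_min, rep(c(w$r_min_o, 0, 0), nw))
  eps <- c(top$atoms$epsilon, rep(c(w$epsilon_o, 0, 0), nw))
  qs <- ljs <- rep(1, ns)
  if (!is.null(state)) { qs <- state$charge_scale; ljs <- state$lj_scale }
  n <- nrow(coords)
  box <- system$box_edge
  kind <- settings$switch_kind
  cutoff <- system$periodic
  # exclusion set: bonded graph distances 1 and 2
  excl <- matrix(FALSE, max(ns, 1), max(ns, 1))
  if (ns > 0) {
    adj <- matrix(FALSE, ns, ns)
    for (b in seq_len(nrow(top$bonds))) {
      adj[top$bonds[b, 1], top$bonds[b, 2]] <- TRUE
      adj[top$bonds[b, 2], top$bonds[b, 1]] <- TRUE
    }
    excl <- adj
    for (m in 1:ns) {
      nb <- which(adj[m, ])
      for (a in nb) for (c in nb) if (a != c) excl[a, c] <- TRUE
    }
    diag(excl) <- TRUE
  }
  comps <- c(solute_solvent = 0, intra_solute = 0, solvent_solvent = 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    i_sol <- i <= ns; j_sol <- j <= ns
    if (i_sol && j_sol && excl[i, j]) next
    if (!i_sol && !j_sol &&
        ((i - ns - 1) %/% 3 == (j - ns - 1) %/% 3)) next
    d <- coords[i, ] - coords[j, ]
    if (system$periodic) d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    si <- if (i_sol) ljs[i] else 1; sj <- if (j_sol) ljs[j] else 1
    rm <- (rmin[i] * si + rmin[j] * sj) / 2
    ee <- sqrt(eps[i] * si * eps[j] * sj)
    qq <- (if (i_sol) q[i] * qs[i] else q[i]) *
          (if (j_sol) q[j] * qs[j] else q[j])
    e <- oracle_lj(r, rm, ee, settings$r_on, settings$r_off, kind, cutoff) +
      oracle_coul(r, qq, settings$r_on, settings$r_off, kind, cutoff)
    key <- if (i_sol && j_sol) "intra_solute"
           else if (!i_sol && !j_sol) "solvent_solvent" else "solute_solvent"
    comps[key] <- comps[key] + e
  }
  comps
}

# Independent MBAR solution: minimise the convex objective
#   phi(f) = sum_n log sum_k N_k exp(f_k - u_nk) - sum_k N_k f_k
# over f[2..K] with optim/BFGS and an analytic gradient.
oracle_mbar <- function(u, N_k) {
  K <- ncol(u)
  lse <- function(m) {
    mx <- apply(m, 1, max)
    mx + log(rowSums(exp(m - mx)))
  }
  phi <- function(ftail) {
    f <- c(0, ftail)
    sum(lse(sweep(-u, 2, log(N_k) + f, "+"))) - sum(N_k * f)
  }
  grad <- function(ftail) {
    f <- c(0, ftail)
    ld <- lse(sweep(-u, 2, log(N_k) + f, "+"))
    W <- exp(sweep(-u, 2, f, "+") - ld)
    (N_k * (colSums(W) - 1))[-1]
  }
  fit <- optim(numeric(K - 1), phi, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  c(0, fit$par)
}

# random reduced-potential matrices from overlapping Gaussian states
random_gaussian_matrix <- function(K, n_per, seed) {
  set.seed(seed)
  mu <- cumsum(runif(K, -0.5, 0.5))
  sig <- runif(K, 0.8, 1.6)
  x <- unlist(lapply(seq_len(K), function(k) rnorm(n_per, mu[k], sig[k])))
  u <- sapply(seq_len(K), function(k)
    0.5 * ((x - mu[k]) / sig[k])^2 + log(sig[k]))
  energy_matrix(u, rep(n_per, K))
}

make_small_system <- function(n_heavy = 2, n_h = 2, n_waters = 15,
                              box = 10.5, seed = 5) {
  top <- make_toy_solute(n_heavy, n_h, "chain", seed = seed)
  solvate(top, n_waters, box, seed = seed + 1)
}
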