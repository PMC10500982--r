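# Synthetic fixture generators: toy solutes and water baths that make the
# whole pipeline testable without any external input.  Toy solutes emulate
# neutral small organic molecules (1-15 heavy atoms, explicit hydrogens)
# with physically plausible LJ parameters; waters are rigid 3-site monomers.

# deterministic, roughly tetrahedral unit directions for substituents
.unit_dirs <- local({
  d <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
             c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0),
             c(0, -1, 0), c(0, 0, -1), c(1, 1, 0), c(1, 0, 1))
  d / sqrt(rowSums(d^2))
})

#' Generate a toy solute topology
#'
#' Builds a connected heavy-atom graph of the requested kind (`chain`,
#' `ring` or `star`), attaches hydrogens round-robin to heavy atoms with
#' free valence (max 4 bonds per heavy atom), draws partial charges that
#' sum exactly to zero, and LJ parameters in plausible ranges (heavy
#' atoms: epsilon 0.05-0.2 kcal/mol, r_min 3.0-4.5 A; hydrogens: epsilon
#' 0.02-0.05, r_min 2.0-2.5 A).  `ring` builds a cycle of up to six atoms
#' with any extra heavy atoms appended as substituents, so
#' `make_toy_solute(7, 8, "ring")` is a toluene-like topology.
#'
#' @param n_heavy number of heavy atoms (>= 1; >= 3 for rings).
#' @param n_hydrogen number of hydrogens.
#' @param topology_kind "chain", "ring" or "star".
#' @param seed RNG seed.
#' @return a [solute_topology()] with initial coordinates.
#' @export
make_toy_solute <- function(n_heavy, n_hydrogen = 0,
                            topology_kind = c("chain", "ring", "star"),
                            seed = 1) {
  topology_kind <- match.arg(topology_kind)
  stopifnot(n_heavy >= 1, n_hydrogen >= 0)
  set.seed(seed)
  bl <- 1.5; hl <- 1.1
  bonds <- matrix(integer(0), 0, 2)
  xyz <- matrix(0, n_heavy, 3)
  if (topology_kind == "chain") {
    if (n_heavy > 1L)
      bonds <- cbind(seq_len(n_heavy - 1L), seq_len(n_heavy - 1L) + 1L)
    xyz[, 1L] <- (seq_len(n_heavy) - 1L) * bl
    # slight zig-zag so 1-3 neighbours do not overlap linearly
    xyz[, 2L] <- 0.3 * (seq_len(n_heavy) %% 2L)
  } else if (topology_kind == "ring") {
    if (n_heavy < 3L) stop("a ring needs at least 3 heavy atoms")
    m <- min(6L, n_heavy)
    R <- bl / (2 * sin(pi / m))
    ang <- 2 * pi * (seq_len(m) - 1L) / m
    xyz[seq_len(m), ] <- cbind(R * cos(ang), R * sin(ang), 0)
    bonds <- cbind(seq_len(m), c(seq_len(m)[-1L], 1L))
    if (n_heavy > m) {
      for (k in seq.int(m + 1L, n_heavy)) {
        anchor <- ((k - m - 1L) %% m) + 1L
        dir <- xyz[anchor, ] / max(sqrt(sum(xyz[anchor, ]^2)), 1e-9)
        xyz[k, ] <- xyz[anchor, ] + bl * dir
        bonds <- rbind(bonds, c(anchor, k))
      }
    }
  } else { # star
    if (n_heavy > 5L)
      stop("impossible valence: a star centre supports at most 4 spokes")
    if (n_heavy > 1L) {
      for (k in seq.int(2L, n_heavy)) {
        xyz[k, ] <- bl * .unit_dirs[k - 1L, ]
        bonds <- rbind(bonds, c(1L, k))
      }
    }
  }
  deg <- vapply(seq_len(n_heavy), function(a) sum(bonds == a), 0L)
  free <- pmax(4L - deg, 0L)
  if (n_hydrogen > sum(free))
    stop("impossible valence: ", n_hydrogen, " hydrogens requested but only ",
         sum(free), " heavy valences free")
  # round-robin hydrogen attachment over heavy atoms with free valence
  h_anchor <- integer(0)
  slots <- free
  while (length(h_anchor) < n_hydrogen) {
    for (a in seq_len(n_heavy)) {
      if (slots[a] > 0L && length(h_anchor) < n_hydrogen) {
        h_anchor <- c(h_anchor, a); slots[a] <- slots[a] - 1L
      }
    }
  }
  n <- n_heavy + n_hydrogen
  if (n_hydrogen > 0L) {
    hx <- matrix(0, n_hydrogen, 3)
    used <- integer(n_heavy)
    for (i in seq_len(n_hydrogen)) {
      a <- h_anchor[i]
      used[a] <- used[a] + 1L
      hx[i, ] <- xyz[a, ] + hl * .unit_dirs[(used[a] %% nrow(.unit_dirs)) + 1L, ]
      bonds <- rbind(bonds, c(a, n_heavy + i))
    }
    xyz <- rbind(xyz, hx)
  }
  # charges are dyadic rationals (multiples of 2^-20 e, ~1e-6 e
  # granularity, finer than force-field charge precision): every partial
  # sum is then exact in floating point, so recentring the last atom makes
  # the net charge *exactly* zero in any summation order
  grid <- 2^20
  kmax <- as.integer(0.3 * grid)
  k <- sample.int(2L * kmax + 1L, n) - kmax - 1L
  if (n > 1L) {
    k[n] <- -sum(k[-n])
    # keep the balancing charge in range without losing integer exactness
    while (abs(k[n]) > kmax) {
      k[-n] <- k[-n] %/% 2L
      k[n] <- -sum(k[-n])
    }
  } else k[1L] <- 0L
  q <- k / grid
  atoms <- data.frame(
    element = c(rep("C", n_heavy), rep("H", n_hydrogen)),
    charge = q,
    r_min = c(runif(n_heavy, 3.0, 4.5), runif(n_hydrogen, 2.0, 2.5)),
    epsilon = c(runif(n_heavy, 0.05, 0.2), runif(n_hydrogen, 0.02, 0.05)),
    stringsAsFactors = FALSE)
  top <- solute_topology(atoms, bonds,
                         name = sprintf("toy-%s-%dC%dH", topology_kind,
                                        n_heavy, n_hydrogen),
                         xyz = xyz)
  # remember designed bond lengths as the spring equilibria
  attr(top, "bond_r0") <- sqrt(rowSums((xyz[bonds[, 1L], , drop = FALSE] -
                                        xyz[bonds[, 2L], , drop = FALSE])^2))
  top
}

# Clash rule (intermolecular, minimum image): heavy-heavy > min_dist,
# H-heavy > 0.75 * min_dist, H-H > 0.5 * min_dist.  Hydrogen-bond-like
# H...O approaches tighter than a full heavy-atom contact are physical at
# liquid density, which is why hydrogens get the looser thresholds.
place_waters <- function(n_waters, box_edge, seed, avoid = NULL,
                         avoid_heavy = NULL, min_dist = 2.0,
                         model = toy_water(), max_tries = 2000L) {
  set.seed(seed)
  sites <- avoid
  heavy <- avoid_heavy %||% rep(TRUE, NROW(avoid))
  coords <- matrix(0, 0, 3)
  mind2 <- function(s, pts) {
    if (is.null(pts) || nrow(pts) == 0L) return(Inf)
    d <- sweep(pts, 2L, s)
    d <- d - box_edge * round(d / box_edge)
    min(rowSums(d^2))
  }
  for (w in seq_len(n_waters)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      o <- runif(3, 0, box_edge)
      e1 <- rnorm(3); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- rnorm(3)
      s <- water_sites(model, o, e1, e2)
      hv <- sites[heavy, , drop = FALSE]
      hy <- sites[!heavy, , drop = FALSE]
      ok <- mind2(s[1L, ], hv) > min_dist^2 &&
        mind2(s[1L, ], hy) > (0.75 * min_dist)^2 &&
        mind2(s[2L, ], hv) > (0.75 * min_dist)^2 &&
        mind2(s[3L, ], hv) > (0.75 * min_dist)^2 &&
        mind2(s[2L, ], hy) > (0.5 * min_dist)^2 &&
        mind2(s[3L, ], hy) > (0.5 * min_dist)^2
      if (ok) {
        coords <- rbind(coords, s)
        sites <- rbind(sites, s)
        heavy <- c(heavy, TRUE, FALSE, FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("packing failure: could not place water ", w, " after ",
           max_tries, " tries")
  }
  coords
}

#' Generate a pure water box
#'
#' Places `n_waters` rigid toy waters in a cubic box without steric
#' clashes (minimum intermolecular site distance > 2 A), reproducibly by
#' seed.  This is the "same box minus the solute" companion system used
#' by the a-posteriori LRC.
#'
#' @param n_waters count.
#' @param box_edge Angstrom.
#' @param seed RNG seed.
#' @param model a [toy_water()].
#' @return a [solvated_system()] with a zero-atom solute.
#' @export
make_water_bath <- function(n_waters, box_edge, seed = 1,
                            model = toy_water()) {
  coords <- place_waters(n_waters, box_edge, seed, model = model)
  empty <- structure(list(atoms = data.frame(element = character(0),
                                             charge = numeric(0),
                                             r_min = numeric(0),
                                             epsilon = numeric(0)),
                          bonds = matrix(integer(0), 0, 2),
                          name = "water-box", xyz = NULL),
                     class = "solute_topology")
  solvated_system(empty, water = model, water_xyz = coords,
                  box_edge = box_edge, periodic = TRUE)
}

#' Solvate a toy solute in a periodic water box
#'
#' Centres the solute in the box and packs waters around it, avoiding
#' overlap with the solute sites.
#'
#' @param solute a [solute_topology()] with coordinates.
#' @param n_waters number of waters.
#' @param box_edge Angstrom.
#' @param seed RNG seed.
#' @param model a [toy_water()].
#' @export
solvate <- function(solute, n_waters, box_edge, seed = 1,
                    model = toy_water()) {
  xyz <- solute$xyz
  if (is.null(xyz)) stop("solute has no coordinates")
  centre <- box_edge / 2 - colMeans(xyz)
  xyz <- sweep(xyz, 2L, centre, "+")
  coords <- place_waters(n_waters, box_edge, seed, avoid = xyz,
                         avoid_heavy = !is_hydrogen(solute),
                         min_dist = 2.2, model = model)
  sol <- solute; sol$xyz <- xyz
  attr(sol, "bond_r0") <- attr(solute, "bond_r0")
  solvated_system(sol, water = model, water_xyz = coords,
                  box_edge = box_edge, periodic = TRUE)
}

#' Vacuum companion system of a solvated system
#'
#' The same solute, alone and non-periodic: the vacuum annihilation leg of
#' the thermodynamic cycle (no cutoff is applied in vacuum).
#'
#' @param system a [solvated_system()].
#' @export
vacuum_system <- function(system) {
  solvated_system(system$solute, solute_xyz = system$solute_xyz,
                  water = system$water, water_xyz = NULL,
                  box_edge = system$box_edge, periodic = FALSE)
}
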