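#' Solute topology with CHARMM-convention nonbonded parameters
#'
#' A solute is a set of atoms (element, partial charge in e, LJ parameters
#' `r_min` in Angstrom and `epsilon` in kcal/mol) plus a bond list.  LJ
#' parameters follow the CHARMM convention: per-atom minimum-energy distances
#' are combined by the arithmetic mean (Lorentz-Berthelot on `r_min/2`),
#' well depths by the geometric mean.  The heavy-atom connectivity graph
#' must be connected; hydrogens are identified by element.
#'
#' @param atoms data frame with columns `element`, `charge`, `r_min`,
#'   `epsilon` (one row per atom; 1-based indexing throughout).
#' @param bonds two-column integer matrix of bonded atom pairs.
#' @param name label for the solute.
#' @param xyz optional n x 3 matrix of initial coordinates (Angstrom).
#' @return An object of class `solute_topology`.
#' @export
solute_topology <- function(atoms, bonds, name = "solute", xyz = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "charge", "r_min", "epsilon") %in% names(atoms)))
  n <- nrow(atoms)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) > 0 && (min(bonds) < 1L || max(bonds) > n))
    stop("bond index out of range (atoms are 1..", n, ")")
  if (any(atoms$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(atoms$epsilon > 0 & atoms$r_min <= 0))
    stop("r_min must be > 0 for atoms with epsilon > 0")
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    stopifnot(nrow(xyz) == n, ncol(xyz) == 3L)
  }
  top <- structure(list(atoms = atoms, bonds = bonds, name = name, xyz = xyz),
                   class = "solute_topology")
  heavy <- classify_atoms(top)$heavy
  if (length(heavy) > 1L && !graph_connected(heavy, bonds))
    stop("heavy-atom connectivity graph is not connected")
  top
}

#' @export
print.solute_topology <- function(x, ...) {
  cl <- classify_atoms(x)
  cat(sprintf("Solute '%s': %d atoms (%d heavy, %d H), %d bonds, net charge %+.4f e\n",
              x$name, nrow(x$atoms), length(cl$heavy), length(cl$hydrogen),
              nrow(x$bonds), net_charge(x)))
  invisible(x)
}

#' Net charge of a solute in e
#' @param topology a [solute_topology()].
#' @export
net_charge <- function(topology) sum(topology$atoms$charge)

is_hydrogen <- function(topology) topology$atoms$element == "H"

#' Partition atom indices into hydrogens and heavy atoms
#'
#' Hydrogens are identified by element symbol; the partition is exhaustive
#' and disjoint.  The SAI schedule scales all hydrogen LJ parameters jointly
#' and removes heavy atoms one by one.
#'
#' @param topology a [solute_topology()].
#' @return list with integer vectors `hydrogen` and `heavy`.
#' @export
classify_atoms <- function(topology) {
  h <- is_hydrogen(topology)
  list(hydrogen = which(h), heavy = which(!h))
}

# connectivity of the subgraph induced on `keep` by `bonds`
graph_connected <- function(keep, bonds) {
  if (length(keep) <= 1L) return(TRUE)
  adj <- lapply(seq_along(keep), function(i) integer(0))
  idx <- match(seq_len(max(c(keep, bonds))), keep)
  for (b in seq_len(nrow(bonds))) {
    i <- idx[bonds[b, 1L]]; j <- idx[bonds[b, 2L]]
    if (!is.na(i) && !is.na(j)) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(length(keep)); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

#' Replace atoms by non-interacting dummies
#'
#' Sets partial charge and LJ well depth to zero for the listed atoms;
#' bonded terms are untouched.  A fully dummied solute contributes zero
#' nonbonded energy in any configuration.
#'
#' @param topology a [solute_topology()].
#' @param indices atom indices to dummy (1-based).
#' @return The modified topology.
#' @export
make_dummy_parameters <- function(topology, indices) {
  indices <- as.integer(indices)
  if (length(indices) &&
      (min(indices) < 1L || max(indices) > nrow(topology$atoms)))
    stop("invalid atom index")
  topology$atoms$charge[indices] <- 0
  topology$atoms$epsilon[indices] <- 0
  topology
}

#' Rigid three-site toy water model
#'
#' A rigid 3-site monomer (one LJ oxygen site, two charged hydrogen sites)
#' with fixed internal geometry, moved as a rigid body during sampling.
#' The default numbers are TIP3P-like but the model makes no claim to be
#' TIP3P-faithful; it only has to behave like a polar, hydrogen-bonding
#' liquid at toy scale.
#'
#' @param q_o,q_h site charges in e (must sum to zero per monomer).
#' @param r_min_o,epsilon_o oxygen LJ parameters (Angstrom, kcal/mol).
#' @param r_oh O-H distance in Angstrom; `theta_deg` H-O-H angle in degrees.
#' @export
toy_water <- function(q_o = -0.834, q_h = 0.417, r_min_o = 3.5364,
                      epsilon_o = 0.152, r_oh = 0.9572, theta_deg = 104.52) {
  stopifnot(abs(q_o + 2 * q_h) < 1e-10, epsilon_o >= 0, r_oh > 0)
  structure(list(q_o = q_o, q_h = q_h, r_min_o = r_min_o,
                 epsilon_o = epsilon_o, r_oh = r_oh, theta_deg = theta_deg),
            class = "toy_water")
}

# site coordinates of one water given O position and two unit vectors
water_sites <- function(model, o, e1, e2) {
  th <- model$theta_deg * pi / 180
  h1 <- o + model$r_oh * e1
  # e2 orthogonalized against e1, then rotated to the H-O-H angle
  e2p <- e2 - sum(e2 * e1) * e1
  e2p <- e2p / sqrt(sum(e2p^2))
  h2 <- o + model$r_oh * (cos(th) * e1 + sin(th) * e2p)
  rbind(o, h1, h2)
}

#' Solvated (or vacuum) toy system
#'
#' Bundles a solute topology with coordinates, a bath of rigid toy waters
#' and a cubic periodic box.  Periodic systems must satisfy
#' `box_edge >= 2 * r_off` for the intended cutoff (checked at energy/
#' sampling time, mirroring the requirement that boxes be commensurate with
#' the cutoff).
#'
#' @param solute a [solute_topology()] (may have zero atoms for a pure
#'   water box; see [make_water_bath()]).
#' @param solute_xyz n x 3 coordinates of the solute (Angstrom); defaults
#'   to `solute$xyz`.
#' @param water a [toy_water()] model.
#' @param water_xyz (3*n_waters) x 3 coordinates, one O,H,H triple per
#'   water, or NULL for no solvent.
#' @param box_edge cubic box edge in Angstrom.
#' @param periodic logical.
#' @return An object of class `solvated_system`.
#' @export
solvated_system <- function(solute, solute_xyz = solute$xyz,
                            water = toy_water(), water_xyz = NULL,
                            box_edge = 30, periodic = TRUE) {
  ns <- nrow(solute$atoms)
  if (ns > 0) {
    if (is.null(solute_xyz)) stop("solute coordinates required")
    solute_xyz <- as.matrix(solute_xyz)
    stopifnot(nrow(solute_xyz) == ns, ncol(solute_xyz) == 3L)
  } else solute_xyz <- matrix(numeric(0), 0, 3)
  if (!is.null(water_xyz)) {
    water_xyz <- as.matrix(water_xyz)
    if (nrow(water_xyz) %% 3L != 0L || ncol(water_xyz) != 3L)
      stop("water coordinates must be (3*n_waters) x 3")
  } else water_xyz <- matrix(numeric(0), 0, 3)
  structure(list(solute = solute, solute_xyz = solute_xyz, water = water,
                 water_xyz = water_xyz, n_waters = nrow(water_xyz) %/% 3L,
                 box_edge = box_edge, periodic = periodic),
            class = "solvated_system")
}

#' @export
print.solvated_system <- function(x, ...) {
  cat(sprintf("Toy system: %d solute atoms + %d waters, box %.2f A (%s)\n",
              nrow(x$solute$atoms), x$n_waters, x$box_edge,
              if (x$periodic) "periodic" else "non-periodic"))
  invisible(x)
}

# intra-solute nonbonded exclusions: self, 1-2 and 1-3 bonded neighbours
exclusion_matrix <- function(topology) {
  n <- nrow(topology$atoms)
  ex <- diag(n) > 0
  b <- topology$bonds
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(b))) {
    adj[b[k, 1L], b[k, 2L]] <- TRUE; adj[b[k, 2L], b[k, 1L]] <- TRUE
  }
  ex <- ex | adj                       # 1-2
  for (j in seq_len(n)) {              # 1-3: shared bonded neighbour
    nb <- which(adj[j, ])
    if (length(nb) > 1L)
      for (a in nb) for (c in nb) if (a != c) ex[a, c] <- TRUE
  }
  ex
}

# flatten a system into the argument lists the C++ kernels expect
flatten_system <- function(system, bond_k = 300) {
  top <- system$solute
  ns <- nrow(top$atoms)
  nw <- system$n_waters
  w <- system$water
  coords <- rbind(system$solute_xyz, system$water_xyz)
  q <- c(top$atoms$charge, rep(c(w$q_o, w$q_h, w$q_h), nw))
  rmin <- c(top$atoms$r_min, rep(c(w$r_min_o, 0, 0), nw))
  eps <- c(top$atoms$epsilon, rep(c(w$epsilon_o, 0, 0), nw))
  bonds <- if (ns > 0 && nrow(top$bonds) > 0) {
    b <- top$bonds
    r0 <- sqrt(rowSums((system$solute_xyz[b[, 1L], , drop = FALSE] -
                        system$solute_xyz[b[, 2L], , drop = FALSE])^2))
    r0 <- attr(top, "bond_r0") %||% r0
    cbind(b[, 1L] - 1, b[, 2L] - 1, r0, bond_k)
  } else matrix(numeric(0), 0, 4)
  excl <- if (ns > 0) exclusion_matrix(top) else matrix(FALSE, 0, 0)
  list(coords = coords, q = q, rmin = rmin, eps = eps, ns = ns, nw = nw,
       box = system$box_edge, periodic = system$periodic,
       excl = matrix(as.integer(excl), nrow(excl), ncol(excl)),
       bonds = bonds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
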