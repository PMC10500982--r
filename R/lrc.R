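# Lennard-Jones long-range correction (LRC): the attractive interactions
# neglected beyond the cutoff.  Computed analytically for a fixed box
# (isotropic NVT correction), or by the a-posteriori full-box-minus-water-box
# averaging over constant-pressure trajectories.

lrc_result <- function(value, stderr, method, components = NULL) {
  stopifnot(stderr >= 0)
  structure(list(value = value, stderr = stderr, method = method,
                 components = components), class = "lrc_result")
}

#' @export
print.lrc_result <- function(x, ...) {
  cat(sprintf("LJ LRC (%s): %.4f +/- %.4f kcal/mol\n", x$method, x$value,
              x$stderr))
  invisible(x)
}

# site types (r_min, epsilon, count) of a system under optional state scaling
site_types <- function(system, state = NULL) {
  flat <- flatten_system(system)
  rmin <- flat$rmin; eps <- flat$eps
  if (!is.null(state) && flat$ns > 0) {
    s <- state$lj_scale
    rmin[seq_len(flat$ns)] <- rmin[seq_len(flat$ns)] * s
    eps[seq_len(flat$ns)] <- eps[seq_len(flat$ns)] * s
  }
  keep <- eps > 0
  key <- paste(rmin[keep], eps[keep])
  agg <- tapply(seq_along(key), key, length)
  u <- !duplicated(key)
  data.frame(r_min = rmin[keep][u], epsilon = eps[keep][u],
             n = as.vector(agg[key[u]]))
}

# volume-independent part: 2*pi * sum_{a,b} N_a N_b * I_ab with
# I_ab = int_{r_off}^inf U r^2 dr + int_{r_on}^{r_off} (U - U_switched) r^2 dr
tail_coefficient <- function(types, settings) {
  roff <- settings$r_off
  total <- 0
  for (a in seq_len(nrow(types))) for (b in seq_len(nrow(types))) {
    rm <- (types$r_min[a] + types$r_min[b]) / 2
    ee <- sqrt(types$epsilon[a] * types$epsilon[b])
    beyond <- ee * (rm^12 / (9 * roff^9) - 2 * rm^6 / (3 * roff^3))
    deficit <- 0
    if (settings$switch_kind != "NONE") {
      integrand <- function(r) {
        s6 <- (rm / r)^6
        full <- ee * (s6^2 - 2 * s6)
        (full - lj_energy(r, rm, ee, settings)) * r^2
      }
      deficit <- integrate(integrand, settings$r_on, roff,
                           rel.tol = 1e-10, abs.tol = 1e-13)$value
    }
    total <- total + types$n[a] * types$n[b] * (beyond + deficit)
  }
  2 * pi * total
}

#' Analytic isotropic LJ tail correction
#'
#' `E_LRC = (2 pi / V) sum_{a,b} N_a N_b int [U_ab(r) - U_ab^switched(r)] r^2 dr`
#' over site-type pairs, assuming uniform density beyond the cutoff.  The
#' beyond-cutoff part is taken in closed form (attractive tail
#' `-2 eps r_min^6 / (3 r_off^3)` per pair type plus the r^-12 term); the
#' switch-deficit part on `[r_on, r_off]` is evaluated by adaptive
#' quadrature to 1e-10 relative tolerance.
#'
#' @param system a periodic [solvated_system()].
#' @param settings a [nonbonded_settings()].
#' @param state optional intermediate state scaling the solute parameters.
#' @param volume override the box volume (Angstrom^3); defaults to
#'   `box_edge^3`.
#' @return kcal/mol.
#' @export
analytic_tail <- function(system, settings = nonbonded_settings(),
                          state = NULL, volume = NULL) {
  if (!system$periodic) stop("analytic tail correction requires a periodic system")
  types <- site_types(system, state)
  if (nrow(types) == 0L) return(0)
  V <- volume %||% system$box_edge^3
  tail_coefficient(types, settings) / V
}

# water-only copy of a solvated system
strip_solute <- function(system) {
  empty <- structure(list(atoms = data.frame(element = character(0),
                                             charge = numeric(0),
                                             r_min = numeric(0),
                                             epsilon = numeric(0)),
                          bonds = matrix(integer(0), 0, 2),
                          name = "water-box", xyz = NULL),
                     class = "solute_topology")
  solvated_system(empty, water = system$water, water_xyz = system$water_xyz,
                  box_edge = system$box_edge, periodic = system$periodic)
}

#' LRC contribution to the ASFE at fixed volume
#'
#' The analytic-tail difference between the fully interacting
#' solute-solvent system and the same box with the solute removed: the
#' dispersion the aqueous annihilation leg never sees because of the
#' cutoff.  Always negative for solutes whose atoms are all attractive
#' (epsilon > 0), and growing in magnitude with solute size.
#'
#' @param system the solvated [solvated_system()].
#' @param settings a [nonbonded_settings()].
#' @return An `lrc_result` with `method = "analytic"`.
#' @export
lrc_correction <- function(system, settings = nonbonded_settings()) {
  full <- analytic_tail(system, settings)
  water <- analytic_tail(strip_solute(system), settings)
  lrc_result(full - water, stderr = 0, method = "analytic",
             components = c(full = full, water = water))
}

#' A-posteriori LRC from constant-pressure trajectories
#'
#' For each frame of an NPT trajectory, the analytic tail is evaluated at
#' that frame's instantaneous volume; the first third of each trajectory
#' is discarded as equilibration (mirroring 1 ns of 3 ns); the estimate is
#' the difference of the per-trajectory averages,
#' `<dE_LRC^full> - <dE_LRC^water>`.  With several independent
#' repetitions (distinct seeds) the value is their mean and the quoted
#' error their standard deviation.
#'
#' @param full_trajs `sai_trajectory` (or list of them, one per
#'   repetition) of the fully interacting solute-solvent system, with
#'   per-frame volumes.
#' @param water_trajs matching trajectory/trajectories of the water box
#'   with the solute removed.
#' @param full_system,water_system the systems the trajectories sample;
#'   `water_system` defaults to `full_system` minus the solute.
#' @param settings a [nonbonded_settings()].
#' @param discard fraction of frames dropped from the start of each
#'   trajectory.
#' @return An `lrc_result` with `method = "a_posteriori"`.
#' @export
a_posteriori_lrc <- function(full_trajs, water_trajs, full_system,
                             water_system = strip_solute(full_system),
                             settings = nonbonded_settings(),
                             discard = 1 / 3) {
  aslist <- function(x) if (inherits(x, "sai_trajectory")) list(x) else x
  full_trajs <- aslist(full_trajs); water_trajs <- aslist(water_trajs)
  if (length(full_trajs) != length(water_trajs))
    stop("need matching numbers of full and water repetitions")
  cf <- tail_coefficient(site_types(full_system), settings)
  cw <- tail_coefficient(site_types(water_system), settings)
  mean_tail <- function(traj, coeff) {
    if (is.null(traj$volumes) || !length(traj$volumes))
      stop("trajectory carries no volume data")
    v <- traj$volumes
    v <- v[seq.int(floor(discard * length(v)) + 1L, length(v))]
    mean(coeff / v)
  }
  fulls <- vapply(full_trajs, mean_tail, 0, coeff = cf)
  waters <- vapply(water_trajs, mean_tail, 0, coeff = cw)
  diffs <- fulls - waters
  lrc_result(mean(diffs),
             stderr = if (length(diffs) > 1L) sd(diffs) else 0,
             method = "a_posteriori",
             components = c(full = mean(fulls), water = mean(waters)))
}
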