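#' Nonbonded cutoff treatment settings
#'
#' Cutoff treatments mirror those compared in the underlying workflow:
#' the CHARMM potential switch (`VSWI`), the OpenMM native potential
#' switch (`OMM_VSWI`, a quintic smoothstep), the CHARMM force switch
#' (`VFSW`, Steinbach-Brooks form) and plain truncation (`NONE`).  LJ
#' interactions are tapered between `r_on` and `r_off`; Coulomb
#' interactions use minimum-image electrostatics with a potential-switch
#' taper (there is no Ewald summation in the toy engine, so comparisons
#' between LJ switch kinds differ only in the LJ treatment).
#'
#' @param r_on switch-on distance, Angstrom.
#' @param r_off cutoff distance, Angstrom; must exceed `r_on`.
#' @param switch_kind one of "OMM_VSWI", "VSWI", "VFSW", "NONE".
#' @param temperature Kelvin.
#' @param pressure atm (used for constant-pressure sampling and reduced
#'   potentials of NPT frames).
#' @param coulomb_constant kcal Angstrom / (mol e^2).
#' @export
nonbonded_settings <- function(r_on = 10, r_off = 12,
                               switch_kind = c("OMM_VSWI", "VSWI", "VFSW",
                                               "NONE"),
                               temperature = 303.15, pressure = 1,
                               coulomb_constant = 332.0637) {
  switch_kind <- match.arg(switch_kind)
  if (!(r_on > 0 && r_on < r_off))
    stop("need 0 < r_on < r_off (got r_on = ", r_on, ", r_off = ", r_off, ")")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(r_on = r_on, r_off = r_off, switch_kind = switch_kind,
                 temperature = temperature, pressure = pressure,
                 coulomb_constant = coulomb_constant),
            class = "nonbonded_settings")
}

switch_kind_code <- function(kind) {
  match(kind, c("NONE", "VSWI", "OMM_VSWI", "VFSW")) - 1L
}

settings_cpp <- function(settings) {
  list(r_on = settings$r_on, r_off = settings$r_off,
       kind = switch_kind_code(settings$switch_kind),
       kcoul = settings$coulomb_constant)
}

beta_of <- function(settings) 1 / (.kB * settings$temperature)

#' Switching-function factor
#'
#' Unitless taper applied to the LJ potential: 1 below `r_on`, 0 above
#' `r_off`.  `OMM_VSWI` uses the quintic smoothstep
#' `S = 1 - 10x^3 + 15x^4 - 6x^5` with `x = (r - r_on)/(r_off - r_on)`;
#' `VSWI` uses the CHARMM form
#' `S = (r_off^2 - r^2)^2 (r_off^2 + 2r^2 - 3r_on^2) / (r_off^2 - r_on^2)^3`.
#' `VFSW` modifies the potential form rather than multiplying it, so it
#' has no multiplier; requesting it returns `NA` as a sentinel (see
#' [lj_energy()]).
#'
#' @param r distance(s), Angstrom.
#' @param settings a [nonbonded_settings()].
#' @export
switching_factor <- function(r, settings) {
  stopifnot(all(r >= 0))
  if (settings$switch_kind == "VFSW") return(rep(NA_real_, length(r)))
  cpp_switch_factor(as.numeric(r), settings$r_on, settings$r_off,
                    switch_kind_code(settings$switch_kind))
}

#' Lennard-Jones pair energy under a cutoff treatment
#'
#' Base form `U = eps[(r_min/r)^12 - 2 (r_min/r)^6]` (so `U(r_min) = -eps`).
#' Potential-switch kinds multiply `U` by the switching factor; `VFSW`
#' applies the CHARMM force-switch form (continuous force at `r_on`, energy
#' and force zero at `r_off`).
#'
#' @param r distance(s), Angstrom.
#' @param r_min,epsilon combined LJ minimum distance (Angstrom) and well
#'   depth (kcal/mol).
#' @param settings a [nonbonded_settings()].
#' @param cutoff apply the cutoff treatment (FALSE gives the plain form,
#'   as used in vacuum legs).
#' @export
lj_energy <- function(r, r_min, epsilon, settings, cutoff = TRUE) {
  stopifnot(all(r > 0))
  cpp_lj_energy(as.numeric(r), r_min, epsilon, settings$r_on, settings$r_off,
                switch_kind_code(settings$switch_kind), cutoff)
}

#' Separation-shifted soft-core Lennard-Jones energy
#'
#' Evaluates the plain LJ form at `r_eff = sqrt(r^2 + alpha (1 - lam))`
#' and multiplies by `lam`, so `lam = 1` recovers plain LJ exactly and
#' `lam = 0` gives zero for all r.  This removes the endpoint singularity
#' that the serial-atom-insertion protocol avoids by construction; it is
#' used by the thermodynamic-integration reference route.
#'
#' @param r distance(s), Angstrom.
#' @param lam coupling in `[0, 1]`.
#' @param r_min,epsilon LJ parameters.
#' @param alpha separation shift, Angstrom^2.
#' @export
softcore_lj_energy <- function(r, lam, r_min, epsilon, alpha = 5) {
  stopifnot(lam >= 0, lam <= 1, all(r >= 0))
  cpp_softcore_lj(as.numeric(r), lam, r_min, epsilon, alpha)
}

state_coupling <- function(state, n_atoms) {
  if (is.null(state))
    list(mode = 0L, qs = rep(1, n_atoms), ljs = rep(1, n_atoms))
  else
    list(mode = 0L, qs = as.numeric(state$charge_scale),
         ljs = as.numeric(state$lj_scale))
}

check_box <- function(system, settings) {
  if (system$periodic && system$box_edge < 2 * settings$r_off)
    stop("periodic box edge ", system$box_edge,
         " A is smaller than 2 * r_off = ", 2 * settings$r_off, " A")
}

#' Total nonbonded energy of a toy system
#'
#' Deterministic pair sum (minimum image for periodic boxes) of LJ and
#' Coulomb terms with a state's scaling applied; intra-solute nonbonded
#' terms exclude 1-2 and 1-3 bonded neighbours.  Components are reported
#' separately and sum to the total.
#'
#' @param system a [solvated_system()].
#' @param state an intermediate state (NULL for the physical state).
#' @param settings a [nonbonded_settings()].
#' @return named numeric: `total`, `solute_solvent`, `intra_solute`,
#'   `solvent_solvent`, `bonded` (kcal/mol).
#' @export
total_energy <- function(system, state = NULL, settings = nonbonded_settings()) {
  check_box(system, settings)
  flat <- flatten_system(system)
  cpp_total_energy(flat, settings_cpp(settings),
                   state_coupling(state, flat$ns))
}

#' Sample a toy system by Metropolis Monte Carlo
#'
#' Stands in for the molecular dynamics runs of the full-scale workflow:
#' any valid Boltzmann sampler suffices because the estimators consume
#' configurations only.  Moves are single solute-atom translations, rigid
#' whole-solute translation/rotation, rigid-body water translation+rotation,
#' and (for `npt = TRUE`) isotropic volume moves.  Step sizes are
#' auto-tuned toward an acceptance rate of 0.2-0.6 during a discarded
#' tuning phase; a fixed seed gives a bit-identical trajectory.
#'
#' @param system a [solvated_system()].
#' @param state intermediate state (NULL = physical).
#' @param settings a [nonbonded_settings()].
#' @param n_sweeps production sweeps; one frame is kept every `save_every`
#'   sweeps.
#' @param seed integer seed.
#' @param n_tune discarded tuning sweeps.
#' @param save_every sweeps between saved frames.
#' @param npt sample at constant pressure (adds volume moves; frames then
#'   carry instantaneous volumes for the beta*p*V reduced-potential term).
#' @param softcore_lambda if non-NULL, sample the soft-core reference path
#'   at this coupling value instead of an SAI state.
#' @param alpha separation shift of the soft-core path, Angstrom^2.
#' @return A `sai_trajectory`: frame array (n_frames x sites x 3), per-frame
#'   box edges and volumes, acceptance rates.
#' @export
mc_sample <- function(system, state = NULL, settings = nonbonded_settings(),
                      n_sweeps = 1000, seed = 1, n_tune = 200,
                      save_every = 2, npt = FALSE, softcore_lambda = NULL,
                      alpha = 5) {
  stopifnot(n_sweeps > 0)
  check_box(system, settings)
  flat <- flatten_system(system)
  coupling <- if (is.null(softcore_lambda)) state_coupling(state, flat$ns)
              else list(mode = 1L, lambda = softcore_lambda, alpha = alpha)
  control <- list(beta = beta_of(settings),
                  pressure_red = settings$pressure * .atm_to_kcal_A3,
                  npt = npt, n_tune = as.integer(n_tune),
                  n_sweeps = as.integer(n_sweeps),
                  save_every = as.integer(save_every),
                  step_atom = 0.25, step_solute = 0.3, step_water = 0.25)
  set.seed(seed)
  out <- cpp_mc_sample(flat, settings_cpp(settings), coupling, control)
  new_trajectory(out$frames, boxes = out$boxes, volumes = out$volumes,
                 state_index = if (is.null(state)) NA_integer_ else state$index,
                 seed = seed, acceptance = out$acceptance, npt = npt)
}

#' Analytic reduced free energy of a harmonic oscillator
#'
#' Per degree of freedom, `f = 1/2 log(k / (2 pi kB T))` in reduced
#' (unitless) units, so the difference between two force constants is
#' `1/2 log(k2/k1)`.  Used as a closed-form validation oracle for the
#' MBAR solver.
#'
#' @param k force constant, kcal/mol/Angstrom^2 (> 0).
#' @param temperature Kelvin.
#' @export
harmonic_reference <- function(k, temperature = 303.15) {
  if (any(k <= 0)) stop("force constant must be > 0")
  0.5 * log(k / (2 * pi * .kB * temperature))
}
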