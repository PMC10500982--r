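# End-to-end ASFE orchestration: schedule -> per-state sampling of both
# legs -> reduced-potential matrix -> MBAR -> repeat aggregation -> LRC ->
# combined ASFE.  A soft-core thermodynamic-integration reference route is
# provided for cross-validation (path independence of the endpoints).

#' Run configuration for a toy ASFE calculation
#'
#' @param schedule a [schedule_config()].
#' @param nonbonded a [nonbonded_settings()].  Toy systems use reduced
#'   cutoffs; the box must satisfy `box_edge >= 2 r_off`.
#' @param n_sweeps production MC sweeps per state.
#' @param n_tune discarded tuning sweeps per state.
#' @param save_every sweeps between saved frames.
#' @param equil_fraction fraction of each trajectory discarded as
#'   equilibration before the estimator (default 0.25).
#' @param repeats independent repeats with distinct seeds (default 4);
#'   repeat r uses `base_seed + r` as its seed offset.
#' @param base_seed integer.
#' @param lrc "analytic", "a_posteriori" or "none".
#' @export
asfe_config <- function(schedule = schedule_config(),
                        nonbonded = nonbonded_settings(r_on = 4, r_off = 5),
                        n_sweeps = 1500, n_tune = 300, save_every = 3,
                        equil_fraction = 0.25, repeats = 4, base_seed = 1,
                        lrc = c("analytic", "a_posteriori", "none")) {
  stopifnot(repeats >= 1, equil_fraction >= 0, equil_fraction < 1)
  structure(list(schedule = schedule, nonbonded = nonbonded,
                 n_sweeps = n_sweeps, n_tune = n_tune,
                 save_every = save_every, equil_fraction = equil_fraction,
                 repeats = repeats, base_seed = base_seed,
                 lrc = match.arg(lrc)),
            class = "asfe_config")
}

leg_seed <- function(base_seed, repeat_i, leg, k) {
  # distinct, reproducible, < 2^31
  ((base_seed + repeat_i) * 97L + leg * 31L) * 1009L + k
}

# sample every schedule state of one leg and return the MBAR annihilation
# free energy in kcal/mol (plus diagnostics)
sample_leg_mbar <- function(system, schedule, config, leg_id, repeat_i) {
  settings <- config$nonbonded
  trajs <- lapply(schedule$states, function(s)
    mc_sample(system, state = s, settings = settings,
              n_sweeps = config$n_sweeps, n_tune = config$n_tune,
              save_every = config$save_every,
              seed = leg_seed(config$base_seed, repeat_i, leg_id, s$index)))
  trajs <- lapply(trajs, discard_equilibration,
                  fraction = config$equil_fraction)
  em <- reduced_potential_matrix(trajs, schedule, system, settings)
  fit <- mbar_solve(em)
  ov <- withCallingHandlers(overlap_matrix(fit),
                            warning = function(w) invokeRestart("muffleWarning"))
  K <- length(schedule$states)
  adj <- if (K > 1L) vapply(seq_len(K - 1L), function(k) ov[k, k + 1L], 0)
         else 1
  list(delta_g = mbar_delta_f(fit, units = "kcal/mol"),
       min_overlap = min(adj), fit = fit)
}

#' Compute a toy ASFE by the SAI/MBAR route
#'
#' Orchestrates the full workflow for one solvated toy system: builds the
#' annihilation schedule, samples every intermediate state of the vacuum
#' and aqueous legs (independently for each repeat), estimates both leg
#' free energies by MBAR, adds the LJ long-range correction, and combines
#' them as `ASFE = dG_vac - dG_aq + dG_LRC`.  Uncertainties are standard
#' deviations over the repeats; low adjacent-state overlap is reported in
#' the diagnostics.
#'
#' @param system a solvated [solvated_system()] (the vacuum companion is
#'   derived automatically).
#' @param config an [asfe_config()].
#' @return An object of class `asfe_result`.
#' @export
run_asfe <- function(system, config = asfe_config()) {
  check_box(system, config$nonbonded)
  schedule <- build_schedule(system$solute, config$schedule)
  vac_sys <- vacuum_system(system)
  vac_g <- aq_g <- numeric(config$repeats)
  min_ov <- Inf
  for (r in seq_len(config$repeats)) {
    vres <- sample_leg_mbar(vac_sys, schedule, config, leg_id = 0L,
                            repeat_i = r)
    ares <- sample_leg_mbar(system, schedule, config, leg_id = 1L,
                            repeat_i = r)
    vac_g[r] <- vres$delta_g
    aq_g[r] <- ares$delta_g
    min_ov <- min(min_ov, ares$min_overlap, vres$min_overlap)
  }
  agg <- function(x, leg) {
    if (length(x) > 1L) {
      a <- aggregate_repeats(x)
      free_energy_result(a$mean, a$sd, x, leg = leg, method = "MBAR")
    } else free_energy_result(x, 0, x, leg = leg, method = "MBAR")
  }
  vac <- agg(vac_g, "vacuum")
  aq <- agg(aq_g, "aqueous")
  lrc <- switch(config$lrc,
                analytic = lrc_correction(system, config$nonbonded),
                none = lrc_result(0, 0, "none"),
                a_posteriori = sample_a_posteriori_lrc(system, config))
  est <- combine_asfe(vac, aq, lrc)
  structure(list(asfe = est$asfe, stderr = est$stderr, vac = vac, aq = aq,
                 lrc = lrc, schedule = schedule, config = config,
                 min_overlap = min_ov, method = "MBAR"),
            class = "asfe_result")
}

#' @export
print.asfe_result <- function(x, ...) {
  cat(sprintf("Toy ASFE (%s route, %d states, %d repeats)\n", x$method,
              length(x$schedule$states), x$config$repeats))
  cat(sprintf("  ASFE        = %8.4f +/- %.4f kcal/mol\n", x$asfe, x$stderr))
  cat(sprintf("  vacuum leg  = %8.4f +/- %.4f\n", x$vac$delta_g, x$vac$stderr))
  cat(sprintf("  aqueous leg = %8.4f +/- %.4f\n", x$aq$delta_g, x$aq$stderr))
  cat(sprintf("  LJ LRC      = %8.4f +/- %.4f (%s)\n", x$lrc$value,
              x$lrc$stderr, x$lrc$method))
  if (is.finite(x$min_overlap) && x$min_overlap < 0.03)
    cat(sprintf("  warning: min adjacent-state overlap %.3f < 0.03\n",
                x$min_overlap))
  invisible(x)
}

#' @export
summary.asfe_result <- function(object, ...) {
  print(object)
  cat("Per-repeat leg free energies (kcal/mol):\n")
  print(data.frame(repeat_ = seq_along(object$vac$per_repeat),
                   vacuum = object$vac$per_repeat,
                   aqueous = object$aq$per_repeat), row.names = FALSE)
  invisible(object)
}

#' Compute a toy ASFE by the soft-core thermodynamic-integration route
#'
#' Reference route: both legs are annihilated along a single coupling
#' parameter lambda in `[0, 1]` with separation-shifted (soft-core) LJ and
#' Coulomb interactions for all solute-involving pairs.  Each of the
#' `n_lambda` equidistant states is sampled by MC, `<dU/dlambda>` is
#' accumulated (first 10% of samples discarded as burn-in), and the
#' profile is integrated analytically with a natural cubic spline.
#'
#' @param system a solvated [solvated_system()].
#' @param config an [asfe_config()] (schedule settings are ignored).
#' @param n_lambda number of equidistant lambda states (default 21).
#' @param alpha separation shift in Angstrom^2.
#' @param burn_in fraction of samples discarded per lambda.
#' @return An `asfe_result` with `method = "TI"`.
#' @export
run_asfe_ti <- function(system, config = asfe_config(), n_lambda = 21,
                        alpha = 5, burn_in = 0.1) {
  check_box(system, config$nonbonded)
  settings <- config$nonbonded
  lambdas <- seq(0, 1, length.out = n_lambda)
  leg_dg <- function(sys, leg_id, repeat_i) {
    flat <- flatten_system(sys)
    means <- vapply(seq_along(lambdas), function(i) {
      traj <- mc_sample(sys, settings = settings,
                        n_sweeps = config$n_sweeps, n_tune = config$n_tune,
                        save_every = config$save_every,
                        seed = leg_seed(config$base_seed, repeat_i,
                                        leg_id + 2L, i),
                        softcore_lambda = lambdas[i], alpha = alpha)
      traj <- discard_equilibration(traj, fraction = burn_in)
      dudl <- cpp_dudl_frames(traj$frames, traj$boxes, flat,
                              settings_cpp(settings), lambdas[i], alpha)
      mean(dudl)
    }, 0)
    ti_estimate(ti_profile(lambdas, means))$delta_g
  }
  vac_sys <- vacuum_system(system)
  vac_g <- aq_g <- numeric(config$repeats)
  for (r in seq_len(config$repeats)) {
    vac_g[r] <- leg_dg(vac_sys, 0L, r)
    aq_g[r] <- leg_dg(system, 1L, r)
  }
  agg <- function(x, leg) {
    if (length(x) > 1L) {
      a <- aggregate_repeats(x)
      free_energy_result(a$mean, a$sd, x, leg = leg, method = "TI")
    } else free_energy_result(x, 0, x, leg = leg, method = "TI")
  }
  vac <- agg(vac_g, "vacuum")
  aq <- agg(aq_g, "aqueous")
  lrc <- switch(config$lrc,
                analytic = lrc_correction(system, settings),
                none = lrc_result(0, 0, "none"),
                a_posteriori = sample_a_posteriori_lrc(system, config))
  est <- combine_asfe(vac, aq, lrc)
  structure(list(asfe = est$asfe, stderr = est$stderr, vac = vac, aq = aq,
                 lrc = lrc, schedule = NULL, config = config,
                 min_overlap = NA_real_, method = "TI"),
            class = "asfe_result")
}

# constant-pressure sampling of the full and water-only systems for the
# a-posteriori LRC (default three repetitions with distinct seeds)
sample_a_posteriori_lrc <- function(system, config, repetitions = 3) {
  settings <- config$nonbonded
  water_sys <- strip_solute(system)
  full <- lapply(seq_len(repetitions), function(r)
    mc_sample(system, settings = settings, n_sweeps = config$n_sweeps,
              n_tune = config$n_tune, save_every = config$save_every,
              seed = leg_seed(config$base_seed, r, 5L, 1L), npt = TRUE))
  water <- lapply(seq_len(repetitions), function(r)
    mc_sample(water_sys, settings = settings, n_sweeps = config$n_sweeps,
              n_tune = config$n_tune, save_every = config$save_every,
              seed = leg_seed(config$base_seed, r, 6L, 1L), npt = TRUE))
  a_posteriori_lrc(full, water, system, water_sys, settings)
}
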