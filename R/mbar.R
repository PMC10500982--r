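#' Discard the equilibration part of a trajectory
#'
#' Drops the first `floor(fraction * n)` frames, keeping the last
#' `ceiling((1 - fraction) * n)`; with the default 25% a 10,000-frame
#' trajectory keeps 7,500 frames.
#'
#' @param traj a `sai_trajectory`.
#' @param fraction in `[0, 1)`.
#' @export
discard_equilibration <- function(traj, fraction = 0.25) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- traj$n_frames
  if (n == 0L) stop("empty trajectory")
  drop <- floor(fraction * n)
  keep <- seq.int(drop + 1L, n)
  traj$frames <- traj$frames[keep, , , drop = FALSE]
  traj$boxes <- traj$boxes[keep]
  traj$volumes <- traj$volumes[keep]
  traj$n_frames <- length(keep)
  traj
}

#' Reduced-potential matrix u(x, k) for MBAR
#'
#' Re-evaluates every retained frame of every per-state trajectory under
#' every state's parameters: `u(x, k) = beta * U_k(x)`, plus
#' `beta * p * V(x)` when the frames carry instantaneous volumes
#' (constant-pressure sampling).  Vacuum legs never include the pressure
#' term.
#'
#' @param trajs list of `sai_trajectory`, one per schedule state, in state
#'   order.
#' @param schedule the [build_schedule()] result the trajectories were
#'   sampled under.
#' @param system the physical-state [solvated_system()].
#' @param settings a [nonbonded_settings()].
#' @return An object of class `energy_matrix` with fields `u` (N x K),
#'   `N_k`, `beta`, `pressure_term`.
#' @export
reduced_potential_matrix <- function(trajs, schedule, system,
                                     settings = nonbonded_settings()) {
  K <- length(schedule$states)
  if (length(trajs) != K)
    stop("need one trajectory per state (", K, "), got ", length(trajs))
  flat <- flatten_system(system)
  couplings <- lapply(schedule$states, state_coupling, n_atoms = flat$ns)
  beta <- beta_of(settings)
  use_pv <- any(vapply(trajs, function(t) isTRUE(t$npt), logical(1)))
  blocks <- lapply(trajs, function(traj) {
    u <- cpp_energy_frames(traj$frames, traj$boxes, flat,
                           settings_cpp(settings), couplings) * beta
    if (use_pv && isTRUE(traj$npt))
      u <- u + beta * settings$pressure * .atm_to_kcal_A3 * traj$volumes
    u
  })
  u <- do.call(rbind, blocks)
  if (!all(is.finite(u))) stop("non-finite reduced potentials")
  structure(list(u = u, N_k = vapply(trajs, function(t) t$n_frames, 0L),
                 beta = beta, pressure_term = use_pv),
            class = "energy_matrix")
}

#' Construct an energy matrix directly
#'
#' For analytically sampled validation problems (e.g. harmonic states) the
#' N x K reduced-potential matrix can be supplied directly.
#'
#' @param u N x K matrix of reduced potentials, rows grouped by generating
#'   state.
#' @param N_k samples contributed per state (sums to N).
#' @param beta 1/(kB T) in mol/kcal (bookkeeping only).
#' @export
energy_matrix <- function(u, N_k, beta = 1) {
  u <- as.matrix(u)
  stopifnot(sum(N_k) == nrow(u), ncol(u) == length(N_k), all(is.finite(u)))
  structure(list(u = u, N_k = as.integer(N_k), beta = beta,
                 pressure_term = FALSE), class = "energy_matrix")
}

#' Solve the self-consistent MBAR equations
#'
#' Computes per-state reduced free energies `f_k` from the reduced-potential
#' matrix by the multistate Bennett acceptance ratio: the self-consistent
#' solution of
#' `f_i = -log sum_n exp(-u_i(x_n)) / sum_k N_k exp(f_k - u_k(x_n))`,
#' log-sum-exp stabilized, anchored at `f_1 = 0`.  Self-consistent
#' iteration is polished with Newton steps on the (convex) MBAR objective;
#' convergence requires `max |delta f| < tol` between iterations.
#'
#' @param matrix an `energy_matrix`.
#' @param tol convergence tolerance on f (default 1e-10).
#' @param max_iter iteration cap.
#' @return An object of class `mbar_fit`: `f` (reduced free energies,
#'   `f[1] = 0`), `W` (N x K weight matrix), `N_k`, `beta`, iteration
#'   diagnostics.  On non-convergence an error carrying the current
#'   overlap matrix is raised.
#' @export
mbar_solve <- function(matrix, tol = 1e-10, max_iter = 1e5) {
  u <- matrix$u
  N_k <- matrix$N_k
  if (any(N_k <= 0)) stop("every state must contribute samples (N_k > 0)")
  K <- ncol(u); N <- nrow(u)
  logN <- log(N_k)
  f <- numeric(K)
  # log denominator per sample: logsumexp_k(log N_k + f_k - u_nk)
  log_denom <- function(f) row_logsumexp(sweep(-u, 2L, logN + f, "+"))
  sc_update <- function(f) {
    ld <- log_denom(f)
    fn <- -apply(-u - ld, 2L, logsumexp)
    fn - fn[1L]
  }
  # convex MBAR objective and derivatives (for the Newton polish)
  obj_grad <- function(f) {
    ld <- log_denom(f)
    W <- exp(sweep(-u, 2L, f, "+") - ld) # W_nk = exp(f_k - u_nk)/denom
    grad <- N_k * (colSums(W) - 1)
    list(ld = ld, W = W, grad = grad)
  }
  it <- 0L; converged <- FALSE
  repeat {
    fn <- sc_update(f)
    delta <- max(abs(fn - f)); f <- fn; it <- it + 1L
    if (delta < 1e-2 || it >= 200L) break
  }
  while (it < max_iter) {
    og <- obj_grad(f)
    W <- og$W
    WN <- sweep(W, 2L, N_k, "*")
    H <- -crossprod(WN, WN) # K x K
    diag(H) <- diag(H) + N_k * colSums(W)
    idx <- 2:K
    step <- tryCatch(solve(H[idx, idx, drop = FALSE], og$grad[idx]),
                     error = function(e) NULL)
    if (is.null(step)) { # fall back to self-consistent iteration
      fn <- sc_update(f)
      delta <- max(abs(fn - f)); f <- fn; it <- it + 1L
      if (delta < tol) { converged <- TRUE; break }
      next
    }
    fn <- f; fn[idx] <- fn[idx] - step
    fn <- fn - fn[1L]
    # safeguard: halve the Newton step if it is large
    if (max(abs(fn - f)) > 10) fn <- (f + fn) / 2
    delta <- max(abs(fn - f)); f <- fn; it <- it + 1L
    if (delta < tol) { converged <- TRUE; break }
  }
  og <- obj_grad(f)
  if (!converged) {
    fit <- structure(list(f = f, W = og$W, N_k = N_k, beta = matrix$beta,
                          iterations = it, converged = FALSE),
                     class = "mbar_fit")
    cond <- simpleError(paste0("MBAR did not converge after ", it,
                               " iterations"))
    cond$overlap <- overlap_matrix(fit)
    stop(cond)
  }
  structure(list(f = f, W = og$W, N_k = N_k, beta = matrix$beta,
                 iterations = it, converged = TRUE),
            class = "mbar_fit")
}

#' @export
print.mbar_fit <- function(x, ...) {
  cat(sprintf("MBAR fit: %d states, N = %d samples, %d iterations\n",
              length(x$f), sum(x$N_k), x$iterations))
  cat("f_k (reduced):", paste(signif(x$f, 6), collapse = " "), "\n")
  invisible(x)
}

#' Free energy difference between two states of an MBAR fit
#'
#' @param fit an `mbar_fit`.
#' @param i,j state indices (default: first to last).
#' @param units "reduced" or "kcal/mol" (divides by beta).
#' @export
mbar_delta_f <- function(fit, i = 1L, j = length(fit$f),
                         units = c("reduced", "kcal/mol")) {
  units <- match.arg(units)
  d <- fit$f[j] - fit$f[i]
  if (units == "kcal/mol") d / fit$beta else d
}

#' MBAR overlap matrix
#'
#' `O_ij = sum_n W_ni W_nj N_j`; rows sum to 1.  Low overlap between
#' adjacent intermediate states signals unreliable free energy
#' differences; a warning is emitted when any adjacent-state overlap is
#' below `warn_below`.
#'
#' @param fit an `mbar_fit`.
#' @param warn_below adjacent-overlap warning threshold.
#' @export
overlap_matrix <- function(fit, warn_below = 0.03) {
  O <- sweep(crossprod(fit$W), 2L, fit$N_k, "*")
  K <- ncol(O)
  if (K > 1L) {
    adj <- vapply(seq_len(K - 1L), function(k) O[k, k + 1L], 0)
    if (any(adj < warn_below))
      warning("low adjacent-state overlap (min ",
              signif(min(adj), 3), ") between states ",
              paste(which(adj < warn_below), collapse = ", "),
              " and their successors")
  }
  O
}

#' Within-run bootstrap uncertainty of an MBAR free energy difference
#'
#' Secondary diagnostic next to the repeat-based standard deviation:
#' resamples frames within each state with replacement and re-solves MBAR
#' (warm-started from the full-data solution).
#'
#' @param matrix an `energy_matrix`.
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param i,j states to difference (default first to last).
#' @return standard error of `f_j - f_i` (reduced units).
#' @export
mbar_bootstrap_stderr <- function(matrix, B = 50, seed = 1, i = 1L,
                                  j = ncol(matrix$u)) {
  set.seed(seed)
  N_k <- matrix$N_k
  offs <- cumsum(c(0L, N_k))
  reps <- vapply(seq_len(B), function(b) {
    rows <- unlist(lapply(seq_along(N_k), function(k)
      offs[k] + sample.int(N_k[k], N_k[k], replace = TRUE)))
    em <- energy_matrix(matrix$u[rows, , drop = FALSE], N_k, matrix$beta)
    fit <- mbar_solve(em)
    fit$f[j] - fit$f[i]
  }, 0)
  sd(reps)
}
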