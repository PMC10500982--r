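#' Free energy result for one leg
#'
#' @param delta_g kcal/mol.
#' @param stderr kcal/mol (standard deviation over independent repeats,
#'   following the repeat-based error protocol).
#' @param per_repeat the per-repeat free energies.
#' @param leg "vacuum", "aqueous" or "unknown".
#' @param method "MBAR" or "TI".
#' @export
free_energy_result <- function(delta_g, stderr = 0, per_repeat = delta_g,
                               leg = c("unknown", "vacuum", "aqueous"),
                               method = c("MBAR", "TI")) {
  leg <- match.arg(leg); method <- match.arg(method)
  stopifnot(stderr >= 0)
  structure(list(delta_g = delta_g, stderr = stderr,
                 per_repeat = per_repeat, leg = leg, method = method),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("dG(%s, %s) = %.4f +/- %.4f kcal/mol (%d repeat%s)\n",
              x$leg, x$method, x$delta_g, x$stderr, length(x$per_repeat),
              if (length(x$per_repeat) == 1L) "" else "s"))
  invisible(x)
}

#' Aggregate independent repeats into mean and standard deviation
#'
#' Statistical errors follow the repeat protocol: each repeat yields an
#' independent free energy difference; the reported uncertainty is the
#' sample standard deviation (`ddof = 1`) over those values.
#'
#' @param results numeric vector of per-repeat free energies (>= 2).
#' @return list with `mean` and `sd`.
#' @export
aggregate_repeats <- function(results) {
  results <- as.numeric(results)
  if (length(results) < 2L) stop("need at least 2 repeats")
  list(mean = mean(results), sd = sd(results))
}

#' Combine the two annihilation legs and the LRC into an ASFE
#'
#' Both legs must be annihilation free energies (physical -> fully
#' decoupled).  The absolute solvation free energy follows the
#' thermodynamic cycle `ASFE = dG_vac - dG_aq + dG_LRC`; the uncertainty
#' is the quadrature sum of the three standard errors.
#'
#' @param vac,aq `free_energy_result` objects for the vacuum and aqueous
#'   legs.
#' @param lrc an `lrc_result` (see [analytic_tail()]), a numeric value in
#'   kcal/mol, or NULL for no correction.
#' @return An object of class `asfe_estimate` with `asfe`, `stderr` and
#'   the components.
#' @export
combine_asfe <- function(vac, aq, lrc = NULL) {
  stopifnot(inherits(vac, "free_energy_result"),
            inherits(aq, "free_energy_result"))
  if (is.null(lrc)) lrc <- list(value = 0, stderr = 0)
  if (is.numeric(lrc)) lrc <- list(value = lrc, stderr = 0)
  asfe <- vac$delta_g - aq$delta_g + lrc$value
  se <- sqrt(vac$stderr^2 + aq$stderr^2 + lrc$stderr^2)
  structure(list(asfe = asfe, stderr = se, vac = vac, aq = aq, lrc = lrc),
            class = "asfe_estimate")
}

#' @export
print.asfe_estimate <- function(x, ...) {
  cat(sprintf("ASFE = %.4f +/- %.4f kcal/mol\n", x$asfe, x$stderr))
  cat(sprintf("  vacuum leg  %.4f +/- %.4f\n", x$vac$delta_g, x$vac$stderr))
  cat(sprintf("  aqueous leg %.4f +/- %.4f\n", x$aq$delta_g, x$aq$stderr))
  cat(sprintf("  LJ LRC      %.4f +/- %.4f\n", x$lrc$value, x$lrc$stderr))
  invisible(x)
}
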