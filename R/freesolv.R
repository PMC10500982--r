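# Benchmark-statistics layer: FreeSolv-style flat-file parsing, error
# metrics with bootstrap confidence intervals, deviation-count tables, and
# per-functional-group / per-size summaries for comparing calculated and
# experimental absolute solvation free energies.

#' Parse a FreeSolv-style delimited flat file
#'
#' One record per data line; lines starting with `#` are comments.  The
#' default column mapping follows the upstream layout (compound id;
#' SMILES; iupac name; experimental value; experimental uncertainty;
#' calculated value; calculated uncertainty), but the positions are
#' configurable because the upstream column layout has changed across
#' releases.  All energies are kcal/mol.
#'
#' @param path file path.
#' @param delimiter field separator (default ";").
#' @param columns named integer vector mapping record fields to column
#'   positions.
#' @return data frame of class `freesolv_records` with columns
#'   `compound_id`, `smiles`, `name`, `expt`, `expt_unc`, `calc`,
#'   `calc_unc` and optional `group`.
#' @export
parse_freesolv <- function(path, delimiter = ";",
                           columns = c(compound_id = 1, smiles = 2, name = 3,
                                       expt = 4, expt_unc = 5, calc = 6,
                                       calc_unc = 7)) {
  ln <- readLines(path)
  keep <- !grepl("^\\s*#", ln) & nzchar(trimws(ln))
  if (!any(keep)) {
    out <- data.frame(compound_id = character(0), smiles = character(0),
                      name = character(0), expt = numeric(0),
                      expt_unc = numeric(0), calc = numeric(0),
                      calc_unc = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("freesolv_records", "data.frame")
    return(out)
  }
  lines <- which(keep)
  parts <- strsplit(ln[keep], delimiter, fixed = TRUE)
  ncol_needed <- max(columns)
  bad <- vapply(parts, length, 0L) < ncol_needed
  if (any(bad))
    stop("parse error: wrong column count (need >= ", ncol_needed,
         ") on line(s) ", paste(lines[bad], collapse = ", "))
  field <- function(i) trimws(vapply(parts, `[[`, "", columns[[i]]))
  num <- function(i) {
    v <- suppressWarnings(as.numeric(field(i)))
    if (anyNA(v))
      stop("parse error: non-numeric ", i, " on line(s) ",
           paste(lines[is.na(v)], collapse = ", "))
    v
  }
  out <- data.frame(compound_id = field("compound_id"),
                    smiles = field("smiles"), name = field("name"),
                    expt = num("expt"), expt_unc = num("expt_unc"),
                    calc = num("calc"), calc_unc = num("calc_unc"),
                    stringsAsFactors = FALSE)
  if (any(out$expt_unc < 0) || any(out$calc_unc < 0))
    stop("uncertainties must be >= 0")
  class(out) <- c("freesolv_records", "data.frame")
  out
}

#' Read a groups file and attach first-category functional groups
#'
#' The groups file maps compound id to one or more category labels; to
#' avoid double-counting polyfunctional compounds only the first listed
#' category is used.
#'
#' @param records a `freesolv_records` data frame.
#' @param path delimited text: compound id, then categories.
#' @param delimiter field separator.
#' @export
assign_groups <- function(records, path, delimiter = ";") {
  ln <- readLines(path)
  keep <- !grepl("^\\s*#", ln) & nzchar(trimws(ln))
  parts <- strsplit(ln[keep], delimiter, fixed = TRUE)
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  first <- trimws(vapply(parts, function(p)
    if (length(p) >= 2L) p[[2L]] else NA_character_, ""))
  records$group <- first[match(records$compound_id, ids)]
  records
}

#' Signed and absolute deviation of a calculated value
#'
#' @param calc,expt kcal/mol.
#' @return list with `signed` (`calc - expt`) and `absolute`.
#' @export
deviation <- function(calc, expt) {
  stopifnot(all(is.finite(calc)), all(is.finite(expt)))
  s <- calc - expt
  list(signed = s, absolute = abs(s))
}

#' Error metrics comparing calculated and experimental values
#'
#' RMSE, MAE, Pearson r and Spearman rho (average-rank ties) over the
#' record set, optionally with 95% bootstrap confidence intervals
#' (molecule-level resampling, percentile method).
#'
#' @param records a `freesolv_records` data frame (or any data frame with
#'   `calc` and `expt` columns), n >= 2.
#' @param ci compute bootstrap confidence intervals.
#' @param B bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `metric_report`.
#' @export
error_metrics <- function(records, ci = FALSE, B = 10000, seed = 1) {
  x <- records$calc; y <- records$expt
  n <- length(x)
  if (n < 2L) stop("need at least 2 records")
  pt <- .metric_point(x, y)
  cis <- NULL
  if (ci) {
    cis <- lapply(setNames(nm = names(pt)), function(m)
      bootstrap_ci(records, metric = m, B = B, seed = seed))
  }
  structure(list(rmse = pt[["rmse"]], mae = pt[["mae"]],
                 pearson_r = pt[["pearson_r"]],
                 spearman_rho = pt[["spearman_rho"]], n = n, ci = cis),
            class = "metric_report")
}

.metric_point <- function(x, y) {
  d <- x - y
  if (sd(x) == 0 || sd(y) == 0) {
    # RMSE/MAE are still well defined; correlations are not
    warning("correlation undefined for constant vectors")
    r <- rho <- NA_real_
  } else {
    r <- cor(x, y, method = "pearson")
    rho <- cor(x, y, method = "spearman")
  }
  c(rmse = sqrt(mean(d^2)), mae = mean(abs(d)), pearson_r = r,
    spearman_rho = rho)
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(nm, v) {
    ci <- x$ci[[nm]]
    if (is.null(ci)) sprintf("%.3f", v)
    else sprintf("%.3f [%.3f, %.3f]", v, ci[1L], ci[2L])
  }
  cat(sprintf("n = %d molecules\n", x$n))
  cat("  RMSE     ", fmt("rmse", x$rmse), "kcal/mol\n")
  cat("  MAE      ", fmt("mae", x$mae), "kcal/mol\n")
  cat("  Pearson  ", fmt("pearson_r", x$pearson_r), "\n")
  cat("  Spearman ", fmt("spearman_rho", x$spearman_rho), "\n")
  invisible(x)
}

#' Nonparametric bootstrap confidence interval for an error metric
#'
#' Resamples molecules with replacement and returns the percentile
#' interval `[2.5%, 97.5%]`; a fixed seed makes it reproducible.
#'
#' @param records data frame with `calc` and `expt`.
#' @param metric one of "rmse", "mae", "pearson_r", "spearman_rho", or a
#'   function(calc, expt).
#' @param B replicates.
#' @param seed RNG seed.
#' @param level confidence level.
#' @export
bootstrap_ci <- function(records, metric = "rmse", B = 10000, seed = 1,
                         level = 0.95) {
  n <- nrow(records)
  stopifnot(n >= 2L, B >= 1L)
  fn <- if (is.function(metric)) metric
        else function(x, y) .metric_point(x, y)[[metric]]
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    # degenerate resamples (e.g. one molecule drawn n times) yield NA
    # correlations; they are dropped from the percentile interval
    suppressWarnings(fn(records$calc[idx], records$expt[idx]))
  }, 0)
  a <- (1 - level) / 2
  unname(quantile(reps, c(a, 1 - a), na.rm = TRUE, type = 7))
}

#' Counts of molecules with large deviations
#'
#' For each threshold t, the number (and percentage) of records whose
#' absolute deviation from experiment exceeds t, as in the large-deviation
#' table of benchmark reports.
#'
#' @param records data frame with `calc` and `expt`.
#' @param thresholds kcal/mol.
#' @export
deviation_counts <- function(records, thresholds = c(2, 3, 4, 6)) {
  ad <- abs(records$calc - records$expt)
  n <- length(ad)
  counts <- vapply(thresholds, function(t) sum(ad > t), 0L)
  data.frame(threshold = thresholds, count = counts,
             percent = if (n > 0) 100 * counts / n else rep(NA_real_,
                                                            length(counts)))
}

#' Per-functional-group error summary
#'
#' Summarizes absolute deviations per group: MAE, median absolute error,
#' first/third quartiles, min/max and n.  Only groups with at least
#' `min_members` molecules are summarized; smaller groups are flagged as
#' below threshold.
#'
#' @param records data frame with `calc`, `expt` and `group` (each record
#'   carries at most one group: the first listed category).
#' @param min_members inclusion threshold (default 10).
#' @return list with data frames `summary` and `below_threshold`.
#' @export
group_summary <- function(records, min_members = 10) {
  records <- records[!is.na(records$group), , drop = FALSE]
  ad <- abs(records$calc - records$expt)
  sp <- split(ad, records$group)
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    data.frame(group = g, n = length(v), mae = mean(v),
               median_ae = median(v),
               q1 = unname(quantile(v, 0.25)), q3 = unname(quantile(v, 0.75)),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$n >= min_members
  list(summary = tab[ok, , drop = FALSE],
       below_threshold = tab[!ok, c("group", "n"), drop = FALSE])
}

#' Count heavy (non-hydrogen) atoms in a SMILES string
#'
#' Counts all non-hydrogen atoms, including halogens: bracket atoms
#' (except explicit hydrogens such as `[H]` / `[2H]`), the two-letter
#' organic-subset symbols Cl and Br, and the one-letter organic-subset
#' symbols (aromatic included).
#'
#' @param smiles character vector.
#' @return integer vector of heavy-atom counts.
#' @export
count_heavy_atoms <- function(smiles) {
  vapply(smiles, function(s) {
    toks <- regmatches(s, gregexpr(
      "\\[[^]]*\\]|Cl|Br|[BCNOPSFIbcnops]", s))[[1L]]
    sum(vapply(toks, function(t) {
      if (startsWith(t, "[")) {
        # bracket atom: drop isotope digits, look at the element symbol
        sym <- sub("^\\[[0-9]*", "", t)
        !grepl("^H[^a-z]|^H\\]", sym)
      } else TRUE
    }, logical(1)))
  }, 0L, USE.NAMES = FALSE)
}

#' MAE binned by heavy-atom count
#'
#' Groups records by the number of heavy atoms (computed from SMILES if
#' not supplied) and reports the per-bin MAE with a bootstrap band; bins
#' with a single molecule are reported without a band.
#'
#' @param records data frame with `calc`, `expt` and either `heavy_atoms`
#'   or `smiles`.
#' @param B bootstrap replicates per bin.
#' @param seed RNG seed.
#' @export
error_by_size <- function(records, B = 1000, seed = 1) {
  ha <- records$heavy_atoms %||% count_heavy_atoms(records$smiles)
  ad <- abs(records$calc - records$expt)
  sp <- split(ad, ha)
  set.seed(seed)
  rows <- lapply(names(sp), function(h) {
    v <- sp[[h]]
    if (length(v) > 1L) {
      reps <- vapply(seq_len(B), function(b)
        mean(sample(v, length(v), replace = TRUE)), 0)
      lo <- unname(quantile(reps, 0.025)); hi <- unname(quantile(reps, 0.975))
    } else lo <- hi <- NA_real_
    data.frame(heavy_atoms = as.integer(h), n = length(v), mae = mean(v),
               ci_low = lo, ci_high = hi)
  })
  out <- do.call(rbind, rows)
  out[order(out$heavy_atoms), , drop = FALSE]
}
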