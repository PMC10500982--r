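#' Configuration of the SAI annihilation schedule
#'
#' Defaults follow the published protocol: partial charges are scaled by
#' 1.0, 0.6, 0.3, 0.0 over four states; hydrogen LJ parameters are scaled
#' jointly to zero in two steps (0.5, 0.0); heavy atoms are then switched
#' off one per state, except the last heavy atom which is removed in two
#' states (0.5, 0.0).  A terminal all-zero bookkeeping state is emitted by
#' default so that a seven-heavy-atom solute (toluene-like) yields 15
#' intermediate states.
#'
#' @param charge_factors numeric, starting at 1 and strictly decreasing
#'   to 0.
#' @param hydrogen_lj_factors joint hydrogen LJ factors, strictly
#'   decreasing to 0.
#' @param last_heavy_factors LJ factors for the final heavy atom.
#' @param emit_terminal_state emit a duplicated fully-decoupled terminal
#'   state (MBAR is unaffected by a duplicated endpoint).
#' @export
schedule_config <- function(charge_factors = c(1.0, 0.6, 0.3, 0.0),
                            hydrogen_lj_factors = c(0.5, 0.0),
                            last_heavy_factors = c(0.5, 0.0),
                            emit_terminal_state = TRUE) {
  chk <- function(x, nm, from_one) {
    if (any(diff(x) >= 0) || x[length(x)] != 0)
      stop(nm, " must be strictly decreasing and end at 0")
    if (from_one && x[1L] != 1) stop(nm, " must begin at 1.0")
  }
  chk(charge_factors, "charge_factors", TRUE)
  chk(hydrogen_lj_factors, "hydrogen_lj_factors", FALSE)
  chk(last_heavy_factors, "last_heavy_factors", FALSE)
  structure(list(charge_factors = charge_factors,
                 hydrogen_lj_factors = hydrogen_lj_factors,
                 last_heavy_factors = last_heavy_factors,
                 emit_terminal_state = isTRUE(emit_terminal_state)),
            class = "schedule_config")
}

#' Heavy-atom removal order for serial atom insertion
#'
#' Determines the order in which heavy atoms are switched off so that the
#' still-interacting heavy-atom region stays connected after every removal
#' (the intent of serial atom insertion: peel the molecule from its
#' periphery inward).  At each step, among the remaining heavy atoms whose
#' removal leaves the remainder connected (non-cut vertices), the atom with
#' the smallest current degree is removed; ties are broken by smallest
#' original degree, then by ascending atom index.  For rings no leaf
#' exists, so the rule opens the ring at the lowest-index atom of minimal
#' degree and then continues pruning.
#'
#' @param topology a [solute_topology()] with a connected heavy-atom graph.
#' @return integer vector of heavy-atom indices in removal order.
#' @export
heavy_atom_removal_order <- function(topology) {
  heavy <- classify_atoms(topology)$heavy
  if (length(heavy) == 0L) stop("solute has no heavy atoms")
  b <- topology$bonds
  hb <- b[b[, 1L] %in% heavy & b[, 2L] %in% heavy, , drop = FALSE]
  if (!graph_connected(heavy, hb)) stop("heavy-atom graph is disconnected")
  deg0 <- sapply(heavy, function(a) sum(hb == a))
  names(deg0) <- heavy
  remaining <- heavy
  order_out <- integer(0)
  while (length(remaining) > 1L) {
    cand <- remaining[vapply(remaining, function(a) {
      graph_connected(setdiff(remaining, a), hb)
    }, logical(1))]
    degc <- vapply(cand, function(a)
      sum(hb[, 1L] %in% remaining & hb[, 2L] %in% remaining &
            (hb[, 1L] == a | hb[, 2L] == a)), 0)
    cand <- cand[order(degc, deg0[as.character(cand)], cand)]
    pick <- cand[1L]
    order_out <- c(order_out, pick)
    remaining <- setdiff(remaining, pick)
  }
  c(order_out, remaining)
}

#' Build the SAI annihilation schedule for a solute
#'
#' Emits the ordered list of intermediate states: the charge block (one
#' state per charge factor, the first being the physical state), the joint
#' hydrogen LJ block, one state per heavy atom in removal order except the
#' last, the two-step last-heavy block, and (by default) a terminal
#' all-zero bookkeeping state.  With the defaults the state count is
#' `4 + 2 + (n_heavy - 1) + 2 + 1` (15 for a toluene-like solute with
#' seven heavy atoms).  Coupling is monotone non-increasing per atom: an
#' interaction, once removed, never reappears.
#'
#' @param topology a [solute_topology()].
#' @param config a [schedule_config()].
#' @return An object of class `sai_schedule`: list of states, each with
#'   1-based `index`, per-atom `charge_scale` and `lj_scale` vectors, a
#'   `block` label and a human-readable `label`.
#' @export
build_schedule <- function(topology, config = schedule_config()) {
  cl <- classify_atoms(topology)
  n <- nrow(topology$atoms)
  if (length(cl$heavy) == 0L)
    stop("solute without heavy atoms is unsupported")
  if (abs(net_charge(topology)) > 1e-6)
    warning("solute has net charge ", signif(net_charge(topology), 4),
            " e; uniform charge scaling changes the net charge")
  heavy_order <- heavy_atom_removal_order(topology)
  states <- list()
  qs <- rep(1, n); ls <- rep(1, n)
  add <- function(block, label) {
    states[[length(states) + 1L]] <<- list(
      index = length(states) + 1L, charge_scale = qs, lj_scale = ls,
      block = block, label = label)
  }
  for (f in config$charge_factors) {
    qs <- rep(f, n)
    add("charge", sprintf("charges x %.2f", f))
  }
  if (length(cl$hydrogen) > 0L) {
    for (f in config$hydrogen_lj_factors) {
      ls[cl$hydrogen] <- f
      add("hydrogen_lj", sprintf("hydrogen LJ x %.2f", f))
    }
  }
  nh <- length(heavy_order)
  if (nh > 1L) {
    for (a in heavy_order[-nh]) {
      ls[a] <- 0
      add("heavy_lj", sprintf("heavy atom %d off", a))
    }
  }
  last <- heavy_order[nh]
  for (f in config$last_heavy_factors) {
    ls[last] <- f
    add("heavy_lj", sprintf("last heavy atom %d LJ x %.2f", last, f))
  }
  if (config$emit_terminal_state) {
    qs <- rep(0, n); ls <- rep(0, n)
    add("terminal", "terminal (fully decoupled)")
  }
  structure(list(states = states, heavy_order = heavy_order,
                 config = config, n_atoms = n,
                 solute_name = topology$name),
            class = "sai_schedule")
}

#' @export
length.sai_schedule <- function(x) length(x$states)

#' @export
as.data.frame.sai_schedule <- function(x, ...) {
  do.call(rbind, lapply(x$states, function(s) data.frame(
    state = s$index, block = s$block, label = s$label,
    charge_scale = mean(s$charge_scale), min_lj_scale = min(s$lj_scale),
    stringsAsFactors = FALSE)))
}

#' @export
print.sai_schedule <- function(x, ...) {
  cat(sprintf("SAI annihilation schedule for '%s': %d states (heavy order: %s)\n",
              x$solute_name, length(x$states),
              paste(x$heavy_order, collapse = " ")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Apply an intermediate state's scaling to a system
#'
#' Scales per-atom charges by `charge_scale` and both LJ parameters
#' (`r_min`, `epsilon`) by `lj_scale`; the solvent is untouched.  The
#' solute net charge after scaling equals `net_charge * charge_scale`, so
#' neutral solutes stay exactly neutral in every state.
#'
#' @param system a [solvated_system()].
#' @param state one element of `build_schedule(...)$states`.
#' @return The parameterized system snapshot.
#' @export
apply_state <- function(system, state) {
  top <- system$solute
  stopifnot(length(state$charge_scale) == nrow(top$atoms))
  top$atoms$charge <- top$atoms$charge * state$charge_scale
  top$atoms$r_min <- top$atoms$r_min * state$lj_scale
  top$atoms$epsilon <- top$atoms$epsilon * state$lj_scale
  system$solute <- top
  system
}

#' Write one self-contained input directory per intermediate state
#'
#' Creates subdirectories `intst1 ... intstK`, each holding the scaled
#' system file (`system.yaml`) and a metadata file (`state.yaml`) with the
#' per-atom factors, so any state can be sampled in isolation (the layout
#' enables embarrassing parallelism).  Re-running is byte-idempotent.
#'
#' @param schedule a [build_schedule()] result.
#' @param system the physical-state [solvated_system()].
#' @param directory output directory.
#' @return Character vector of state directory paths, invisibly.
#' @export
write_state_inputs <- function(schedule, system, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in schedule$states) {
    d <- file.path(directory, paste0("intst", s$index))
    dir.create(d, showWarnings = FALSE)
    write_system(apply_state(system, s), file.path(d, "system.yaml"))
    meta <- c("format: saisolv-state",
              paste0("index: ", s$index),
              paste0("block: ", s$block),
              paste0("label: ", s$label),
              paste0("charge_scale: [",
                     paste(fmt_num(s$charge_scale), collapse = ", "), "]"),
              paste0("lj_scale: [",
                     paste(fmt_num(s$lj_scale), collapse = ", "), "]"))
    writeLines(meta, file.path(d, "state.yaml"))
    paths <- c(paths, d)
  }
  invisible(paths)
}

#' Read back the state metadata written by [write_state_inputs()]
#' @param state_dir one `intstN` directory.
#' @export
read_state_spec <- function(state_dir) {
  doc <- yaml::read_yaml(file.path(state_dir, "state.yaml"))
  list(index = as.integer(doc$index), block = doc$block, label = doc$label,
       charge_scale = as.numeric(doc$charge_scale),
       lj_scale = as.numeric(doc$lj_scale))
}
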