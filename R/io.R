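# Text I/O: the documented system format (YAML with declared units) and a
# multi-frame XYZ-style trajectory format.  Numbers are written with 17
# significant digits so that write -> load -> write round trips are
# byte-identical.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a toy system to the documented text format
#'
#' The format is YAML with an explicit unit header (Angstrom, kcal/mol, e),
#' the Lorentz-Berthelot combining rule declared, 1-based atom indices and
#' full-precision numbers, so that files are diffable and round-trip
#' bit-exactly.
#'
#' @param system a [solvated_system()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path) {
  top <- system$solute
  ln <- c("format: saisolv-system",
          "version: 1",
          "units: {length: angstrom, energy: kcal/mol, charge: e}",
          "combining_rule: lorentz-berthelot",
          "atom_indexing: 1-based",
          paste0("name: ", top$name),
          paste0("box_edge: ", fmt_num(system$box_edge)),
          paste0("periodic: ", if (system$periodic) "true" else "false"),
          "solute:",
          "  atoms:")
  for (i in seq_len(nrow(top$atoms))) {
    a <- top$atoms[i, ]
    xyz <- if (nrow(system$solute_xyz)) system$solute_xyz[i, ] else c(0, 0, 0)
    ln <- c(ln, sprintf(
      "    - {element: %s, charge: %s, r_min: %s, epsilon: %s, xyz: [%s, %s, %s]}",
      a$element, fmt_num(a$charge), fmt_num(a$r_min), fmt_num(a$epsilon),
      fmt_num(xyz[1]), fmt_num(xyz[2]), fmt_num(xyz[3])))
  }
  ln <- c(ln, "  bonds:")
  for (b in seq_len(nrow(top$bonds)))
    ln <- c(ln, sprintf("    - [%d, %d]", top$bonds[b, 1L], top$bonds[b, 2L]))
  w <- system$water
  ln <- c(ln, "water:",
          sprintf("  model: {q_o: %s, q_h: %s, r_min_o: %s, epsilon_o: %s, r_oh: %s, theta_deg: %s}",
                  fmt_num(w$q_o), fmt_num(w$q_h), fmt_num(w$r_min_o),
                  fmt_num(w$epsilon_o), fmt_num(w$r_oh), fmt_num(w$theta_deg)),
          "  sites:")
  for (i in seq_len(nrow(system$water_xyz)))
    ln <- c(ln, sprintf("    - [%s, %s, %s]",
                        fmt_num(system$water_xyz[i, 1]),
                        fmt_num(system$water_xyz[i, 2]),
                        fmt_num(system$water_xyz[i, 3])))
  writeLines(ln, path)
  invisible(path)
}

#' Load a toy system from the documented text format
#'
#' Parses and validates a file written by [write_system()].  Malformed
#' YAML raises a parse error naming the offending line; invariant
#' violations (bond indices out of range, epsilon < 0, a periodic box
#' smaller than twice the cutoff intended for it) raise validation errors.
#'
#' @param path input file path.
#' @return a [solvated_system()].
#' @export
load_system <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "saisolv-system"))
    stop("not a saisolv-system file: ", path)
  at <- doc$solute$atoms
  atoms <- data.frame(
    element = vapply(at, function(a) as.character(a$element), ""),
    charge = vapply(at, function(a) as.numeric(a$charge), 0),
    r_min = vapply(at, function(a) as.numeric(a$r_min), 0),
    epsilon = vapply(at, function(a) as.numeric(a$epsilon), 0),
    stringsAsFactors = FALSE)
  xyz <- t(vapply(at, function(a) as.numeric(a$xyz), numeric(3)))
  bonds <- doc$solute$bonds
  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  top <- solute_topology(atoms, bonds, name = doc$name %||% "solute", xyz = xyz)
  m <- doc$water$model
  model <- toy_water(q_o = m$q_o, q_h = m$q_h, r_min_o = m$r_min_o,
                     epsilon_o = m$epsilon_o, r_oh = m$r_oh,
                     theta_deg = m$theta_deg)
  sites <- doc$water$sites
  wxyz <- if (length(sites)) do.call(rbind, sites) else NULL
  solvated_system(top, solute_xyz = xyz, water = model, water_xyz = wxyz,
                  box_edge = as.numeric(doc$box_edge),
                  periodic = isTRUE(doc$periodic))
}

#' Write a trajectory as multi-frame XYZ-style text
#'
#' One block per frame: a site-count line, a comment line carrying the box
#' edge, then one `x y z` line per site.
#'
#' @param traj a `sai_trajectory` (see [mc_sample()]).
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  nf <- traj$n_frames
  nsite <- dim(traj$frames)[2L]
  for (f in seq_len(nf)) {
    writeLines(as.character(nsite), con)
    writeLines(sprintf("frame %d box %s state %d", f,
                       fmt_num(traj$boxes[f]), traj$state_index), con)
    writeLines(sprintf("%s %s %s", fmt_num(traj$frames[f, , 1]),
                       fmt_num(traj$frames[f, , 2]),
                       fmt_num(traj$frames[f, , 3])), con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#' @param path input file path.
#' @export
read_trajectory <- function(path) {
  ln <- readLines(path)
  frames <- list(); boxes <- numeric(0); state <- 1L
  i <- 1L
  while (i <= length(ln)) {
    nsite <- as.integer(ln[i])
    hdr <- strsplit(ln[i + 1L], " ")[[1L]]
    boxes <- c(boxes, as.numeric(hdr[4L]))
    state <- as.integer(hdr[6L])
    block <- ln[(i + 2L):(i + 1L + nsite)]
    xyz <- matrix(scan(text = block, quiet = TRUE), ncol = 3, byrow = TRUE)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nsite
  }
  nf <- length(frames)
  arr <- array(0, c(nf, nrow(frames[[1L]]), 3))
  for (f in seq_len(nf)) arr[f, , ] <- frames[[f]]
  new_trajectory(arr, boxes = boxes, volumes = boxes^3, state_index = state,
                 seed = NA_integer_)
}

#' Construct a trajectory object
#'
#' @param frames array of dimension (n_frames, n_sites, 3), Angstrom.
#' @param boxes per-frame box edges; `volumes` per-frame volumes.
#' @param volumes per-frame box volumes, Angstrom^3.
#' @param state_index schedule state that generated the frames.
#' @param seed RNG seed used.
#' @param acceptance optional named acceptance rates.
#' @param npt whether frames come from constant-pressure sampling.
#' @export
new_trajectory <- function(frames, boxes, volumes, state_index, seed,
                           acceptance = NULL, npt = FALSE) {
  structure(list(frames = frames, boxes = boxes, volumes = volumes,
                 state_index = state_index, seed = seed,
                 n_frames = dim(frames)[1L], acceptance = acceptance,
                 npt = npt),
            class = "sai_trajectory")
}

#' @export
print.sai_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d sites (state %s, seed %s%s)\n",
              x$n_frames, dim(x$frames)[2L], x$state_index, x$seed,
              if (isTRUE(x$npt)) ", NPT" else ""))
  invisible(x)
}
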