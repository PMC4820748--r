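#' Read a (multi-model) GRO trajectory
#'
#' Parses a concatenation of one or more GRO models: title line (frame time
#' read from a `t=` token, in ps), atom count, fixed-column atom records and
#' a box line. The topology (residue index/name, bead name, bead id) is
#' taken from the first model; each frame carries its own box. Coordinates
#' are nm (native GRO); times are converted ps -> ns on read. Models
#' lacking a `t=` token are assigned times by frame order times
#' `default_spacing_ns`.
#'
#' Only orthorhombic boxes are supported: a box line with nonzero
#' off-diagonal components is rejected, not silently truncated.
#'
#' @param path path to the GRO file.
#' @param default_spacing_ns frame spacing in ns used when the titles carry
#'   no `t=` token. Default 2.
#' @return a `cg_trajectory` (all beads in group `"protein"`; use
#'   [assign_groups()] to partition).
#' @export
read_gro_trajectory <- function(path, default_spacing_ns = 2) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  frames <- list()
  topo <- NULL
  i <- 1L
  model <- 0L
  n_total <- length(lines)
  while (i <= n_total) {
    if (!nzchar(trimws(lines[i])) && i == n_total) break
    model <- model + 1L
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L)
      stop(sprintf("GRO model %d: malformed atom count line '%s'",
                   model, lines[i + 1L]))
    if (i + 1L + natoms + 1L > n_total)
      stop(sprintf("GRO model %d: file truncated (expected %d atom records)",
                   model, natoms))
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]

    box_vals <- suppressWarnings(as.numeric(strsplit(trimws(box_line),
                                                     "\\s+")[[1]]))
    if (any(is.na(box_vals)) || length(box_vals) < 3L)
      stop(sprintf("GRO model %d: malformed box line '%s'", model, box_line))
    if (length(box_vals) > 3L && any(abs(box_vals[-(1:3)]) > 1e-9))
      stop(sprintf("GRO model %d: triclinic box not supported", model))
    box <- box_vals[1:3]
    if (any(box <= 0))
      stop(sprintf("GRO model %d: non-positive box edge", model))

    if (model == 1L) {
      resid <- as.integer(substr(atom_lines, 1L, 5L))
      resname <- trimws(substr(atom_lines, 6L, 10L))
      beadname <- trimws(substr(atom_lines, 11L, 15L))
      if (any(is.na(resid)))
        stop("GRO model 1: malformed residue index field")
      topo <- bead_topology(beadname, resid, resname)
    } else if (natoms != nrow(topo)) {
      stop(sprintf("GRO model %d has %d beads; model 1 has %d",
                   model, natoms, nrow(topo)))
    }

    x <- as.numeric(substr(atom_lines, 21L, 28L))
    y <- as.numeric(substr(atom_lines, 29L, 36L))
    z <- as.numeric(substr(atom_lines, 37L, 44L))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop(sprintf("GRO model %d: malformed coordinate field", model))

    tm <- regmatches(title, regexpr("t= *[-+0-9.eE]+", title))
    time_ns <- if (length(tm) == 1L) {
      as.numeric(sub("t= *", "", tm)) / 1000  # ps -> ns
    } else {
      NA_real_
    }
    frames[[model]] <- list(time = time_ns, box = box,
                            coords = cbind(x, y, z))
    i <- i + 3L + natoms
  }
  if (model == 0L) stop("no GRO models found in ", path)

  times <- vapply(frames, `[[`, numeric(1), "time")
  if (anyNA(times))
    times <- (seq_along(frames) - 1L) * default_spacing_ns
  frames <- lapply(seq_along(frames), function(j)
    cg_frame(times[j], frames[[j]]$box, frames[[j]]$coords))
  cg_trajectory(topo, frames, provenance = list(source = path,
                                                format = "gro"))
}

#' Write a trajectory as a (multi-model) GRO file
#'
#' Times are written as `t=` tokens in ps; coordinates at GRO precision
#' (three decimals, nm).
#'
#' @param trajectory a `cg_trajectory`.
#' @param path output file path.
#' @param title title stem for each model.
#' @export
write_gro <- function(trajectory, path, title = "membanchor") {
  topo <- trajectory$topology
  n <- nrow(topo)
  con <- file(path, "w")
  on.exit(close(con))
  atom_stub <- sprintf("%5d%-5s%5s%5d",
                       topo$residue_index %% 100000L,
                       substr(topo$residue_name, 1L, 5L),
                       substr(topo$bead_name, 1L, 5L),
                       (topo$bead_id + 1L) %% 100000L)
  for (fr in trajectory$frames) {
    writeLines(sprintf("%s t= %.4f", title, fr$time * 1000), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(paste0(atom_stub,
                      sprintf("%8.3f%8.3f%8.3f", fr$coords[, 1],
                              fr$coords[, 2], fr$coords[, 3])), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2],
                       fr$box[3]), con)
  }
  invisible(path)
}
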