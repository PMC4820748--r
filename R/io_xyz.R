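#' Read the whitespace XYZ-with-time trajectory dialect
#'
#' Each frame is a header line `time_ns n_beads box_x box_y box_z` followed
#' by `n_beads` rows `bead_name residue_index residue_name x y z`
#' (coordinates in nm). A plain-text companion to the GRO reader.
#'
#' @param path input file path.
#' @return a `cg_trajectory`.
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  topo <- NULL
  i <- 1L
  model <- 0L
  while (i <= length(lines)) {
    model <- model + 1L
    hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                "\\s+")[[1]]))
    if (length(hdr) != 5L || anyNA(hdr))
      stop(sprintf("XYZ frame %d: malformed header '%s'", model, lines[i]))
    nb <- as.integer(hdr[2])
    if (i + nb > length(lines))
      stop(sprintf("XYZ frame %d: file truncated", model))
    rows <- strsplit(trimws(lines[(i + 1L):(i + nb)]), "\\s+")
    if (any(lengths(rows) != 6L))
      stop(sprintf("XYZ frame %d: malformed bead row", model))
    m <- do.call(rbind, rows)
    if (model == 1L) {
      topo <- bead_topology(m[, 1], as.integer(m[, 2]), m[, 3])
    } else if (nb != nrow(topo)) {
      stop(sprintf("XYZ frame %d has %d beads; frame 1 has %d",
                   model, nb, nrow(topo)))
    }
    coords <- matrix(as.numeric(m[, 4:6]), ncol = 3L)
    frames[[model]] <- cg_frame(hdr[1], hdr[3:5], coords)
    i <- i + 1L + nb
  }
  if (model == 0L) stop("no frames found in ", path)
  cg_trajectory(topo, frames, provenance = list(source = path,
                                                format = "xyz"))
}

#' Write a trajectory in the whitespace XYZ-with-time dialect
#'
#' @param trajectory a `cg_trajectory`.
#' @param path output file path.
#' @export
write_xyz_trajectory <- function(trajectory, path) {
  topo <- trajectory$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in trajectory$frames) {
    writeLines(sprintf("%.6f %d %.6f %.6f %.6f", fr$time, nrow(topo),
                       fr$box[1], fr$box[2], fr$box[3]), con)
    writeLines(sprintf("%s %d %s %.6f %.6f %.6f", topo$bead_name,
                       topo$residue_index, topo$residue_name,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}
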