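#' Construct a single trajectory frame
#'
#' @param time frame time in ns.
#' @param box orthorhombic box edges in nm (length-3, all > 0).
#' @param coords numeric n x 3 matrix of bead coordinates in nm. Coordinates
#'   may lie outside the box; wrapping is the distance kernel's job.
#' @return list of class `"cg_frame"`.
#' @export
cg_frame <- function(time, box, coords) {
  coords <- as.matrix(coords)
  stopifnot(is.numeric(time), length(time) == 1L,
            length(box) == 3L, all(box > 0), ncol(coords) == 3L)
  structure(list(time = as.numeric(time), box = as.numeric(box),
                 coords = unname(coords)), class = "cg_frame")
}

#' Construct a coarse-grained trajectory
#'
#' @param topology a `bead_topology`.
#' @param frames list of `cg_frame` objects with strictly increasing times
#'   and bead counts matching the topology.
#' @param provenance free-form metadata list.
#' @return object of class `"cg_trajectory"`.
#' @export
cg_trajectory <- function(topology, frames, provenance = list()) {
  nb <- nrow(topology)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != nb)
      stop(sprintf("frame %d has %d beads; topology has %d",
                   i, nrow(frames[[i]]$coords), nb))
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames,
                 provenance = provenance), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  times <- frame_times(x)
  cat(sprintf("cg_trajectory: %d beads, %d frames", nrow(x$topology),
              length(x$frames)))
  if (length(times))
    cat(sprintf(", t = %g..%g ns", times[1], times[length(times)]))
  cat("\n")
  cat("  groups:",
      paste(names(table(x$topology$group)), table(x$topology$group),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Frame times of a trajectory
#' @param trajectory a `cg_trajectory`.
#' @return numeric vector of frame times in ns.
#' @export
frame_times <- function(trajectory) {
  vapply(trajectory$frames, `[[`, numeric(1), "time")
}

#' Number of frames in a trajectory
#' @param trajectory a `cg_trajectory`.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Subsample a trajectory to a fixed analysis interval
#'
#' Picks, for each target time `interval, 2*interval, ...` up to the final
#' frame time, the source frame nearest in time (ties toward the earlier
#' frame; each source frame used at most once). The grid starts at
#' `t = interval`, excluding the initial frame, so a 1000 ns trajectory
#' sampled at 2 ns yields exactly 500 analysis snapshots.
#'
#' @param trajectory a `cg_trajectory`.
#' @param interval analysis interval in ns; must be at least the native
#'   frame spacing (no upsampling).
#' @return a `cg_trajectory` containing the selected frames.
#' @export
subsample_frames <- function(trajectory, interval) {
  stopifnot(interval > 0)
  times <- frame_times(trajectory)
  n <- length(times)
  if (n == 0L) stop("trajectory has no frames")
  if (n > 1L) {
    native <- min(diff(times))
    if (interval < native - 1e-9)
      stop(sprintf(paste0("interval (%g ns) is below the native frame ",
                          "spacing (%g ns); cannot upsample"),
                   interval, native))
  }
  k <- floor(times[n] / interval + 1e-9)
  if (k < 1L)
    stop("trajectory is shorter than one analysis interval")
  sel <- integer(k)
  last <- 0L
  for (j in seq_len(k)) {
    target <- j * interval
    if (last >= n) stop("ran out of frames while subsampling")
    cand <- (last + 1L):n
    # which.min returns the first minimum: ties go to the earlier frame
    idx <- cand[which.min(abs(times[cand] - target))]
    sel[j] <- idx
    last <- idx
  }
  prov <- trajectory$provenance
  prov$subsampled_interval_ns <- interval
  cg_trajectory(trajectory$topology, trajectory$frames[sel], prov)
}
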