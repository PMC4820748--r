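#' Snapshot-level protein-membrane contact series
#'
#' A snapshot is a contact when the minimum distance between any protein
#' bead and any lipid bead (minimum image, orthorhombic box) is strictly
#' below `params$contact_threshold`. The trajectory is expected to be
#' subsampled to the analysis interval and to have groups assigned.
#'
#' @param trajectory a `cg_trajectory` with non-empty protein and lipid
#'   groups.
#' @param params an [analysis_params()] object.
#' @param lipid_bead_names optional bead-name restriction for the membrane
#'   side (default: all lipid beads).
#' @return logical vector, one element per snapshot.
#' @export
contact_series <- function(trajectory, params = analysis_params(),
                           lipid_bead_names = NULL) {
  topo <- trajectory$topology
  prot <- select_beads(topo, group = "protein")
  lip <- select_beads(topo, group = "lipid", bead_names = lipid_bead_names)
  if (length(prot) == 0L) stop("selection 'protein' is empty")
  if (length(lip) == 0L) stop("selection 'lipid' is empty")
  vapply(trajectory$frames, function(fr) {
    any_within_cpp(fr$coords[prot, , drop = FALSE],
                   fr$coords[lip, , drop = FALSE],
                   fr$box, params$contact_threshold)
  }, logical(1))
}

#' Anchor-residue membrane-contact series
#'
#' Contact mask of the lipid-anchor residue (all its beads, across chains
#' sharing the residue index) against all lipid beads.
#'
#' @inheritParams contact_series
#' @return logical vector per snapshot.
#' @export
anchor_contact_series <- function(trajectory, params = analysis_params()) {
  topo <- trajectory$topology
  anchor <- select_beads(topo, group = "protein",
                         residue_index = params$anchor_residue_index)
  if (length(anchor) == 0L)
    stop(sprintf("anchor residue %d not found in the protein topology",
                 params$anchor_residue_index))
  lip <- select_beads(topo, group = "lipid")
  if (length(lip) == 0L) stop("selection 'lipid' is empty")
  vapply(trajectory$frames, function(fr) {
    any_within_cpp(fr$coords[anchor, , drop = FALSE],
                   fr$coords[lip, , drop = FALSE],
                   fr$box, params$contact_threshold)
  }, logical(1))
}

# first index of the first run of >= run_length consecutive TRUE values;
# NA if none. report = "run_start" or "run_end".
first_run_index <- function(mask, run_length, report = "run_start") {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0L) return(NA_integer_)
  start <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  if (report == "run_end") start + as.integer(run_length) - 1L else start
}

#' Detect the lipid-anchor insertion event
#'
#' The insertion event is the first time the anchor residue is in membrane
#' contact for `params$insertion_run_length` successive snapshots. The
#' returned index is the first snapshot of that qualifying run (or its last
#' snapshot when `params$insertion_report = "run_end"`); `NA` when no run
#' qualifies.
#'
#' @inheritParams contact_series
#' @param anchor_mask optional precomputed anchor contact mask (logical per
#'   snapshot); computed from the trajectory when missing.
#' @return integer snapshot index (1-based) or `NA`.
#' @export
detect_insertion <- function(trajectory, params = analysis_params(),
                             anchor_mask = NULL) {
  if (is.null(anchor_mask))
    anchor_mask <- anchor_contact_series(trajectory, params)
  first_run_index(anchor_mask, params$insertion_run_length,
                  params$insertion_report)
}

#' Classify a trajectory from its contact mask and insertion result
#'
#' @param contact_mask logical contact series.
#' @param insertion_frame integer snapshot index or `NA`.
#' @return one of `"inserted"`, `"contact_only"`, `"no_contact"`.
#' @export
classify_trajectory <- function(contact_mask, insertion_frame) {
  if (!is.na(insertion_frame)) "inserted"
  else if (any(contact_mask)) "contact_only"
  else "no_contact"
}

#' Full per-trajectory event analysis
#'
#' Computes the contact series, anchor-insertion detection and trajectory
#' classification for one (already subsampled, groups-assigned) trajectory.
#'
#' @inheritParams contact_series
#' @param id trajectory identifier stored in the record.
#' @param insertable whether the protein carries an insertable lipid
#'   anchor. The insertion event is defined only for the anchor-modified
#'   protein; with `insertable = FALSE` (e.g. the unmodified or
#'   disulfide-dimerized variants) no insertion is reported, though the
#'   anchor-residue contact mask is still recorded.
#' @return an `event_record`: list with `trajectory_id`, `times` (ns),
#'   `contact_mask`, `anchor_mask`, `first_contact_frame`,
#'   `insertion_frame` (1-based snapshot indices or `NA`) and
#'   `classification`.
#' @export
analyze_trajectory <- function(trajectory, params = analysis_params(),
                               id = "traj", insertable = TRUE) {
  mask <- contact_series(trajectory, params)
  amask <- anchor_contact_series(trajectory, params)
  ins <- if (insertable)
    first_run_index(amask, params$insertion_run_length,
                    params$insertion_report)
  else NA_integer_
  fc <- if (any(mask)) which(mask)[1] else NA_integer_
  structure(list(
    trajectory_id = id,
    times = frame_times(trajectory),
    contact_mask = mask,
    anchor_mask = amask,
    first_contact_frame = fc,
    insertion_frame = ins,
    classification = classify_trajectory(mask, ins)
  ), class = "event_record")
}

#' Ensemble association curves
#'
#' From a list of per-trajectory event records sharing the same snapshot
#' grid, computes at every snapshot time t:
#' * `cumulative_contact`: fraction of trajectories with at least one
#'   contact at any snapshot `<= t`;
#' * `subtotal_contact`: fraction with at least one contact inside the
#'   trailing half-open window `(t - subtotal_window, t]` (5 snapshots at
#'   the 10 ns / 2 ns defaults);
#' * `cumulative_inserted`: fraction of trajectories whose insertion event
#'   is at a snapshot `<= t`, normalized over the whole ensemble or over
#'   the inserted subset.
#'
#' @param records list of `event_record`s with identical snapshot times.
#' @param params an [analysis_params()] object.
#' @param inserted_denominator `"ensemble"` (default) or `"inserted"`.
#' @return object of class `"ensemble_curves"`: data.frame with columns
#'   `time`, `cumulative_contact`, `subtotal_contact`,
#'   `cumulative_inserted`, plus attributes `n_trajectories` and
#'   `n_inserted`.
#' @export
ensemble_curves <- function(records, params = analysis_params(),
                            inserted_denominator = c("ensemble", "inserted")) {
  inserted_denominator <- match.arg(inserted_denominator)
  stopifnot(length(records) >= 1L)
  times <- records[[1]]$times
  nsnap <- length(times)
  for (r in records)
    if (length(r$contact_mask) != nsnap)
      stop("records have mismatched snapshot counts")
  n <- length(records)

  fc <- vapply(records, `[[`, integer(1), "first_contact_frame")
  ins <- vapply(records, `[[`, integer(1), "insertion_frame")
  idx <- seq_len(nsnap)

  cum_contact <- vapply(idx, function(i) sum(!is.na(fc) & fc <= i) / n,
                        numeric(1))

  # half-open trailing window (t - W, t]
  sub <- numeric(nsnap)
  for (i in idx) {
    jmin <- which(times > times[i] - params$subtotal_window)[1]
    win <- jmin:i
    sub[i] <- mean(vapply(records, function(r) any(r$contact_mask[win]),
                          logical(1)))
  }

  n_ins <- sum(!is.na(ins))
  denom <- if (inserted_denominator == "inserted") {
    if (n_ins == 0L)
      stop("inserted_denominator = 'inserted' but no trajectory inserted")
    n_ins
  } else n
  cum_ins <- vapply(idx, function(i) sum(!is.na(ins) & ins <= i) / denom,
                    numeric(1))

  out <- data.frame(time = times,
                    cumulative_contact = cum_contact,
                    subtotal_contact = sub,
                    cumulative_inserted = cum_ins)
  attr(out, "n_trajectories") <- n
  attr(out, "n_inserted") <- n_ins
  attr(out, "inserted_denominator") <- inserted_denominator
  class(out) <- c("ensemble_curves", "data.frame")
  out
}

#' Write ensemble curves as CSV
#' @param curves an `ensemble_curves` object.
#' @param path output file path.
#' @export
write_curves_csv <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}

#' Write per-trajectory event records as CSV (one row per snapshot)
#' @param records list of `event_record`s.
#' @param path output file path.
#' @export
write_records_csv <- function(records, path) {
  dfs <- lapply(records, function(r) data.frame(
    trajectory_id = r$trajectory_id,
    snapshot = seq_along(r$times),
    time = r$times,
    contact = r$contact_mask,
    anchor_contact = r$anchor_mask,
    classification = r$classification
  ))
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}
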