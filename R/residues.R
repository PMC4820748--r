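#' Per-trajectory residue head-group contact counts
#'
#' For one (subsampled, groups-assigned) trajectory and its event record,
#' counts, inside the phase window, the snapshots in which each protein
#' residue has at least one bead within `params$residue_contact_threshold`
#' of a lipid head-group bead (minimum image). Building block for
#' [residue_contact_probability()]; exposed so ensembles can be pooled
#' without holding all trajectories in memory.
#'
#' Phase windows (1-based snapshot indices):
#' * `after_insertion`: `insertion_frame .. end` (inserted trajectories
#'   only; others contribute nothing);
#' * `before_insertion`: `first_contact_frame .. insertion_frame - 1` of
#'   inserted trajectories;
#' * `after_first_contact`: `first_contact_frame .. end` of any
#'   contacting trajectory.
#'
#' @param trajectory a `cg_trajectory`.
#' @param record its `event_record` from [analyze_trajectory()].
#' @param params an [analysis_params()] object.
#' @param phase `"after_insertion"`, `"before_insertion"` or
#'   `"after_first_contact"`.
#' @return list with `counts` (named integer vector over protein residue
#'   indices) and `denominator` (number of in-window snapshots; 0 when the
#'   trajectory contributes nothing to this phase).
#' @export
residue_contact_counts <- function(trajectory, record,
                                   params = analysis_params(),
                                   phase = c("after_insertion",
                                             "before_insertion",
                                             "after_first_contact")) {
  phase <- match.arg(phase)
  topo <- trajectory$topology
  prot <- select_beads(topo, group = "protein")
  if (length(prot) == 0L) stop("selection 'protein' is empty")
  heads <- select_beads(topo, group = "lipid",
                        bead_names = params$head_group_bead_names)
  if (length(heads) == 0L)
    stop("no lipid head-group beads (",
         paste(params$head_group_bead_names, collapse = ","), ") found")

  res_levels <- sort(unique(topo$residue_index[prot]))
  n_res <- length(res_levels)
  res_id <- match(topo$residue_index[prot], res_levels)
  counts <- integer(n_res)
  names(counts) <- res_levels

  nsnap <- length(record$contact_mask)
  ins <- record$insertion_frame
  fc <- record$first_contact_frame
  window <- switch(phase,
    after_insertion = if (is.na(ins)) integer(0) else ins:nsnap,
    before_insertion = if (is.na(ins) || is.na(fc) || fc >= ins) integer(0)
                       else fc:(ins - 1L),
    after_first_contact = if (is.na(fc)) integer(0) else fc:nsnap
  )
  if (length(window) == 0L)
    return(list(counts = counts, denominator = 0L))

  for (i in window) {
    fr <- trajectory$frames[[i]]
    hit <- residue_any_within_cpp(fr$coords[prot, , drop = FALSE],
                                  res_id, n_res,
                                  fr$coords[heads, , drop = FALSE],
                                  fr$box, params$residue_contact_threshold)
    counts <- counts + hit
  }
  list(counts = counts, denominator = length(window))
}

#' Aggregate pooled counts into a residue contact profile
#'
#' @param count_list list of results from [residue_contact_counts()]
#'   (same residue universe).
#' @param phase phase label to store.
#' @param ensemble_size number of trajectories that contributed snapshots.
#' @return a `residue_contact_profile`: data.frame with columns
#'   `residue_index`, `probability`, plus attributes `denominator`,
#'   `phase`, `ensemble_size`.
#' @export
pool_residue_counts <- function(count_list, phase, ensemble_size = NULL) {
  count_list <- Filter(function(x) x$denominator > 0L, count_list)
  if (length(count_list) == 0L)
    stop(sprintf("no trajectory contributes snapshots to phase '%s'", phase))
  counts <- Reduce(`+`, lapply(count_list, `[[`, "counts"))
  denom <- sum(vapply(count_list, `[[`, integer(1), "denominator"))
  out <- data.frame(
    residue_index = as.integer(names(counts)),
    probability = as.numeric(counts) / denom
  )
  attr(out, "denominator") <- denom
  attr(out, "phase") <- phase
  attr(out, "ensemble_size") <- if (is.null(ensemble_size))
    length(count_list) else ensemble_size
  class(out) <- c("residue_contact_profile", "data.frame")
  out
}

#' Per-residue lipid head-group contact probability
#'
#' For each protein residue, the ratio of in-window snapshots (pooled
#' across trajectories) in which the residue has at least one bead within
#' the contact threshold of a lipid head-group bead (C1A, C1B, NH3, PO4 by
#' default). The window is selected per trajectory by `phase`: after the
#' insertion event, between first contact and insertion, or after the
#' first contact (see [residue_contact_counts()]).
#'
#' @param trajectories list of (subsampled, groups-assigned)
#'   `cg_trajectory` objects.
#' @param records matching list of `event_record`s.
#' @param params an [analysis_params()] object.
#' @param phase phase window selector.
#' @param per_trajectory if TRUE, average per-trajectory probabilities
#'   instead of pooling snapshots (snapshot-weighted pooling is the
#'   default).
#' @return a `residue_contact_profile` data.frame.
#' @export
residue_contact_probability <- function(trajectories, records,
                                        params = analysis_params(),
                                        phase = c("after_insertion",
                                                  "before_insertion",
                                                  "after_first_contact"),
                                        per_trajectory = FALSE) {
  phase <- match.arg(phase)
  stopifnot(length(trajectories) == length(records))
  cl <- Map(function(tr, re) residue_contact_counts(tr, re, params, phase),
            trajectories, records)
  if (!per_trajectory)
    return(pool_residue_counts(cl, phase))
  cl <- Filter(function(x) x$denominator > 0L, cl)
  if (length(cl) == 0L)
    stop(sprintf("no trajectory contributes snapshots to phase '%s'", phase))
  probs <- vapply(cl, function(x) x$counts / x$denominator,
                  numeric(length(cl[[1]]$counts)))
  out <- data.frame(
    residue_index = as.integer(names(cl[[1]]$counts)),
    probability = rowMeans(probs)
  )
  attr(out, "denominator") <- sum(vapply(cl, `[[`, integer(1), "denominator"))
  attr(out, "phase") <- phase
  attr(out, "ensemble_size") <- length(cl)
  class(out) <- c("residue_contact_profile", "data.frame")
  out
}

#' Residues with high lipid contact probability
#'
#' @param profile a `residue_contact_profile`.
#' @param cutoff probability cut-off (inclusive). There is no canonical
#'   default; choose per analysis.
#' @return data.frame of residues with `probability >= cutoff`, sorted by
#'   descending probability.
#' @export
high_contact_residues <- function(profile, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  keep <- profile$probability >= cutoff
  out <- profile[keep, , drop = FALSE]
  out[order(-out$probability, out$residue_index), , drop = FALSE]
}

#' Write a residue contact profile as CSV
#' @param profile a `residue_contact_profile`.
#' @param path output file path.
#' @param residue_names optional named character vector (residue_index ->
#'   name) to include.
#' @export
write_profile_csv <- function(profile, path, residue_names = NULL) {
  df <- as.data.frame(profile)
  df$denominator <- attr(profile, "denominator")
  df$phase <- attr(profile, "phase")
  if (!is.null(residue_names))
    df$residue_name <- residue_names[as.character(df$residue_index)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Map a residue contact profile onto a PDB structure via B-factors
#'
#' Writes a copy of the structure with every atom's B-factor set to
#' 100 x its residue's contact probability (0.00 for residues absent from
#' the profile), so molecular viewers can color the binding interface.
#'
#' @param pdb_path input PDB file.
#' @param profile a `residue_contact_profile`.
#' @param out_path output PDB file.
#' @param residue_offset added to profile residue indices to match the PDB
#'   numbering (default 0).
#' @return invisibly, the number of structure residues that matched the
#'   profile.
#' @export
write_bfactor_pdb <- function(pdb_path, profile, out_path,
                              residue_offset = 0L) {
  pdb <- bio3d::read.pdb(pdb_path)
  prof_res <- profile$residue_index + residue_offset
  b <- profile$probability[match(pdb$atom$resno, prof_res)]
  n_match <- length(intersect(unique(pdb$atom$resno), prof_res))
  if (n_match == 0L)
    stop("no residue overlap between the structure and the profile")
  pdb$atom$b <- round(ifelse(is.na(b), 0, 100 * b), 2)
  bio3d::write.pdb(pdb, file = out_path)
  invisible(n_match)
}
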