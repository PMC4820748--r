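#' Analysis parameters for membrane-association statistics
#'
#' Bundles every constant the contact/insertion analysis depends on. The
#' defaults are the standard coarse-grained analysis settings for this
#' workflow: a snapshot counts as a contact when the minimum protein-lipid
#' bead distance falls strictly below 6 angstrom (0.6 nm); an insertion
#' event is the first run of three successive snapshots in which the
#' lipid-anchor residue touches the membrane; ensemble "subtotal" curves use
#' a 10 ns trailing window on trajectories sampled every 2 ns; per-residue
#' contact probabilities are evaluated against the Martini lipid head-group
#' beads C1A, C1B, NH3 and PO4.
#'
#' @param contact_threshold Contact cut-off in nm (strict `<`). Default 0.6
#'   (6 angstrom).
#' @param insertion_run_length Number of successive anchor-contact snapshots
#'   that defines an insertion event. Default 3.
#' @param subtotal_window Trailing window length in ns for the subtotal
#'   curve. Default 10.
#' @param frame_interval Analysis snapshot interval in ns. Default 2.
#' @param head_group_bead_names Bead names making up a lipid head group.
#' @param anchor_residue_index Residue index of the lipid-anchored residue
#'   (the palmitoylated cysteine; residue 70 in the reference numbering).
#' @param residue_contact_threshold Cut-off in nm for residue-level
#'   head-group contacts; defaults to `contact_threshold` so one threshold
#'   governs both definitions.
#' @param insertion_report Which snapshot of the qualifying run is reported
#'   as the insertion event: `"run_start"` (default) or `"run_end"` (the
#'   `insertion_run_length`-th snapshot).
#' @return An object of class `"analysis_params"`.
#' @export
analysis_params <- function(contact_threshold = 0.6,
                            insertion_run_length = 3L,
                            subtotal_window = 10,
                            frame_interval = 2,
                            head_group_bead_names = c("C1A", "C1B", "NH3", "PO4"),
                            anchor_residue_index = 70L,
                            residue_contact_threshold = contact_threshold,
                            insertion_report = c("run_start", "run_end")) {
  insertion_report <- match.arg(insertion_report)
  stopifnot(
    is.numeric(contact_threshold), length(contact_threshold) == 1L,
    contact_threshold > 0,
    is.numeric(residue_contact_threshold), residue_contact_threshold > 0,
    is.numeric(insertion_run_length), insertion_run_length >= 1,
    is.numeric(frame_interval), frame_interval > 0,
    is.numeric(subtotal_window), subtotal_window >= frame_interval,
    is.character(head_group_bead_names), length(head_group_bead_names) >= 1L,
    is.numeric(anchor_residue_index), length(anchor_residue_index) == 1L
  )
  structure(list(
    contact_threshold = as.numeric(contact_threshold),
    insertion_run_length = as.integer(insertion_run_length),
    subtotal_window = as.numeric(subtotal_window),
    frame_interval = as.numeric(frame_interval),
    head_group_bead_names = as.character(head_group_bead_names),
    anchor_residue_index = as.integer(anchor_residue_index),
    residue_contact_threshold = as.numeric(residue_contact_threshold),
    insertion_report = insertion_report
  ), class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Membrane-association analysis parameters\n")
  cat(sprintf("  contact threshold      : %.3f nm (%.1f A, strict <)\n",
              x$contact_threshold, 10 * x$contact_threshold))
  cat(sprintf("  insertion run length   : %d successive snapshots\n",
              x$insertion_run_length))
  cat(sprintf("  snapshot interval      : %g ns\n", x$frame_interval))
  cat(sprintf("  subtotal window        : %g ns\n", x$subtotal_window))
  cat(sprintf("  head-group beads       : %s\n",
              paste(x$head_group_bead_names, collapse = ", ")))
  cat(sprintf("  anchor residue         : %d\n", x$anchor_residue_index))
  invisible(x)
}
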