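# Independent reference implementations used as oracles, plus small
# fixture builders. Kept deliberately naive (plain R loops) so they share
# nothing with the package's kernels.

# all-pairs minimum-image minimum distance, plain R
oracle_min_dist <- function(A, B, box) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- A[i, ] - B[j, ]
      d <- d - box * round(d / box)
      best <- min(best, sqrt(sum(d^2)))
    }
  }
  best
}

# first index of the first run of >= len consecutive TRUEs, by direct scan
oracle_first_run <- function(mask, len) {
  n <- length(mask)
  if (n < len) return(NA_integer_)
  for (i in seq_len(n - len + 1L)) {
    if (all(mask[i:(i + len - 1L)])) return(i)
  }
  NA_integer_
}

# random frame pair for kernel comparisons
random_frame_pair <- function(na = 30L, nb = 40L) {
  box <- runif(3, 2, 12)
  list(
    A = cbind(runif(na, -5, 15), runif(na, -5, 15), runif(na, -5, 15)),
    B = cbind(runif(nb, -5, 15), runif(nb, -5, 15), runif(nb, -5, 15)),
    box = box
  )
}

# minimal trajectory: one protein bead per residue plus lipid beads at
# given coordinates, constant box
toy_trajectory <- function(protein_coords_list, lipid_coords,
                           lipid_names = rep("PO4", nrow(lipid_coords)),
                           box = c(10, 10, 10), times = NULL) {
  np <- nrow(protein_coords_list[[1]])
  topo <- bead_topology(
    bead_name = c(rep("BB", np), lipid_names),
    residue_index = c(seq_len(np), np + seq_len(nrow(lipid_coords))),
    residue_name = c(rep("ALA", np), rep("POPE", nrow(lipid_coords))),
    group = c(rep("protein", np), rep("lipid", nrow(lipid_coords)))
  )
  if (is.null(times)) times <- 2 * seq_along(protein_coords_list)
  frames <- lapply(seq_along(protein_coords_list), function(i)
    cg_frame(times[i], box, rbind(protein_coords_list[[i]], lipid_coords)))
  cg_trajectory(topo, frames)
}

# hand-built event record for curve tests
make_record <- function(times, contact_mask, anchor_mask = contact_mask,
                        insertion_frame = NA_integer_, id = "r") {
  fc <- if (any(contact_mask)) which(contact_mask)[1] else NA_integer_
  structure(list(
    trajectory_id = id, times = times, contact_mask = contact_mask,
    anchor_mask = anchor_mask, first_contact_frame = fc,
    insertion_frame = as.integer(insertion_frame),
    classification = classify_trajectory(contact_mask,
                                         as.integer(insertion_frame))
  ), class = "event_record")
}

# small fast sim config for tests (reduced membrane patch and protein)
tiny_sim_config <- function(...) {
  # 36 lipids on a 4 x 4 nm patch: 0.67 nm spacing keeps every surface
  # point within the 0.6 nm contact threshold of a head bead, so a pinned
  # anchor is in permanent contact
  defaults <- list(n_lipids = 36L, box = c(4, 4, 10), n_residues = 12L,
                   anchor_residue_index = 5L, radius_of_gyration = 0.8,
                   n_frames = 40L, initial_z_offset = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# analysis params matching tiny_sim_config's anchor residue
tiny_params <- function(...) analysis_params(anchor_residue_index = 5L, ...)
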