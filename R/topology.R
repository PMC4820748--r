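#' Construct a bead topology table
#'
#' A bead topology is a data.frame with one row per coarse-grained bead and
#' columns `bead_id` (0-based, contiguous), `bead_name`, `residue_index`,
#' `residue_name`, `group` (one of protein/lipid/solvent/ion) and
#' `molecule_id`.
#'
#' @param bead_name character vector of bead names (e.g. "BB", "SC1", "PO4").
#' @param residue_index integer vector of residue indices.
#' @param residue_name character vector of residue names.
#' @param group group label per bead; defaults to `"protein"`.
#' @param molecule_id integer molecule identifier; defaults to
#'   `residue_index` (each residue its own molecule), which suits lipids and
#'   is immaterial for the analyses here.
#' @return data.frame of class `c("bead_topology", "data.frame")`.
#' @export
bead_topology <- function(bead_name, residue_index, residue_name,
                          group = "protein", molecule_id = residue_index) {
  n <- length(bead_name)
  stopifnot(length(residue_index) == n, length(residue_name) == n)
  group <- rep_len(as.character(group), n)
  bad <- setdiff(unique(group), c("protein", "lipid", "solvent", "ion"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(
    bead_id = seq_len(n) - 1L,
    bead_name = as.character(bead_name),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    group = group,
    molecule_id = rep_len(as.integer(molecule_id), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bead_topology", "data.frame")
  out
}

#' Assign protein/lipid/solvent groups by residue name
#'
#' Partitions the beads of a topology: residues named in
#' `lipid_residue_names` become `lipid`, residues in `solvent_residue_names`
#' become `solvent` (or `ion` for names in `ion_residue_names`), and all
#' remaining beads are `protein`.
#'
#' @param topology a `bead_topology`.
#' @param lipid_residue_names character set of lipid residue names
#'   (e.g. "POPE"). Must be non-empty.
#' @param solvent_residue_names character set of solvent residue names
#'   (e.g. "W"). May be empty.
#' @param ion_residue_names character set of ion residue names
#'   (e.g. "NA", "CL"). May be empty.
#' @param verbose log the per-group bead counts. Default FALSE.
#' @return the topology with updated `group` column.
#' @export
assign_groups <- function(topology, lipid_residue_names,
                          solvent_residue_names = character(),
                          ion_residue_names = character(),
                          verbose = FALSE) {
  if (length(lipid_residue_names) == 0L)
    stop("lipid_residue_names must be non-empty")
  g <- rep("protein", nrow(topology))
  g[topology$residue_name %in% lipid_residue_names] <- "lipid"
  g[topology$residue_name %in% solvent_residue_names] <- "solvent"
  g[topology$residue_name %in% ion_residue_names] <- "ion"
  topology$group <- g
  counts <- table(factor(g, levels = c("protein", "lipid", "solvent", "ion")))
  if (counts[["lipid"]] == 0L)
    stop("no beads assigned to the lipid group; check lipid_residue_names")
  if (counts[["protein"]] == 0L)
    stop("no beads left in the protein group after assignment")
  if (verbose)
    message("group counts: ",
            paste(names(counts), as.integer(counts), sep = "=", collapse = " "))
  topology
}

#' Select bead indices from a topology
#'
#' @param topology a `bead_topology`.
#' @param group optional group label(s) to keep.
#' @param bead_names optional bead name set to keep.
#' @param residue_index optional residue index set to keep.
#' @return integer vector of 1-based row indices into the topology.
#' @export
select_beads <- function(topology, group = NULL, bead_names = NULL,
                         residue_index = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(group)) keep <- keep & topology$group %in% group
  if (!is.null(bead_names)) keep <- keep & topology$bead_name %in% bead_names
  if (!is.null(residue_index))
    keep <- keep & topology$residue_index %in% residue_index
  which(keep)
}

#' Write a topology summary as JSON
#'
#' Records bead/residue counts per group and the bead-name vocabulary; a
#' light audit trail for pipeline runs.
#'
#' @param topology a `bead_topology`.
#' @param path output file path.
#' @export
write_topology_summary <- function(topology, path) {
  by_group <- split(topology, topology$group)
  summ <- list(
    n_beads = nrow(topology),
    n_residues = length(unique(paste(topology$molecule_id,
                                     topology$residue_index))),
    groups = lapply(by_group, function(d) list(
      n_beads = nrow(d),
      n_residues = length(unique(paste(d$molecule_id, d$residue_index))),
      bead_names = sort(unique(d$bead_name)),
      residue_names = sort(unique(d$residue_name))
    ))
  )
  jsonlite::write_json(summ, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
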