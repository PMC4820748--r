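#' Minimum distance between two bead selections under periodic boundaries
#'
#' Returns the minimum over all pairs (a in A, b in B) of the minimum-image
#' Euclidean distance under the frame's orthorhombic box. The default
#' cell-list kernel searches outward over shells of grid cells and is exact:
#' it returns the same value as the all-pairs scan (`method = "brute"`).
#'
#' @param frame a `cg_frame`.
#' @param topology the matching `bead_topology`.
#' @param set_a,set_b integer bead indices (1-based rows of the topology),
#'   e.g. from [select_beads()]. Both must be non-empty.
#' @param method `"cells"` (spatial binning, default) or `"brute"`
#'   (all-pairs scan).
#' @param cell_size target cell edge in nm for the binned kernel.
#' @return minimum distance in nm.
#' @export
min_group_distance <- function(frame, topology, set_a, set_b,
                               method = c("cells", "brute"),
                               cell_size = 1.0) {
  method <- match.arg(method)
  if (length(set_a) == 0L) stop("selection 'set_a' is empty")
  if (length(set_b) == 0L) stop("selection 'set_b' is empty")
  A <- frame$coords[set_a, , drop = FALSE]
  B <- frame$coords[set_b, , drop = FALSE]
  if (method == "brute") {
    min_dist_brute_cpp(A, B, frame$box)
  } else {
    min_dist_cells_cpp(A, B, frame$box, cell_size)
  }
}
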