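#' Configuration for the synthetic protein-near-membrane generator
#'
#' The generator is a phenomenological Brownian-dynamics surrogate for
#' coarse-grained MD of a peripheral membrane protein near a planar
#' bilayer: a rigid protein bead cloud diffuses (translation + rotation)
#' above a static single-leaflet lipid patch, is pulled by a short-range
#' attractive well at the membrane surface, and — when lipid-anchored — can
#' irreversibly insert its anchor residue once it reaches head-group
#' proximity. Defaults mirror the reference simulation setup: an
#' 11 x 11 x 17 nm box, 410 lipids, a 7 nm initial center-of-mass
#' z-separation, 500 snapshots of 2 ns each (1 microsecond).
#'
#' @param box box edges in nm.
#' @param n_lipids number of lipid molecules on the leaflet lattice.
#' @param lipid_lattice_spacing lattice spacing in nm; `NULL` picks
#'   `box_x / ceiling(sqrt(n_lipids))`.
#' @param n_tail_beads tail beads per lipid (plus the 4 head beads
#'   C1A, C1B, NH3, PO4). Default 8, i.e. 12 beads per lipid.
#' @param protein_model `"monomer"` or `"dimer"` (two copies related by a
#'   180-degree rotation, anchor residues adjacent).
#' @param n_residues protein residues per chain (default 163, a 5-repeat
#'   ankyrin-repeat stack at 2 beads per residue).
#' @param beads_per_residue coarse-grained beads per residue (default 2:
#'   backbone BB + side-chain SC1).
#' @param radius_of_gyration target protein radius of gyration in nm.
#' @param anchored logical: is the anchor residue lipid-modified (able to
#'   insert)?
#' @param anchor_residue_index residue index of the anchor (default 70).
#' @param initial_z_offset center-of-mass z-separation of protein and
#'   membrane at t = 0, in nm (default 7.0).
#' @param translational_diffusion nm^2/ns.
#' @param rotational_diffusion rad^2/ns.
#' @param membrane_well_depth drift speed scale of the attractive surface
#'   well, nm/ns.
#' @param membrane_well_range decay length of the well, nm.
#' @param anchor_capture_distance anchor-to-lipid-bead distance (nm) below
#'   which insertion may fire. The default equals the 0.6 nm contact
#'   threshold, so capture requires actual anchor-membrane contact.
#' @param anchor_capture_hazard per-snapshot insertion probability while
#'   within capture distance, in `[0, 1]`. The default of 1 makes
#'   insertion coincide with the first anchor contact (acyl-chain burial
#'   is effectively instantaneous at the 2 ns snapshot resolution); set
#'   below 1 to study stochastic waiting times.
#' @param irreversible once inserted, stay inserted (anchor pinned to the
#'   head-bead plane). Default TRUE.
#' @param timestep snapshot interval in ns.
#' @param n_frames number of snapshots after the initial frame.
#' @param membrane_z_frac head-bead plane height as a fraction of `box_z`.
#' @param truth_contact_threshold threshold (nm) used for the ground-truth
#'   first-contact log.
#' @param random_initial_orientation draw a uniform random initial protein
#'   orientation (as in ensemble designs that vary the starting pose).
#' @param seed RNG seed; fixes the whole trajectory.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(box = c(11, 11, 17),
                       n_lipids = 410L,
                       lipid_lattice_spacing = NULL,
                       n_tail_beads = 8L,
                       protein_model = c("monomer", "dimer"),
                       n_residues = 163L,
                       beads_per_residue = 2L,
                       radius_of_gyration = 1.6,
                       anchored = TRUE,
                       anchor_residue_index = 70L,
                       initial_z_offset = 7.0,
                       translational_diffusion = 0.05,
                       rotational_diffusion = 0.02,
                       membrane_well_depth = 0.05,
                       membrane_well_range = 1.0,
                       anchor_capture_distance = 0.6,
                       anchor_capture_hazard = 1.0,
                       irreversible = TRUE,
                       timestep = 2,
                       n_frames = 500L,
                       membrane_z_frac = 0.3,
                       truth_contact_threshold = 0.6,
                       random_initial_orientation = TRUE,
                       seed = 1L) {
  protein_model <- match.arg(protein_model)
  stopifnot(
    length(box) == 3L, all(box > 0),
    n_lipids >= 1L, n_tail_beads >= 0L,
    n_residues >= 2L, beads_per_residue >= 1L,
    radius_of_gyration > 0,
    anchor_residue_index >= 1L, anchor_residue_index <= n_residues,
    initial_z_offset >= 0,
    translational_diffusion > 0, rotational_diffusion > 0,
    membrane_well_depth >= 0, membrane_well_range > 0,
    anchor_capture_distance > 0,
    anchor_capture_hazard >= 0, anchor_capture_hazard <= 1,
    timestep > 0, n_frames >= 1L,
    membrane_z_frac > 0, membrane_z_frac < 1,
    truth_contact_threshold > 0
  )
  structure(as.list(environment()), class = "sim_config")
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# rotation by `angle` about unit `axis` (Rodrigues)
axis_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Build the synthetic single-leaflet membrane patch
#'
#' Places `n_lipids` lipids on a jittered square lattice. Each lipid has
#' the four head-group beads (NH3, PO4, C1A, C1B) near the surface plane
#' (within 0.2 nm) and `n_tail_beads` tail beads strictly below, so the
#' nearest lipid bead seen from above the membrane is always a head-group
#' bead. The leaflet is static; solvent is implicit.
#'
#' @param config a [sim_config()]. Consumes RNG (lattice jitter).
#' @return list with `topology` (lipid beads), `coords` (nm) and `z_head`
#'   (surface plane height, nm).
#' @export
build_membrane <- function(config) {
  nl <- config$n_lipids
  nx <- ceiling(sqrt(nl))
  spacing <- config$lipid_lattice_spacing
  if (is.null(spacing)) spacing <- config$box[1] / nx
  ny <- ceiling(nl / nx)
  if (nx * spacing > config$box[1] + 1e-9 ||
      ny * spacing > config$box[2] + 1e-9)
    stop(sprintf(paste0("lipid lattice (%d x %d at %.3f nm) overflows the ",
                        "box x-y area; reduce lipid_lattice_spacing"),
                 nx, ny, spacing))
  z_head <- config$membrane_z_frac * config$box[3]

  # per-lipid bead template: (name, dx, dz)
  n_tail <- config$n_tail_beads
  ta <- ceiling(n_tail / 2)
  tb <- n_tail - ta
  tmpl <- data.frame(
    name = c("NH3", "PO4", "C1A", "C1B",
             if (ta > 0) paste0("C", 1 + seq_len(ta), "A"),
             if (tb > 0) paste0("C", 1 + seq_len(tb), "B")),
    dx = c(0, 0, 0.12, -0.12,
           rep(0.12, ta), rep(-0.12, tb)),
    dz = c(0.10, 0, -0.18, -0.18,
           if (ta > 0) -0.5 - 0.3 * (seq_len(ta) - 1),
           if (tb > 0) -0.5 - 0.3 * (seq_len(tb) - 1)),
    stringsAsFactors = FALSE
  )
  bpl <- nrow(tmpl)

  idx <- seq_len(nl) - 1L
  cx <- (idx %% nx + 0.5) * spacing +
    stats::runif(nl, -0.1, 0.1) * spacing
  cy <- (idx %/% nx + 0.5) * spacing +
    stats::runif(nl, -0.1, 0.1) * spacing
  cz <- z_head + stats::runif(nl, -0.02, 0.02)

  coords <- matrix(0, nl * bpl, 3)
  coords[, 1] <- rep(cx, each = bpl) + rep(tmpl$dx, nl)
  coords[, 2] <- rep(cy, each = bpl)
  coords[, 3] <- rep(cz, each = bpl) + rep(tmpl$dz, nl)

  topo <- bead_topology(
    bead_name = rep(tmpl$name, nl),
    residue_index = rep(seq_len(nl), each = bpl),
    residue_name = rep("POPE", nl * bpl),
    group = "lipid",
    molecule_id = rep(seq_len(nl), each = bpl)
  )
  list(topology = topo, coords = coords, z_head = z_head)
}

#' Build the rigid protein bead cloud
#'
#' Samples a connected backbone random walk, attaches side-chain beads,
#' rescales to the target radius of gyration, and places the anchor
#' residue's side chain on the protein surface (the most COM-distal
#' residue position is given to the anchor, so insertion is geometrically
#' possible). Dimer mode concatenates a second copy related by a
#' 180-degree rotation with the two anchor side chains adjacent.
#'
#' @param config a [sim_config()]. Consumes RNG.
#' @return list with `topology` (protein beads, residue name CYS for the
#'   anchor, ALA otherwise) and `coords` (nm, centered on the COM).
#' @export
build_protein <- function(config) {
  nres <- config$n_residues
  bpr <- config$beads_per_residue
  if (config$radius_of_gyration <= 0)
    stop("radius_of_gyration target must be positive")

  step <- matrix(stats::rnorm(3 * (nres - 1)), ncol = 3)
  step <- step / sqrt(rowSums(step^2)) * 0.35
  bb <- rbind(c(0, 0, 0), apply(step, 2, cumsum))
  if (nres == 2L) bb <- matrix(bb, ncol = 3)

  coords <- matrix(0, nres * bpr, 3)
  for (r in seq_len(nres)) {
    rows <- (r - 1L) * bpr + seq_len(bpr)
    coords[rows[1], ] <- bb[r, ]
    if (bpr > 1L) {
      off <- matrix(stats::rnorm(3 * (bpr - 1L)), ncol = 3)
      off <- off / sqrt(rowSums(off^2)) * 0.25
      coords[rows[-1], ] <- sweep(off, 2, bb[r, ], `+`)
    }
  }
  coords <- sweep(coords, 2, colMeans(coords))
  rg <- sqrt(mean(rowSums(coords^2)))
  if (rg < 1e-12) stop("degenerate bead cloud; cannot reach target Rg")
  coords <- coords * (config$radius_of_gyration / rg)

  # put the anchor residue at the most surface-exposed position
  res_of <- rep(seq_len(nres), each = bpr)
  sc_row <- if (bpr > 1L) 2L else 1L
  sc_rows <- (seq_len(nres) - 1L) * bpr + sc_row
  far <- which.max(rowSums(coords[sc_rows, , drop = FALSE]^2))
  a <- config$anchor_residue_index
  if (far != a) {
    ra <- (a - 1L) * bpr + seq_len(bpr)
    rf <- (far - 1L) * bpr + seq_len(bpr)
    tmp <- coords[ra, , drop = FALSE]
    coords[ra, ] <- coords[rf, , drop = FALSE]
    coords[rf, ] <- tmp
  }

  bead_name <- rep(c("BB", paste0("SC", seq_len(max(bpr - 1L, 0L)))),
                   nres)[seq_len(nres * bpr)]
  resname <- ifelse(res_of == a, "CYS", "ALA")

  if (config$protein_model == "dimer") {
    flip <- diag(c(1, -1, -1))  # 180 degrees about x
    c2 <- coords %*% flip
    a_sc <- (a - 1L) * bpr + sc_row
    shift <- coords[a_sc, ] + c(0.5, 0, 0) - c2[a_sc, ]
    c2 <- sweep(c2, 2, shift, `+`)
    coords <- rbind(coords, c2)
    coords <- sweep(coords, 2, colMeans(coords))
    bead_name <- rep(bead_name, 2L)
    res_index <- c(res_of, res_of)
    resname <- rep(resname, 2L)
    mol <- rep(1:2, each = nres * bpr)
  } else {
    res_index <- res_of
    mol <- rep(1L, nres * bpr)
  }

  topo <- bead_topology(bead_name, res_index, resname,
                        group = "protein", molecule_id = mol)
  list(topology = topo, coords = coords)
}

#' Simulate one synthetic protein-near-membrane trajectory
#'
#' Overdamped rigid-body dynamics per snapshot: isotropic Gaussian
#' center-of-mass displacement (variance `2 D_t dt` per axis) plus a
#' downhill drift toward the membrane from the exponential surface well;
#' Gaussian rotation about a random axis (variance `2 D_r dt`); x-y
#' periodic wrap of the center of mass; reflecting walls at the box top and
#' the membrane surface plane. When the anchor residue comes within
#' `anchor_capture_distance` of a lipid bead (and `anchored = TRUE`),
#' insertion fires with probability `anchor_capture_hazard` per snapshot;
#' once fired in irreversible mode the anchor side chain is pinned to the
#' head-bead plane for all later frames, which guarantees permanent
#' membrane contact.
#'
#' The emitted trajectory has the initial frame at t = 0 plus `n_frames`
#' frames at multiples of `timestep`; ground-truth frame indices refer to
#' the post-t0 snapshot numbering (1-based), i.e. the numbering obtained by
#' `subsample_frames(trajectory, timestep)`.
#'
#' @param config a [sim_config()].
#' @param id trajectory identifier for the ground-truth log.
#' @return list with `trajectory` (a `cg_trajectory`) and `truth` (a
#'   `ground_truth_log`: `trajectory_id`, `true_first_contact_frame`,
#'   `true_insertion_frame`, `anchored_state`).
#' @export
simulate_trajectory <- function(config, id = "traj") {
  set.seed(config$seed)
  mem <- build_membrane(config)
  pro <- build_protein(config)
  box <- config$box
  dt <- config$timestep
  sd_t <- sqrt(2 * config$translational_diffusion * dt)
  sd_r <- sqrt(2 * config$rotational_diffusion * dt)

  P <- pro$coords
  if (config$random_initial_orientation) P <- P %*% t(random_rotation())

  mem_com_z <- mean(mem$coords[, 3])
  start <- c(box[1] / 2, box[2] / 2, mem_com_z + config$initial_z_offset)
  P <- sweep(P, 2, start, `+`)
  z_head <- mem$z_head

  bpr <- config$beads_per_residue
  sc_row <- if (bpr > 1L) 2L else 1L
  anchor_rows <- which(pro$topology$residue_index ==
                         config$anchor_residue_index)
  pin_candidates <- anchor_rows[pro$topology$bead_name[anchor_rows] ==
                                  pro$topology$bead_name[anchor_rows][sc_row]]
  if (length(pin_candidates) == 0L) pin_candidates <- anchor_rows

  nf <- config$n_frames
  frames <- vector("list", nf + 1L)
  frames[[1L]] <- cg_frame(0, box, rbind(P, mem$coords))

  inserted <- FALSE
  pin_row <- NA_integer_
  anchored_state <- logical(nf)
  first_contact <- NA_integer_
  insertion_frame <- NA_integer_

  for (k in seq_len(nf)) {
    com <- colMeans(P)
    # rotation about the center of mass
    ax <- stats::rnorm(3)
    ang <- stats::rnorm(1, 0, sd_r)
    R <- axis_rotation(ax, ang)
    P <- sweep(sweep(P, 2, com) %*% t(R), 2, com, `+`)
    # translation with membrane well drift
    disp <- stats::rnorm(3, 0, sd_t)
    gap <- com[3] - z_head
    disp[3] <- disp[3] -
      config$membrane_well_depth * exp(-max(gap, 0) / config$membrane_well_range) * dt
    P <- sweep(P, 2, disp, `+`)
    com <- com + disp
    # periodic wrap in x-y (whole-protein shift keeps it rigid)
    shift_xy <- -box[1:2] * floor(com[1:2] / box[1:2])
    if (any(shift_xy != 0)) {
      P[, 1] <- P[, 1] + shift_xy[1]
      P[, 2] <- P[, 2] + shift_xy[2]
      com[1:2] <- com[1:2] + shift_xy
    }
    # reflecting walls for the center of mass in z
    if (com[3] > box[3]) {
      dz <- 2 * box[3] - com[3] - com[3]
      P[, 3] <- P[, 3] + dz; com[3] <- com[3] + dz
    }
    if (com[3] < z_head) {
      dz <- 2 * z_head - com[3] - com[3]
      P[, 3] <- P[, 3] + dz; com[3] <- com[3] + dz
    }

    if (inserted && config$irreversible) {
      dz <- z_head - P[pin_row, 3]
      P[, 3] <- P[, 3] + dz
    } else if (config$anchored && !inserted) {
      # capture eligibility uses the same bead set as the insertion
      # detector (anchor residue vs all lipid beads), so deterministic
      # capture coincides with the first detectable anchor contact
      d_anchor <- min_dist_brute_cpp(P[anchor_rows, , drop = FALSE],
                                     mem$coords, box)
      if (d_anchor < config$anchor_capture_distance &&
          stats::runif(1) < config$anchor_capture_hazard) {
        inserted <- TRUE
        insertion_frame <- k
        if (config$irreversible) {
          # pin the anchor side chain closest to the surface plane
          pin_row <- pin_candidates[which.min(abs(P[pin_candidates, 3] - z_head))]
          dz <- z_head - P[pin_row, 3]
          P[, 3] <- P[, 3] + dz
        }
      }
    }
    anchored_state[k] <- inserted

    if (is.na(first_contact) &&
        any_within_cpp(P, mem$coords, box, config$truth_contact_threshold))
      first_contact <- k

    frames[[k + 1L]] <- cg_frame(k * dt, box, rbind(P, mem$coords))
  }

  topo <- rbind(as.data.frame(pro$topology),
                as.data.frame(mem$topology))
  topo$bead_id <- seq_len(nrow(topo)) - 1L
  topo$molecule_id <- c(pro$topology$molecule_id,
                        mem$topology$molecule_id + max(pro$topology$molecule_id))
  class(topo) <- c("bead_topology", "data.frame")

  traj <- cg_trajectory(topo, frames, provenance = list(
    generator = "membanchor brownian surrogate",
    seed = config$seed,
    protein_model = config$protein_model,
    anchored = config$anchored
  ))
  truth <- structure(list(
    trajectory_id = id,
    true_first_contact_frame = first_contact,
    true_insertion_frame = insertion_frame,
    anchored_state = anchored_state
  ), class = "ground_truth_log")
  list(trajectory = traj, truth = truth)
}

#' Run a seeded ensemble of synthetic trajectories
#'
#' Runs [simulate_trajectory()] with seeds `base_seed + i` (i = 1..n) and
#' per-trajectory random initial orientations; fully reproducible from
#' `(config, base_seed)`.
#'
#' @param config a [sim_config()]; its `seed` field is overridden per
#'   trajectory.
#' @param n_trajectories ensemble size (e.g. 100 anchored, 10 plain, 16
#'   dimer in the reference design).
#' @param base_seed integer base seed.
#' @return list with `trajectories` (list of `cg_trajectory`) and `truths`
#'   (list of `ground_truth_log`).
#' @export
run_ensemble <- function(config, n_trajectories, base_seed = 0L) {
  stopifnot(n_trajectories >= 1L)
  out <- lapply(seq_len(n_trajectories), function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    simulate_trajectory(cfg, id = sprintf("traj_%03d", i))
  })
  list(trajectories = lapply(out, `[[`, "trajectory"),
       truths = lapply(out, `[[`, "truth"))
}

#' Write a ground-truth log list as a JSON sidecar
#' @param truths list of `ground_truth_log`s.
#' @param path output file path.
#' @export
write_ground_truth_json <- function(truths, path) {
  jsonlite::write_json(lapply(truths, function(tr) list(
    trajectory_id = tr$trajectory_id,
    true_first_contact_frame = tr$true_first_contact_frame,
    true_insertion_frame = tr$true_insertion_frame,
    anchored_state = tr$anchored_state
  )), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Serialize a sim_config as YAML
#' @param config a [sim_config()].
#' @param path output file path.
#' @export
write_sim_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a sim_config from YAML
#' @param path YAML file written by [write_sim_config_yaml()].
#' @return a [sim_config()].
#' @export
read_sim_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}
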