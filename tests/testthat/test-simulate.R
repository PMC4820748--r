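test_that("membrane construction places head beads at the surface plane", {
  set.seed(5)
  cfg <- sim_config(n_lipids = 410L, n_tail_beads = 8L)
  mem <- build_membrane(cfg)
  expect_equal(nrow(mem$topology), 410L * 12L)
  heads <- mem$topology$bead_name %in% c("C1A", "C1B", "NH3", "PO4")
  expect_equal(sum(heads), 410L * 4L)
  expect_true(all(abs(mem$coords[heads, 3] - mem$z_head) <= 0.2 + 1e-9))
  # tails strictly below every head bead
  expect_lt(max(mem$coords[!heads, 3]), min(mem$coords[heads, 3]))
})

test_that("a single lipid is a one-column stack", {
  set.seed(5)
  mem <- build_membrane(sim_config(n_lipids = 1L))
  expect_equal(nrow(mem$topology), 12L)
  expect_equal(unique(mem$topology$residue_index), 1L)
})

test_that("lattice jitter keeps neighboring lipids at least 0.8 spacing apart", {
  for (s in 1:100) {
    set.seed(s)
    cfg <- sim_config(n_lipids = 49L, box = c(7, 7, 17))
    mem <- build_membrane(cfg)
    po4 <- mem$coords[mem$topology$bead_name == "PO4", ]
    dmin <- min(dist(po4[, 1:2]))
    spacing <- 7 / ceiling(sqrt(49))
    expect_gte(dmin, 0.8 * spacing)
  }
})

test_that("lattice overflow is reported with a spacing hint", {
  set.seed(1)
  expect_error(build_membrane(sim_config(n_lipids = 410L,
                                         lipid_lattice_spacing = 2)),
               "spacing")
})

test_that("protein construction matches the requested size and geometry", {
  set.seed(9)
  cfg <- sim_config(n_residues = 163L, beads_per_residue = 2L)
  pro <- build_protein(cfg)
  expect_equal(nrow(pro$topology), 326L)
  rg <- sqrt(mean(rowSums(scale(pro$coords, scale = FALSE)^2)))
  expect_equal(rg, cfg$radius_of_gyration, tolerance = 1e-6)
  expect_equal(sum(pro$topology$residue_name == "CYS"), 2L)  # BB + SC1

  set.seed(9)
  dim_cfg <- sim_config(n_residues = 163L, protein_model = "dimer")
  dpro <- build_protein(dim_cfg)
  expect_equal(nrow(dpro$topology), 652L)
  # two anchor residues, one per chain
  anchors <- dpro$topology[dpro$topology$residue_index == 70L, ]
  expect_equal(length(unique(anchors$molecule_id)), 2L)
})

test_that("same seed gives identical trajectories, different seeds differ", {
  cfg <- tiny_sim_config(seed = 31L)
  a <- simulate_trajectory(cfg)
  b <- simulate_trajectory(cfg)
  expect_identical(a$trajectory$frames, b$trajectory$frames)
  expect_identical(a$truth, b$truth)
  cfg2 <- tiny_sim_config(seed = 32L)
  c <- simulate_trajectory(cfg2)
  expect_false(identical(a$trajectory$frames[[10]]$coords,
                         c$trajectory$frames[[10]]$coords))
})

test_that("non-anchored proteins never insert", {
  for (s in 1:10) {
    sim <- simulate_trajectory(tiny_sim_config(anchored = FALSE, seed = s))
    expect_true(is.na(sim$truth$true_insertion_frame))
    expect_false(any(sim$truth$anchored_state))
  }
})

test_that("forced capture inserts at the first analyzable snapshot", {
  sim <- simulate_trajectory(tiny_sim_config(
    anchored = TRUE, anchor_capture_hazard = 1,
    anchor_capture_distance = 100, initial_z_offset = 0, seed = 3))
  expect_equal(sim$truth$true_insertion_frame, 1L)
  expect_true(all(sim$truth$anchored_state))
})

test_that("anchored state is monotone in irreversible mode", {
  for (s in 1:8) {
    sim <- simulate_trajectory(tiny_sim_config(
      anchored = TRUE, anchor_capture_hazard = 0.3, seed = 100 + s))
    st <- sim$truth$anchored_state
    expect_true(all(diff(st) >= 0))  # false -> true at most once
    if (!is.na(sim$truth$true_insertion_frame))
      expect_true(all(st[sim$truth$true_insertion_frame:length(st)]))
  }
})

test_that("free diffusion reproduces the 2*D*t mean-squared displacement", {
  # no well, no capture, boundaries far away: COM z displacement variance
  # over a lag of L snapshots must be 2 * D_t * (L * dt)
  D <- 0.05; dt <- 2
  nseed <- 200L; nfr <- 40L
  disp1 <- c(); disp4 <- c()
  for (s in 1:nseed) {
    sim <- simulate_trajectory(sim_config(
      n_lipids = 4L, box = c(3, 3, 200), n_residues = 2L,
      beads_per_residue = 1L, radius_of_gyration = 0.3,
      anchor_residue_index = 1L,
      anchored = FALSE, membrane_well_depth = 0,
      initial_z_offset = 80, translational_diffusion = D,
      timestep = dt, n_frames = nfr, seed = 5000 + s))
    nprot <- 2L
    z <- vapply(sim$trajectory$frames,
                function(fr) mean(fr$coords[seq_len(nprot), 3]), numeric(1))
    disp1 <- c(disp1, diff(z, lag = 1))
    disp4 <- c(disp4, z[seq(5, nfr + 1, by = 4)] - z[seq(1, nfr - 3, by = 4)])
  }
  expect_equal(mean(disp1^2), 2 * D * dt, tolerance = 0.1)
  expect_equal(mean(disp4^2), 2 * D * 4 * dt, tolerance = 0.1)
})

test_that("ensembles are reproducible from (config, base_seed)", {
  cfg <- tiny_sim_config()
  e1 <- run_ensemble(cfg, 3, base_seed = 77)
  e2 <- run_ensemble(cfg, 3, base_seed = 77)
  expect_identical(lapply(e1$truths, unclass), lapply(e2$truths, unclass))
  expect_identical(e1$trajectories[[2]]$frames[[5]]$coords,
                   e2$trajectories[[2]]$frames[[5]]$coords)
  expect_equal(length(e1$trajectories), 3L)
})

test_that("detector recovers generator ground truth under deterministic capture", {
  # capture fires on the first anchor head-group contact at the contact
  # threshold itself, and pinning then forces a persistent contact run, so
  # the run detector must land exactly on the true insertion snapshot
  params <- tiny_params()
  n_ok <- 0L
  for (s in 1:12) {
    cfg <- tiny_sim_config(anchored = TRUE, anchor_capture_hazard = 1,
                           anchor_capture_distance = 0.6, seed = 400 + s)
    sim <- simulate_trajectory(cfg)
    sub <- subsample_frames(sim$trajectory, cfg$timestep)
    rec <- analyze_trajectory(sub, params)
    expect_identical(rec$insertion_frame, sim$truth$true_insertion_frame)
    if (!is.na(rec$insertion_frame)) {
      n_ok <- n_ok + 1L
      expect_true(all(rec$contact_mask[rec$insertion_frame:
                                         length(rec$contact_mask)]))
    }
  }
  expect_gte(n_ok, 3L)  # the scenario actually exercises insertions
})

test_that("sim_config round-trips through YAML", {
  cfg <- tiny_sim_config(seed = 123L, anchored = FALSE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config_yaml(cfg, f)
  cfg2 <- read_sim_config_yaml(f)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
})
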