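test_that("hand-counted toy profile: residue in contact in 2 of 4 snapshots", {
  lipid <- matrix(c(5, 5, 2), 1)       # single PO4 head bead
  near <- matrix(c(5, 5, 2.3), 1)
  far <- matrix(c(5, 5, 6), 1)
  tr <- toy_trajectory(list(near, far, near, far), lipid)
  rec <- make_record(frame_times(tr), c(TRUE, FALSE, TRUE, FALSE))
  prof <- residue_contact_probability(list(tr), list(rec),
                                      phase = "after_first_contact")
  expect_equal(prof$probability, 0.5)
  expect_equal(attr(prof, "denominator"), 4L)
})

test_that("contact probabilities are restricted to head-group beads", {
  # lipid tail bead within range, head bead far: no residue contact
  lipid <- rbind(c(5, 5, 2), c(5, 5, 6))
  tr <- toy_trajectory(list(matrix(c(5, 5, 2.3), 1)), lipid,
                       lipid_names = c("C4A", "PO4"))
  rec <- make_record(frame_times(tr), TRUE)
  prof <- residue_contact_probability(list(tr), list(rec),
                                      phase = "after_first_contact")
  expect_equal(prof$probability, 0)
})

test_that("phase windows split a trajectory at the insertion event", {
  set.seed(50)
  lipid <- matrix(runif(12, 0, 8), ncol = 3)
  frames <- lapply(1:10, function(i) matrix(runif(9, 0, 8), ncol = 3))
  tr <- toy_trajectory(frames, lipid, box = c(8, 8, 8))
  rec <- make_record(frame_times(tr), rep(TRUE, 10), insertion_frame = 6L)
  rec$first_contact_frame <- 2L
  before <- residue_contact_counts(tr, rec, phase = "before_insertion")
  after <- residue_contact_counts(tr, rec, phase = "after_insertion")
  whole <- residue_contact_counts(tr, rec, phase = "after_first_contact")
  # windows [2,5] and [6,10] are disjoint and tile [first_contact, end]
  expect_equal(before$denominator, 4L)
  expect_equal(after$denominator, 5L)
  expect_equal(before$denominator + after$denominator, whole$denominator)
  expect_equal(before$counts + after$counts, whole$counts)
})

test_that("pooled profiles equal a brute-force R recomputation", {
  set.seed(51)
  box <- c(8, 8, 8)
  lipid <- matrix(runif(24, 0, 8), ncol = 3)
  lipid_names <- rep(c("PO4", "C4A"), 4)   # half heads, half tails
  trs <- list(); recs <- list()
  for (k in 1:3) {
    frames <- lapply(1:8, function(i) matrix(runif(12, 0, 8), ncol = 3))
    tr <- toy_trajectory(frames, lipid, lipid_names = lipid_names, box = box)
    rec <- make_record(frame_times(tr), rep(TRUE, 8),
                       insertion_frame = sample(1:4, 1))
    trs[[k]] <- tr; recs[[k]] <- rec
  }
  params <- analysis_params()
  prof <- residue_contact_probability(trs, recs, params, "after_insertion")
  # independent recomputation: plain R loops over residues and snapshots
  head_rows <- which(lipid_names == "PO4")
  np <- 4L
  counts <- numeric(np); denom <- 0L
  for (k in 1:3) {
    for (i in recs[[k]]$insertion_frame:8) {
      denom <- denom + 1L
      P <- trs[[k]]$frames[[i]]$coords[1:np, , drop = FALSE]
      H <- trs[[k]]$frames[[i]]$coords[np + head_rows, , drop = FALSE]
      for (r in 1:np) {
        if (oracle_min_dist(P[r, , drop = FALSE], H, box) <
            params$residue_contact_threshold)
          counts[r] <- counts[r] + 1
      }
    }
  }
  expect_equal(prof$probability, counts / denom)
  expect_equal(attr(prof, "denominator"), denom)
})

test_that("a pinned anchor residue has after-insertion probability 1", {
  cfg <- tiny_sim_config(anchored = TRUE, anchor_capture_hazard = 1,
                         anchor_capture_distance = 0.6, seed = 8,
                         n_frames = 80L)
  params <- tiny_params()
  sim <- simulate_trajectory(cfg)
  sub <- subsample_frames(sim$trajectory, cfg$timestep)
  rec <- analyze_trajectory(sub, params)
  expect_false(is.na(rec$insertion_frame))
  prof <- residue_contact_probability(list(sub), list(rec), params,
                                      "after_insertion")
  expect_equal(prof$probability[prof$residue_index == 5L], 1.0)
})

test_that("empty pooled windows raise an error rather than a zero profile", {
  lipid <- matrix(c(5, 5, 2), 1)
  tr <- toy_trajectory(list(matrix(c(5, 5, 6), 1)), lipid)
  rec <- make_record(frame_times(tr), FALSE)
  expect_error(residue_contact_probability(list(tr), list(rec),
                                           phase = "after_insertion"),
               "after_insertion")
})

test_that("high-contact selection respects the cutoff and ordering", {
  prof <- structure(
    data.frame(residue_index = 1:4,
               probability = c(0.2, 0.9, 0.6, 0.9)),
    class = c("residue_contact_profile", "data.frame"))
  all_res <- high_contact_residues(prof, 0)
  expect_equal(nrow(all_res), 4L)
  expect_equal(all_res$residue_index[1:2], c(2L, 4L))  # ties by index
  expect_equal(high_contact_residues(prof, 0.5)$residue_index, c(2, 4, 3))
  expect_equal(nrow(high_contact_residues(prof, 1 + 1e-9)), 0L)
})

# minimal fixed-column PDB with one CA atom per residue
write_toy_pdb <- function(path, resnos, bvals = 0) {
  bvals <- rep_len(bvals, length(resnos))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_along(resnos), resnos, resnos * 1.0, 0, 0, 1.0, bvals)
  writeLines(c(lines, "END"), path)
}

test_that("B-factor mapping writes 100 x probability and round-trips", {
  f_in <- withr::local_tempfile(fileext = ".pdb")
  f_out <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f_in, c(69, 70, 71))
  prof <- structure(
    data.frame(residue_index = c(70L, 71L),
               probability = c(1.0, 0.375)),
    class = c("residue_contact_profile", "data.frame"))
  n <- write_bfactor_pdb(f_in, prof, f_out)
  expect_equal(n, 2L)
  back <- bio3d::read.pdb(f_out)
  expect_equal(back$atom$b[back$atom$resno == 70], 100.00)
  expect_equal(back$atom$b[back$atom$resno == 71], 37.5, tolerance = 0.01)
  expect_equal(back$atom$b[back$atom$resno == 69], 0.00)
})

test_that("B-factor mapping with no residue overlap errors", {
  f_in <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f_in, 1:3)
  prof <- structure(
    data.frame(residue_index = 70L, probability = 1.0),
    class = c("residue_contact_profile", "data.frame"))
  expect_error(write_bfactor_pdb(f_in, prof,
                                 withr::local_tempfile(fileext = ".pdb")),
               "overlap")
})
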