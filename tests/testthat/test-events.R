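params <- analysis_params()

test_that("contact threshold is strict: 0.59 nm is contact, 0.60 is not", {
  lipid <- matrix(c(5, 5, 2), 1)
  mk <- function(dz) list(matrix(c(5, 5, 2 + dz), 1))
  tr_in <- toy_trajectory(mk(0.59), lipid)
  tr_edge <- toy_trajectory(mk(0.60), lipid)
  expect_true(contact_series(tr_in, params))
  expect_false(contact_series(tr_edge, params))
})

test_that("contact series equals per-frame brute-force recomputation", {
  set.seed(33)
  lipid <- matrix(runif(30, 0, 8), ncol = 3)
  frames <- lapply(1:20, function(i) matrix(runif(15, 0, 8), ncol = 3))
  tr <- toy_trajectory(frames, lipid, box = c(8, 8, 8))
  got <- contact_series(tr, params)
  ref <- vapply(frames, function(P)
    oracle_min_dist(P, lipid, c(8, 8, 8)) < params$contact_threshold,
    logical(1))
  expect_equal(got, ref)
})

test_that("insertion is the first snapshot of the first qualifying run", {
  p <- analysis_params(anchor_residue_index = 1L)
  # three successive anchor-contact snapshots starting at snapshot 2
  lipid <- matrix(c(5, 5, 2), 1)
  far <- matrix(c(5, 5, 6), 1)
  near <- matrix(c(5, 5, 2.3), 1)
  frames <- list(far, near, near, near, far)
  tr <- toy_trajectory(frames, lipid)
  expect_equal(detect_insertion(tr, p), 2L)
  # run of only two snapshots does not qualify
  tr2 <- toy_trajectory(list(far, near, near, far, far), lipid)
  expect_true(is.na(detect_insertion(tr2, p)))
  # run_end reporting gives the third snapshot of the run
  p_end <- analysis_params(anchor_residue_index = 1L,
                           insertion_report = "run_end")
  expect_equal(detect_insertion(tr, p_end), 4L)
})

test_that("missing anchor residue raises an error", {
  tr <- toy_trajectory(list(matrix(c(5, 5, 6), 1)), matrix(c(5, 5, 2), 1))
  expect_error(detect_insertion(tr, analysis_params(anchor_residue_index = 99L)),
               "anchor residue 99")
})

test_that("run detection agrees with exhaustive scanning on all masks", {
  # all 4096 binary masks of length 12, run lengths 1..4
  for (len in c(1L, 3L, 4L)) {
    for (code in 0:4095) {
      mask <- as.logical(bitwAnd(bitwShiftR(code, 0:11), 1L))
      got <- membanchor:::first_run_index(mask, len)
      ref <- oracle_first_run(mask, len)
      if (!identical(got, ref)) {
        fail(sprintf("mask %d run %d: got %s ref %s", code, len,
                     got, ref))
        break
      }
    }
  }
  succeed()
})

test_that("trajectory classification follows insertion then contact", {
  expect_equal(classify_trajectory(c(TRUE, TRUE), 1L), "inserted")
  expect_equal(classify_trajectory(c(TRUE, FALSE), NA_integer_),
               "contact_only")
  expect_equal(classify_trajectory(c(FALSE, FALSE), NA_integer_),
               "no_contact")
})

test_that("cumulative curve counts trajectories with a contact so far", {
  times <- seq(2, 20, by = 2)
  n <- length(times)
  mk_mask <- function(first) {
    m <- rep(FALSE, n); if (!is.na(first)) m[first] <- TRUE; m
  }
  recs <- list(make_record(times, mk_mask(1)),
               make_record(times, mk_mask(3)),
               make_record(times, mk_mask(NA)))
  cv <- ensemble_curves(recs, params)
  expect_equal(cv$cumulative_contact,
               c(1/3, 1/3, 2/3, 2/3, 2/3, 2/3, 2/3, 2/3, 2/3, 2/3))
})

test_that("a single early contact feeds the subtotal window for 10 ns", {
  times <- seq(2, 24, by = 2)
  n <- length(times)
  m <- rep(FALSE, n); m[1] <- TRUE
  cv <- ensemble_curves(list(make_record(times, m)), params)
  # contact at t=2 lies in the half-open window (t-10, t] for t = 2..10,
  # i.e. snapshots 1..5 at the 2 ns interval
  expect_equal(cv$subtotal_contact, c(rep(1, 5), rep(0, n - 5)))
})

test_that("an all-contact ensemble saturates both curves at 1", {
  times <- seq(2, 40, by = 2)
  recs <- lapply(1:4, function(i)
    make_record(times, rep(TRUE, length(times)), insertion_frame = 1L))
  cv <- ensemble_curves(recs, params)
  expect_true(all(cv$cumulative_contact == 1))
  expect_true(all(cv$subtotal_contact == 1))
  expect_true(all(cv$cumulative_inserted == 1))
})

test_that("inserted-subset normalization uses the inserted count", {
  times <- seq(2, 10, by = 2)
  m <- c(TRUE, rep(FALSE, 4))
  recs <- list(make_record(times, m, insertion_frame = 1L),
               make_record(times, m))
  cv_all <- ensemble_curves(recs, params)
  cv_sub <- ensemble_curves(recs, params, inserted_denominator = "inserted")
  expect_equal(cv_all$cumulative_inserted[5], 0.5)
  expect_equal(cv_sub$cumulative_inserted[5], 1.0)
  no_ins <- list(make_record(times, m))
  expect_error(ensemble_curves(no_ins, params,
                               inserted_denominator = "inserted"),
               "no trajectory inserted")
})

test_that("curve invariants hold on randomized ensembles", {
  set.seed(404)
  for (rep in 1:20) {
    nsnap <- sample(10:40, 1)
    times <- 2 * seq_len(nsnap)
    recs <- lapply(1:8, function(i) {
      m <- runif(nsnap) < runif(1, 0.05, 0.6)
      am <- m & (runif(nsnap) < 0.7)
      make_record(times, m, am,
                  insertion_frame = oracle_first_run(am, 3L))
    })
    cv <- ensemble_curves(recs, params)
    expect_true(all(diff(cv$cumulative_contact) >= 0))
    expect_true(all(diff(cv$cumulative_inserted) >= 0))
    expect_true(all(cv$subtotal_contact <= cv$cumulative_contact + 1e-12))
    expect_true(all(cv$cumulative_contact >= 0 & cv$cumulative_contact <= 1))
    expect_true(all(cv$subtotal_contact >= 0 & cv$subtotal_contact <= 1))
    # window covering the whole span reduces the subtotal to the cumulative
    wide <- analysis_params(subtotal_window = max(times) + 10)
    cv_wide <- ensemble_curves(recs, wide)
    expect_equal(cv_wide$subtotal_contact, cv$cumulative_contact)
  }
})

test_that("mismatched snapshot counts are rejected", {
  r1 <- make_record(c(2, 4), c(TRUE, FALSE))
  r2 <- make_record(c(2, 4, 6), c(TRUE, FALSE, FALSE))
  expect_error(ensemble_curves(list(r1, r2), params), "mismatched")
})
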