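#' Generate and analyze a synthetic ensemble one trajectory at a time
#'
#' Streams an ensemble: each trajectory is simulated, subsampled to the
#' analysis interval, event-analyzed and residue-counted, then discarded,
#' so ensembles of hundreds of trajectories fit in memory. Returns the
#' event records, ground-truth logs, and pooled residue contact counts for
#' the requested phases.
#'
#' @param config a [sim_config()].
#' @param n_trajectories ensemble size.
#' @param base_seed integer base seed (trajectory i uses `base_seed + i`).
#' @param params an [analysis_params()] object.
#' @param phases character vector of residue-profile phases to accumulate
#'   (may be empty).
#' @return list with `records`, `truths`, and `phase_counts` (a named list
#'   of per-trajectory count lists, one entry per phase).
#' @export
analyze_synthetic_ensemble <- function(config, n_trajectories, base_seed,
                                       params = analysis_params(),
                                       phases = character()) {
  records <- vector("list", n_trajectories)
  truths <- vector("list", n_trajectories)
  phase_counts <- stats::setNames(
    lapply(phases, function(p) vector("list", n_trajectories)), phases)
  for (i in seq_len(n_trajectories)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    sim <- simulate_trajectory(cfg, id = sprintf("traj_%03d", i))
    sub <- subsample_frames(sim$trajectory, params$frame_interval)
    rec <- analyze_trajectory(sub, params, id = sim$truth$trajectory_id,
                              insertable = isTRUE(config$anchored))
    records[[i]] <- rec
    truths[[i]] <- sim$truth
    for (p in phases)
      phase_counts[[p]][[i]] <- residue_contact_counts(sub, rec, params, p)
  }
  list(records = records, truths = truths, phase_counts = phase_counts)
}

#' Summarize an ensemble's event records
#'
#' @param records list of `event_record`s.
#' @param params an [analysis_params()] object (for time conversion).
#' @return list: `n`, per-classification counts, `median_first_contact_ns`,
#'   `median_insertion_ns` (inserted subset; `NA` when empty), and
#'   `irreversibility_fraction` (fraction of inserted trajectories whose
#'   every post-insertion snapshot is a contact).
#' @export
summarize_records <- function(records, params = analysis_params()) {
  cls <- vapply(records, `[[`, character(1), "classification")
  fc <- vapply(records, `[[`, integer(1), "first_contact_frame")
  ins <- vapply(records, `[[`, integer(1), "insertion_frame")
  times <- records[[1]]$times
  irr <- vapply(records, function(r) {
    if (is.na(r$insertion_frame)) return(NA)
    all(r$contact_mask[r$insertion_frame:length(r$contact_mask)])
  }, logical(1))
  n_ins <- sum(cls == "inserted")
  list(
    n = length(records),
    inserted = n_ins,
    contact_only = sum(cls == "contact_only"),
    no_contact = sum(cls == "no_contact"),
    median_first_contact_ns = if (all(is.na(fc))) NA_real_
      else stats::median(times[fc[!is.na(fc)]]),
    median_insertion_ns = if (n_ins == 0L) NA_real_
      else stats::median(times[ins[!is.na(ins)]]),
    irreversibility_fraction = if (n_ins == 0L) NA_real_
      else mean(irr[!is.na(irr)])
  )
}

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate ensembles) or `"files"` (read
#'   trajectories from disk).
#' @param params an [analysis_params()] object.
#' @param variants named list describing each system variant. In synthetic
#'   mode each entry is `list(n = <ensemble size>, config = <sim_config>)`;
#'   in files mode `list(paths = <trajectory files>, format = "gro"|"xyz",
#'   lipid_residue_names = ..., solvent_residue_names = ...)`. The default
#'   reproduces the reference three-system design: 100 anchored monomer
#'   runs, 10 non-anchored runs, 16 dimer runs.
#' @param out_dir output directory.
#' @param seed base seed.
#' @param bfactor_pdb optional PDB file to color by the anchored
#'   after-insertion profile.
#' @param high_contact_cutoff probability cut-off used when listing
#'   high-contact residues in the summary.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            params = analysis_params(),
                            variants = NULL,
                            out_dir = "membanchor_out",
                            seed = 1L,
                            bfactor_pdb = NULL,
                            high_contact_cutoff = 0.5) {
  mode <- match.arg(mode)
  if (is.null(variants)) {
    if (mode != "synthetic")
      stop("variants must be supplied in files mode")
    variants <- list(
      anchored = list(n = 100L, config = sim_config(anchored = TRUE)),
      non_anchored = list(n = 10L, config = sim_config(anchored = FALSE)),
      dimer = list(n = 16L,
                   config = sim_config(anchored = FALSE,
                                       protein_model = "dimer",
                                       box = c(11, 11, 20)))
    )
  }
  if (mode == "files") {
    for (v in variants) {
      missing <- v$paths[!file.exists(v$paths)]
      if (length(missing))
        stop("trajectory file(s) not found: ",
             paste(missing, collapse = ", "))
    }
  }
  structure(list(mode = mode, params = params, variants = variants,
                 out_dir = out_dir, seed = as.integer(seed),
                 bfactor_pdb = bfactor_pdb,
                 high_contact_cutoff = high_contact_cutoff),
            class = "pipeline_config")
}

# phases profiled per variant: anchored systems get the insertion split,
# others the after-first-contact profile
variant_phases <- function(anchored) {
  if (isTRUE(anchored)) c("after_insertion", "before_insertion")
  else "after_first_contact"
}

#' Run the end-to-end membrane-association pipeline
#'
#' For every variant: load or generate the ensemble, subsample to the
#' analysis interval, run contact/insertion analysis, build ensemble
#' curves, compute residue contact profiles (after/before insertion for
#' anchored variants; after first contact otherwise), optionally map the
#' anchored after-insertion profile onto a PDB, and write CSV/JSON outputs
#' plus a run manifest (config hash, seed, package version).
#'
#' @param config a [pipeline_config()].
#' @param verbose log per-stage progress.
#' @return invisibly, a list with per-variant summaries, curves, profiles
#'   and the manifest.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  say <- function(...) if (verbose) message(sprintf(...))
  result <- list()
  summary_all <- list()
  warnings_log <- character()

  for (vname in names(config$variants)) {
    v <- config$variants[[vname]]
    say("[%s] stage 1-3: ensemble generation/loading + event analysis",
        vname)
    if (config$mode == "synthetic") {
      anchored <- isTRUE(v$config$anchored)
      phases <- variant_phases(anchored)
      ens <- analyze_synthetic_ensemble(v$config, v$n, config$seed,
                                        params, phases)
      records <- ens$records
      say("[%s] %d trajectories x %d snapshots", vname, length(records),
          length(records[[1]]$times))
      profiles <- list()
      for (p in phases) {
        profiles[[p]] <- tryCatch(
          pool_residue_counts(ens$phase_counts[[p]], p),
          error = function(e) {
            warnings_log <<- c(warnings_log,
                               sprintf("%s/%s: %s", vname, p,
                                       conditionMessage(e)))
            NULL
          })
      }
      write_ground_truth_json(ens$truths,
        file.path(config$out_dir, paste0(vname, "_ground_truth.json")))
    } else {
      reader <- if (identical(v$format, "xyz")) read_xyz_trajectory
                else read_gro_trajectory
      trajs <- lapply(v$paths, function(p) {
        tr <- reader(p)
        tr$topology <- assign_groups(tr$topology, v$lipid_residue_names,
                                     v$solvent_residue_names %||% character())
        subsample_frames(tr, params$frame_interval)
      })
      anchored <- !is.null(v$anchored) && isTRUE(v$anchored)
      records <- Map(function(tr, i) analyze_trajectory(tr, params,
                       id = sprintf("traj_%03d", i), insertable = anchored),
                     trajs, seq_along(trajs))
      phases <- variant_phases(anchored)
      profiles <- list()
      for (p in phases) {
        profiles[[p]] <- tryCatch(
          residue_contact_probability(trajs, records, params, p),
          error = function(e) {
            warnings_log <<- c(warnings_log,
                               sprintf("%s/%s: %s", vname, p,
                                       conditionMessage(e)))
            NULL
          })
      }
    }

    say("[%s] stage 4: ensemble curves", vname)
    curves <- ensemble_curves(records, params)
    write_curves_csv(curves,
      file.path(config$out_dir, paste0(vname, "_curves.csv")))
    write_records_csv(records,
      file.path(config$out_dir, paste0(vname, "_records.csv")))

    say("[%s] stage 5: residue profiles", vname)
    for (p in names(profiles)) {
      if (is.null(profiles[[p]])) next
      write_profile_csv(profiles[[p]],
        file.path(config$out_dir, sprintf("%s_profile_%s.csv", vname, p)))
    }

    summ <- summarize_records(records, params)
    ai <- profiles[["after_insertion"]]
    if (!is.null(ai))
      summ$high_contact_residues <-
        high_contact_residues(ai, config$high_contact_cutoff)$residue_index
    summary_all[[vname]] <- summ
    result[[vname]] <- list(records = records, curves = curves,
                            profiles = profiles, summary = summ)

    if (!is.null(config$bfactor_pdb) && !is.null(ai)) {
      say("[%s] stage 6: B-factor structure mapping", vname)
      write_bfactor_pdb(config$bfactor_pdb, ai,
        file.path(config$out_dir, paste0(vname, "_bfactor.pdb")))
    }
  }

  say("writing summary + manifest")
  jsonlite::write_json(summary_all,
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  cfg_file <- file.path(config$out_dir, "pipeline_config.json")
  jsonlite::write_json(serialize_pipeline_config(config), cfg_file,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(
    package = "membanchor",
    version = as.character(utils::packageVersion("membanchor")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    snapshot_counts = lapply(result, function(r)
      length(r$records[[1]]$times)),
    partial_outputs = warnings_log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(variants = result, summary = summary_all,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain-list view of a pipeline config for hashing/serialization
serialize_pipeline_config <- function(config) {
  list(
    mode = config$mode,
    seed = config$seed,
    params = unclass(config$params),
    high_contact_cutoff = config$high_contact_cutoff,
    variants = lapply(config$variants, function(v) {
      out <- v
      if (!is.null(out$config)) out$config <- unclass(out$config)
      out
    })
  )
}
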