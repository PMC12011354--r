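#' Read and validate a run configuration
#'
#' Loads a YAML or JSON run configuration, fills documented defaults,
#' and validates it. Unknown top-level keys are rejected (they are
#' almost always typos). The resolved configuration (defaults filled) is
#' written next to the outputs by [run_pipeline()] so a run can be
#' reproduced exactly.
#'
#' Top-level keys: `data_dir`, `file_pattern`, `stage_dialect`, `module`
#' (one of `hypnogram`, `spectra`, `power-hilbert`, `tfr`, `spindles`,
#' `envelope-compare`, `simulate`), `out_dir`, `seed`, `downsample_to`,
#' `montage`, `reref` (`scheme`, `channels`), `bad_channels` (named by
#' participant), `hook` (path to an R file defining a function `hook`),
#' `bands` (per-band: `low_hz`, `high_hz`, `design`, `stages`,
#' `artifact_threshold_uv`), `stage_time_limit_min`, `chrono_window_s`,
#' `module_params`, `simulate` (generator settings), `groups` (for
#' envelope-compare: two named participant lists), `strict`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file, or a
#'   list with the same structure.
#' @return A validated `run_config` list with defaults filled.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("data_dir", "file_pattern", "stage_dialect", "module",
             "out_dir", "seed", "downsample_to", "montage", "reref",
             "bad_channels", "hook", "bands", "stage_time_limit_min",
             "chrono_window_s", "module_params", "simulate", "groups",
             "strict")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(file_pattern = "\\.edf$", stage_dialect = "generic_csv",
                   seed = 1L, downsample_to = NULL,
                   montage = "standard_1020",
                   reref = list(scheme = "none", channels = NULL),
                   bad_channels = list(), hook = NULL,
                   bands = NULL, stage_time_limit_min = NULL,
                   chrono_window_s = NULL, module_params = list(),
                   simulate = list(), groups = NULL, strict = FALSE)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  }
  problems <- character()
  modules <- c("hypnogram", "spectra", "power-hilbert", "tfr", "spindles",
               "envelope-compare", "simulate")
  if (is.null(cfg$module) || !cfg$module %in% modules) {
    problems <- c(problems, paste0("module must be one of ",
                                   paste(modules, collapse = ", ")))
  }
  if (is.null(cfg$out_dir)) problems <- c(problems, "out_dir is required")
  if (!identical(cfg$module, "simulate") &&
      !identical(cfg$module, "envelope-compare") &&
      is.null(cfg$data_dir)) {
    problems <- c(problems, "data_dir is required")
  }
  if (!cfg$stage_dialect %in% names(.stage_dialects)) {
    problems <- c(problems, paste0("unknown stage_dialect: ",
                                   cfg$stage_dialect))
  }
  if (length(problems)) {
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  if (is.null(cfg$bands)) {
    cfg$bands <- list(
      delta = list(low_hz = 0.5, high_hz = 4, design = "butterworth",
                   stages = c("N2", "N3"), artifact_threshold_uv = NULL),
      sigma = list(low_hz = 12, high_hz = 16, design = "butterworth",
                   stages = c("N2", "N3"), artifact_threshold_uv = NULL))
  }
  class(cfg) <- "run_config"
  cfg
}

.cfg_band_spec <- function(name, b) {
  band_spec(name, b$low_hz, b$high_hz,
            design = if (is.null(b$design)) "butterworth" else b$design,
            artifact_threshold_uv = b$artifact_threshold_uv)
}

#' Run the analysis pipeline over a directory of participants
#'
#' Mirrors the interactive tool's flow: each participant's recording
#' passes once through the common preprocessing chain (import,
#' downsample, stage-marker embedding, montage, custom hook,
#' re-reference, ICA slot, bad-channel interpolation), then the filter →
#' stage-time restriction → module-analysis trio runs once per requested
#' band. A failing participant is logged and skipped unless
#' `strict = TRUE`. After all participants, the module's group-level
#' step (e.g. group-averaged spectra) runs if one is defined. The
#' resolved configuration is written next to the outputs.
#'
#' @param config A `run_config`, or a path accepted by
#'   [read_run_config()].
#' @return Invisibly, a list: `participants` (per-participant status),
#'   `log` (data frame participant/band/step/seconds), `outputs`
#'   (written file paths).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir,
                                           "resolved_config.yaml"))
  log <- list()
  outputs <- character()
  log_step <- function(participant, band, step, secs) {
    log[[length(log) + 1L]] <<- data.frame(
      participant = participant, band = band, step = step,
      seconds = round(secs, 3), stringsAsFactors = FALSE)
  }
  if (identical(cfg$module, "simulate")) {
    outputs <- simulate_participants(cfg)
    log_step("-", "-", "simulate", 0)
    return(invisible(list(participants = NULL, log = do.call(rbind, log),
                          outputs = outputs)))
  }
  if (identical(cfg$module, "envelope-compare")) {
    return(invisible(.run_envelope_compare(cfg)))
  }
  edfs <- sort(list.files(cfg$data_dir, pattern = cfg$file_pattern,
                          full.names = TRUE))
  if (length(edfs) == 0L) {
    stop("no recordings match pattern '", cfg$file_pattern, "' in ",
         cfg$data_dir, call. = FALSE)
  }
  statuses <- list()
  results <- list()
  for (edf in edfs) {
    pid <- sub("\\.edf$", "", basename(edf), ignore.case = TRUE)
    res <- tryCatch({
      t0 <- proc.time()[3]
      pp <- .common_preprocess(edf, pid, cfg)
      log_step(pid, "-", "preprocess", proc.time()[3] - t0)
      per_band <- list()
      for (bname in names(cfg$bands)) {
        t0 <- proc.time()[3]
        per_band[[bname]] <- .run_band_module(pp, bname, cfg, pid)
        outputs <- c(outputs, per_band[[bname]]$files)
        log_step(pid, bname, paste0("module:", cfg$module),
                 proc.time()[3] - t0)
      }
      list(ok = TRUE, bands = per_band, marked = pp$marked)
    }, error = function(e) {
      log_step(pid, "-", paste0("error:", conditionMessage(e)), 0)
      if (isTRUE(cfg$strict)) stop(e)
      list(ok = FALSE, error = conditionMessage(e))
    })
    statuses[[pid]] <- res$ok
    results[[pid]] <- res
  }
  # group-level step
  if (identical(cfg$module, "spectra")) {
    for (bname in names(cfg$bands)) {
      specs <- lapply(Filter(function(r) isTRUE(r$ok), results),
                      function(r) r$bands[[bname]]$result)
      specs <- Filter(Negate(is.null), specs)
      if (length(specs) >= 1L) {
        ga <- group_average_spectra(specs)
        p <- file.path(cfg$out_dir, paste0("group_spectra_", bname,
                                           ".csv"))
        write_spectrum_csv(ga, p)
        outputs <- c(outputs, p)
        log_step("-", bname, "group:spectra", 0)
      }
    }
  }
  invisible(list(participants = statuses, log = do.call(rbind, log),
                 outputs = outputs))
}

.common_preprocess <- function(edf, pid, cfg) {
  rec <- read_edf(edf)
  if (!is.null(cfg$downsample_to)) {
    rec <- downsample(rec, cfg$downsample_to)
  } else {
    rec <- add_provenance(rec, "downsample[skip]")
  }
  hyp_path <- .find_hypnogram(edf, cfg$stage_dialect)
  hyp <- parse_hypnogram(hyp_path, cfg$stage_dialect)
  marked <- embed_stage_markers(rec, hyp)
  rec <- marked$recording
  rec <- attach_montage(rec, cfg$montage)
  if (!is.null(cfg$hook)) {
    env <- new.env()
    sys.source(cfg$hook, env)
    if (!is.function(env$hook)) {
      stop("hook file must define a function named 'hook'", call. = FALSE)
    }
    rec <- run_custom_hook(rec, env$hook, hook_name = basename(cfg$hook))
  } else {
    rec <- add_provenance(rec, "custom_hook[skip]")
  }
  rec <- rereference(rec, cfg$reref$scheme,
                     channels = cfg$reref$channels)
  rec <- ica_slot(rec)
  bad <- cfg$bad_channels[[pid]]
  if (!is.null(bad) && length(bad)) {
    rec <- interpolate_bad_channels(rec, bad)
  } else {
    rec <- add_provenance(rec, "bci[skip]")
  }
  marked$recording <- rec
  list(recording = rec, marked = marked, hypnogram = hyp, pid = pid)
}

.find_hypnogram <- function(edf, dialect) {
  base <- sub("\\.edf$", "", edf, ignore.case = TRUE)
  suffix <- switch(dialect, generic_csv = "_stages.csv",
                   hume_csv = "_hume.csv", remlogic_txt = "_remlogic.txt",
                   twin_txt = "_twin.txt")
  p <- paste0(base, suffix)
  if (!file.exists(p)) {
    stop("stage notation file not found: ", p, call. = FALSE)
  }
  p
}

.run_band_module <- function(pp, bname, cfg, pid) {
  bcfg <- cfg$bands[[bname]]
  bspec <- .cfg_band_spec(bname, bcfg)
  mp <- cfg$module_params
  out_dir <- file.path(cfg$out_dir, pid)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (is.null(bcfg$stages)) c("N2", "N3") else
    unlist(bcfg$stages)
  sel <- stage_selection(stages,
                         stage_time_limit_min = cfg$stage_time_limit_min,
                         chrono_window_s = cfg$chrono_window_s)
  files <- character()
  result <- NULL
  if (identical(cfg$module, "hypnogram")) {
    # stage-only module: the band table is irrelevant; run once
    if (bname == names(cfg$bands)[1L]) {
      s <- hypnogram_summary(pp$hypnogram)
      p_csv <- file.path(out_dir, "hypnogram_summary.csv")
      write.csv(data.frame(measure = c(paste0("min_", names(s$stage_minutes)),
                                       "total_sleep_min",
                                       "sleep_onset_latency_min",
                                       "waso_min"),
                           value = c(unname(s$stage_minutes),
                                     s$total_sleep_min,
                                     s$sleep_onset_latency_min,
                                     s$waso_min)),
                p_csv, row.names = FALSE)
      p_fig <- file.path(out_dir, "hypnogram.png")
      plot_hypnogram(pp$hypnogram, p_fig)
      files <- c(p_csv, p_fig)
    }
    return(list(files = files, result = NULL))
  }
  filtered <- bandpass(pp$recording, bspec)
  mask <- NULL
  if (!is.null(bcfg$artifact_threshold_uv)) {
    marked_f <- pp$marked
    marked_f$recording <- filtered
    mask <- detect_artifacts(filtered, marked_f,
                             bcfg$artifact_threshold_uv)
    p_mask <- file.path(out_dir, paste0("artifacts_", bname, ".csv"))
    write_artifact_csv(mask, p_mask)
    files <- c(files, p_mask)
  }
  marked_band <- pp$marked
  marked_band$recording <- filtered
  segset <- select_stage_time(marked_band, sel, artifact_mask = mask)
  p_prov <- file.path(out_dir, paste0("provenance_", bname, ".txt"))
  writeLines(segset$concatenated$provenance, p_prov)
  files <- c(files, p_prov)
  if (identical(cfg$module, "spectra")) {
    win <- if (is.null(mp$window_s)) 5 else mp$window_s
    ov <- if (is.null(mp$overlap_frac)) 0.5 else mp$overlap_frac
    result <- amplitude_spectrum(segset, window_s = win,
                                 overlap_frac = ov)
    p <- file.path(out_dir, paste0("spectrum_", bname, ".csv"))
    write_spectrum_csv(result, p)
    files <- c(files, p)
  } else if (identical(cfg$module, "power-hilbert")) {
    env <- hilbert_envelope(filtered, hyp = pp$hypnogram, band = bspec)
    p <- file.path(out_dir, paste0("envelope_", bname, ".psgk"))
    save_container(env, p)
    su <- envelope_summary(env, sel)
    p2 <- file.path(out_dir, paste0("envelope_", bname, "_summary.csv"))
    write.csv(su$summary, p2, row.names = FALSE)
    files <- c(files, p, p2)
    result <- env
  } else if (identical(cfg$module, "tfr")) {
    result <- morlet_tfr(segset$concatenated)
    p <- file.path(out_dir, paste0("tfr_", bname, ".psgk"))
    save_container(result, p)
    files <- c(files, p)
  } else if (identical(cfg$module, "spindles")) {
    params <- spindle_params(
      sigma_band = bspec,
      lower_mult = if (is.null(mp$lower_mult)) 2 else mp$lower_mult,
      upper_mult = if (is.null(mp$upper_mult)) 6 else mp$upper_mult,
      stages = stages)
    marked_raw <- pp$marked
    events <- detect_spindles(pp$recording, marked_raw, params,
                              artifact_mask = mask)
    p <- file.path(out_dir, paste0("spindles_", bname, ".csv"))
    write_spindles_csv(events, p)
    dens <- spindle_density(events, pp$hypnogram, stages = stages)
    p2 <- file.path(out_dir, paste0("spindle_density_", bname, ".csv"))
    write.csv(dens, p2, row.names = FALSE)
    files <- c(files, p, p2)
    result <- events
  }
  list(files = files, result = result)
}

# envelope-compare consumes prior power-hilbert outputs: the common
# preprocessing already happened on that run, so it is skipped here.
.run_envelope_compare <- function(cfg) {
  if (is.null(cfg$groups) || length(cfg$groups) != 2L) {
    stop("envelope-compare needs config 'groups' with two participant lists",
         call. = FALSE)
  }
  band <- if (length(cfg$module_params$band)) cfg$module_params$band else
    names(cfg$bands)[1L]
  sel_stages <- cfg$bands[[band]]$stages
  if (is.null(sel_stages)) sel_stages <- c("N2", "N3")
  sel <- stage_selection(unlist(sel_stages),
                         stage_time_limit_min = cfg$stage_time_limit_min)
  load_group <- function(pids) {
    rows <- lapply(pids, function(pid) {
      p <- file.path(cfg$out_dir, pid, paste0("envelope_", band, ".psgk"))
      if (!file.exists(p)) stop("missing power-hilbert output: ", p,
                                call. = FALSE)
      env <- load_container(p)
      su <- envelope_summary(env, sel)
      chans <- su$summary[su$summary$kind == "channel", ]
      setNames(chans$mean_uv, chans$name)
    })
    do.call(rbind, rows)
  }
  ga <- load_group(unlist(cfg$groups[[1L]]))
  gb <- load_group(unlist(cfg$groups[[2L]]))
  mon <- standard_montage(cfg$montage)
  pos <- mon$coordinates[match(toupper(colnames(ga)),
                               toupper(rownames(mon$coordinates))), ,
                         drop = FALSE]
  rownames(pos) <- colnames(ga)
  adj <- channel_adjacency(pos)
  n_perm <- if (is.null(cfg$module_params$n_perm)) 1000 else
    cfg$module_params$n_perm
  res <- cluster_permutation(ga, gb, adj, n_perm = n_perm,
                             seed = cfg$seed)
  p <- file.path(cfg$out_dir, paste0("envelope_compare_", band, ".csv"))
  write_cluster_csv(res, p)
  list(participants = NULL, result = res, outputs = p,
       log = data.frame(participant = "-", band = band,
                        step = "module:envelope-compare", seconds = 0))
}

#' Generate synthetic participants on disk
#'
#' Writes `n_participants` synthetic recordings (EDF), hypnograms in
#' every requested dialect, and per-participant ground-truth manifests.
#' Per-participant seeds are derived deterministically from the
#' top-level seed, so the same config reproduces identical files.
#'
#' @param cfg A `run_config` whose `simulate` entry may set
#'   `n_participants` (default 2), `dialects` (default all four),
#'   `fs`, `noise_sd`, `n_spindles`, and `spindle_channels`.
#' @return Character vector of written paths.
#' @export
simulate_participants <- function(cfg) {
  sim <- cfg$simulate
  n_p <- if (is.null(sim$n_participants)) 2L else sim$n_participants
  dialects <- if (is.null(sim$dialects)) names(.stage_dialects) else
    unlist(sim$dialects)
  out <- character()
  for (i in seq_len(n_p)) {
    seed_i <- (as.integer(cfg$seed) * 1009L + i) %% 2147483647L
    args <- list(seed = seed_i)
    if (!is.null(sim$fs)) args$fs <- sim$fs
    if (!is.null(sim$noise_sd)) args$noise_sd <- sim$noise_sd
    spec0 <- do.call(synth_spec, args)
    if (!is.null(sim$n_spindles) && sim$n_spindles > 0) {
      chans <- if (is.null(sim$spindle_channels)) {
        spec0$channel_labels
      } else unlist(sim$spindle_channels)
      args$spindle_events <- place_spindle_events(
        spec0$hypnogram, sim$n_spindles, chans)
      spec0 <- do.call(synth_spec, args)
    }
    gen <- generate_recording(spec0)
    pid <- sprintf("synth%02d", i)
    for (d in dialects) {
      paths <- write_fixture(gen$recording, gen$truth$hypnogram, d,
                             cfg$out_dir, basename = pid,
                             truth = if (d == dialects[1L]) gen$truth)
      out <- c(out, paths)
    }
  }
  unique(out)
}
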