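#' Specification for a synthetic polysomnography recording
#'
#' Defines a ground-truthed synthetic night: a stage plan (ordered runs
#' of 30-s epochs), per-stage narrowband amplitudes (sinusoids at each
#' band's center frequency with a random per-channel phase), white
#' Gaussian background noise, and optional injected sigma-band spindle
#' bursts with known onsets.
#'
#' Spindle bursts are Hann-tapered sinusoids at the sigma band's center
#' frequency, injected in phase with the channel's ongoing sigma
#' background so that the burst's rectified peak equals
#' `peak_multiplier` x the channel's baseline mean rectified sigma
#' amplitude (the mean over the pre-injection signal's N2/N3 epochs) —
#' the ground truth is therefore independent of any detector.
#'
#' @param stage_plan Data frame `stage`, `n_epochs` (ordered runs).
#' @param fs Sampling rate in Hz (integer; must exceed twice the highest
#'   band edge).
#' @param channel_labels Channel names (10-20 montage labels).
#' @param band_amplitudes Named list: stage -> named numeric vector of
#'   per-band sinusoid amplitudes in uV. Band names must exist in
#'   `bands`.
#' @param bands Named list of [band_spec()] giving each band's edges
#'   (default [default_bands()]).
#' @param spindle_events Data frame `channel`, `onset_s`, `duration_s`,
#'   `peak_multiplier` (possibly empty). Every event must lie wholly
#'   inside N2 or N3 epochs.
#' @param noise_sd White-noise SD in uV.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A `synth_spec` object (duration is implied by the plan:
#'   30 s x total epochs).
#' @export
synth_spec <- function(stage_plan = default_stage_plan(),
                       fs = 128,
                       channel_labels = c("F3", "F4", "C3", "C4",
                                          "O1", "O2"),
                       band_amplitudes = default_band_amplitudes(),
                       bands = default_bands(),
                       spindle_events = NULL,
                       noise_sd = 5,
                       seed = 1) {
  plan <- as.data.frame(stage_plan, stringsAsFactors = FALSE)
  stopifnot(nrow(plan) > 0, all(c("stage", "n_epochs") %in% names(plan)))
  bad <- setdiff(unique(plan$stage), stage_levels())
  if (length(bad)) stop("unknown stage(s) in plan: ",
                        paste(bad, collapse = ","), call. = FALSE)
  hi_edge <- max(vapply(bands, `[[`, numeric(1), "high_hz"))
  if (fs <= 2 * hi_edge) {
    stop(sprintf("fs = %g Hz must exceed twice the highest band edge (%g Hz)",
                 fs, hi_edge), call. = FALSE)
  }
  for (st in names(band_amplitudes)) {
    unknown <- setdiff(names(band_amplitudes[[st]]), names(bands))
    if (length(unknown)) {
      stop("band_amplitudes names unknown band(s): ",
           paste(unknown, collapse = ","), call. = FALSE)
    }
  }
  hyp <- generate_hypnogram(plan)
  dur <- nrow(hyp) * epoch_length(hyp)
  if (is.null(spindle_events)) {
    spindle_events <- data.frame(channel = character(),
                                 onset_s = numeric(),
                                 duration_s = numeric(),
                                 peak_multiplier = numeric())
  }
  if (nrow(spindle_events)) {
    stopifnot(all(c("channel", "onset_s", "duration_s",
                    "peak_multiplier") %in% names(spindle_events)))
    if (any(!spindle_events$channel %in% channel_labels)) {
      stop("spindle event on unknown channel", call. = FALSE)
    }
    if (any(spindle_events$onset_s < 0 |
            spindle_events$onset_s + spindle_events$duration_s > dur)) {
      stop("spindle event outside the recording", call. = FALSE)
    }
    el <- epoch_length(hyp)
    for (i in seq_len(nrow(spindle_events))) {
      e0 <- floor(spindle_events$onset_s[i] / el)
      e1 <- ceiling((spindle_events$onset_s[i] +
                       spindle_events$duration_s[i]) / el) - 1
      if (!all(hyp$stage[(e0:e1) + 1L] %in% c("N2", "N3"))) {
        stop(sprintf("spindle event %d not wholly inside N2/N3 epochs", i),
             call. = FALSE)
      }
    }
  }
  structure(list(stage_plan = plan, fs = fs,
                 channel_labels = channel_labels,
                 band_amplitudes = band_amplitudes, bands = bands,
                 spindle_events = spindle_events, noise_sd = noise_sd,
                 seed = as.integer(seed), hypnogram = hyp,
                 duration_s = dur),
            class = "synth_spec")
}

#' Default synthetic night structure
#'
#' A compact one-hour night: wake and N1 at lights-off, a long first
#' NREM period (60 N2 + 30 N3 epochs, so stage-time restrictions up to
#' 45 min of N2/N3 are satisfiable), a REM period, and final wake.
#'
#' @return Data frame `stage`, `n_epochs` (120 epochs = 3600 s).
#' @export
default_stage_plan <- function() {
  data.frame(stage = c("W", "N1", "N2", "N3", "N2", "REM", "W"),
             n_epochs = c(4L, 6L, 40L, 30L, 20L, 16L, 4L),
             stringsAsFactors = FALSE)
}

#' Default stage-dependent band amplitudes
#'
#' Emulates the canonical sleep EEG pattern: delta amplitude highest in
#' N3 (slow waves), sigma amplitude highest in N2 (spindle-band
#' activity), modest theta throughout sleep.
#'
#' @return Named list stage -> named numeric vector (uV).
#' @export
default_band_amplitudes <- function() {
  list(W = c(delta = 5, theta = 4, sigma = 2),
       N1 = c(delta = 10, theta = 6, sigma = 3),
       N2 = c(delta = 15, theta = 6, sigma = 12),
       N3 = c(delta = 40, theta = 8, sigma = 10),
       REM = c(delta = 8, theta = 5, sigma = 2))
}

#' Generate a synthetic recording with ground truth
#'
#' Builds the signal as white Gaussian noise plus per-stage band
#' sinusoids (amplitude switching at epoch boundaries, phase continuous
#' across the night, one random phase per channel x band) plus the
#' injected spindle bursts, and returns the ground truth alongside.
#'
#' @param spec A [synth_spec()].
#' @return List with `recording` (a `psg_recording`) and `truth` (list:
#'   `hypnogram`, `spindle_events` with realized amplitudes,
#'   `band_amplitudes`, `baseline_uv` per channel).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  hyp <- spec$hypnogram
  fs <- spec$fs
  n <- as.integer(spec$duration_s * fs)
  n_ch <- length(spec$channel_labels)
  band_names <- names(spec$bands)
  phases <- matrix(runif(n_ch * length(band_names), 0, 2 * pi),
                   nrow = n_ch, dimnames = list(spec$channel_labels,
                                                band_names))
  data <- matrix(rnorm(n_ch * n, sd = spec$noise_sd), nrow = n_ch,
                 dimnames = list(spec$channel_labels, NULL))
  t <- (seq_len(n) - 1) / fs
  # per-sample stage lookup
  eps <- .epoch_samples(hyp, fs, n)
  stage_of <- character(n)
  for (i in seq_len(nrow(eps))) {
    stage_of[(eps$start[i] + 1L):eps$end[i]] <- eps$stage[i]
  }
  centers <- vapply(spec$bands,
                    function(b) (b$low_hz + b$high_hz) / 2, numeric(1))
  # amplitude profile per band over time (stepwise per epoch)
  for (b in band_names) {
    amp_of_stage <- vapply(stage_levels(), function(st) {
      a <- spec$band_amplitudes[[st]]
      if (is.null(a) || is.na(a[b]) || !b %in% names(a)) 0 else a[[b]]
    }, numeric(1))
    amp_t <- amp_of_stage[stage_of]
    if (all(amp_t == 0)) next
    for (ch in seq_len(n_ch)) {
      data[ch, ] <- data[ch, ] +
        amp_t * sin(2 * pi * centers[[b]] * t + phases[ch, b])
    }
  }
  # baseline: mean rectified sigma-filtered amplitude of the
  # pre-injection signal over N2/N3 epochs, per channel
  rec0 <- new_recording(data, fs, spec$channel_labels,
                        provenance = "import[synthetic]")
  truth_events <- spec$spindle_events
  baseline <- rep(NA_real_, n_ch)
  names(baseline) <- spec$channel_labels
  if ("sigma" %in% band_names) {
    sig <- bandpass(rec0, spec$bands$sigma)
    base_idx <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                              eps$start[eps$stage %in% c("N2", "N3")],
                              eps$end[eps$stage %in% c("N2", "N3")],
                              SIMPLIFY = FALSE))
    if (length(base_idx)) {
      baseline <- apply(abs(sig$data[, base_idx, drop = FALSE]), 1, mean)
    }
  }
  if (nrow(truth_events)) {
    f_sigma <- centers[["sigma"]]
    truth_events$baseline_uv <- NA_real_
    truth_events$peak_amplitude_uv <- NA_real_
    for (i in seq_len(nrow(truth_events))) {
      ch <- match(truth_events$channel[i], spec$channel_labels)
      i0 <- as.integer(round(truth_events$onset_s[i] * fs)) + 1L
      len <- as.integer(round(truth_events$duration_s[i] * fs))
      stage_here <- stage_of[i0]
      a_bg <- spec$band_amplitudes[[stage_here]]
      a_bg <- if (!is.null(a_bg) && "sigma" %in% names(a_bg)) {
        a_bg[["sigma"]]
      } else 0
      target <- truth_events$peak_multiplier[i] * baseline[ch]
      a_burst <- target - a_bg
      if (!is.finite(a_burst) || a_burst <= 0) {
        stop(sprintf(
          "spindle event %d: peak %.3g uV does not exceed the sigma background %.3g uV",
          i, target, a_bg), call. = FALSE)
      }
      k <- seq_len(len)
      hann <- 0.5 * (1 - cos(2 * pi * (k - 1) / (len - 1)))
      tt <- t[i0 + k - 1L]
      data[ch, i0 + k - 1L] <- data[ch, i0 + k - 1L] +
        a_burst * hann * sin(2 * pi * f_sigma * tt +
                               phases[ch, "sigma"])
      truth_events$baseline_uv[i] <- baseline[ch]
      truth_events$peak_amplitude_uv[i] <- target
    }
  }
  recording <- new_recording(data, fs, spec$channel_labels,
                             provenance = "import[synthetic]")
  list(recording = recording,
       truth = list(hypnogram = hyp, spindle_events = truth_events,
                    band_amplitudes = spec$band_amplitudes,
                    baseline_uv = baseline))
}

#' Place spindle events deterministically inside N2/N3 epochs
#'
#' Utility for building ground-truth event tables: picks every
#' `stride`-th N2/N3 epoch (skipping the first epoch of each stage run so
#' bursts sit inside stable-stage data) and centers one burst in it,
#' cycling through the given channels.
#'
#' @param hyp A [hypnogram].
#' @param n Number of events.
#' @param channels Channels to cycle through.
#' @param duration_s Burst duration (default 1 s).
#' @param peak_multiplier Peak as a multiple of the sigma baseline.
#' @param stride Epoch stride between events (default 2).
#' @return Data frame `channel`, `onset_s`, `duration_s`,
#'   `peak_multiplier`.
#' @export
place_spindle_events <- function(hyp, n, channels, duration_s = 1,
                                 peak_multiplier = 7, stride = 2L) {
  el <- epoch_length(hyp)
  ok <- which(hyp$stage %in% c("N2", "N3"))
  run_start <- c(TRUE, diff(ok) != 1L)
  ok <- ok[!run_start]
  picks <- ok[seq(1L, by = stride, length.out = n)]
  if (anyNA(picks)) {
    stop("not enough N2/N3 epochs for ", n, " events", call. = FALSE)
  }
  data.frame(channel = rep_len(channels, n),
             onset_s = hyp$onset_s[picks] + (el - duration_s) / 2,
             duration_s = duration_s,
             peak_multiplier = peak_multiplier,
             stringsAsFactors = FALSE)
}

#' Write a synthetic fixture to disk
#'
#' Writes the recording as EDF, the hypnogram in the requested dialect,
#' and (optionally) a JSON sidecar manifest of the ground-truth events;
#' the written pair round-trips through [read_edf()] /
#' [parse_hypnogram()] up to EDF 16-bit quantization.
#'
#' @param recording A `psg_recording`.
#' @param hyp The matching [hypnogram].
#' @param dialect Hypnogram dialect to write.
#' @param out_dir Output directory (created if needed).
#' @param basename File basename (default `"participant"`).
#' @param truth Optional truth list from [generate_recording()], written
#'   as `<basename>_truth.json`.
#' @return Named character vector of written paths.
#' @export
write_fixture <- function(recording, hyp, dialect, out_dir,
                          basename = "participant", truth = NULL) {
  dialect <- match.arg(dialect, names(.stage_dialects))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- switch(dialect, generic_csv = "_stages.csv",
                hume_csv = "_hume.csv", remlogic_txt = "_remlogic.txt",
                twin_txt = "_twin.txt")
  edf_path <- file.path(out_dir, paste0(basename, ".edf"))
  hyp_path <- file.path(out_dir, paste0(basename, ext))
  write_edf(recording, edf_path)
  write_hypnogram(hyp, hyp_path, dialect,
                  start_time = recording$start_time)
  paths <- c(edf = edf_path, hypnogram = hyp_path)
  if (!is.null(truth)) {
    tpath <- file.path(out_dir, paste0(basename, "_truth.json"))
    jsonlite::write_json(
      list(spindle_events = truth$spindle_events,
           baseline_uv = as.list(truth$baseline_uv),
           stage_plan = as.data.frame(table(truth$hypnogram$stage))),
      tpath, auto_unbox = TRUE, digits = NA)
    paths["truth"] <- tpath
  }
  paths
}
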