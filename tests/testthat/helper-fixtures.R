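# Fixtures are generated in code; the synthetic night is cached because
# several test files share it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# The canonical synthetic night with 20 true spindles (peak 7x baseline)
# and 20 distractor bursts (peak 3x baseline) on C3/C4, plus its truth.
night_with_spindles <- function() {
  cached("night_spindles", {
    spec0 <- synth_spec(seed = 11)
    sp <- place_spindle_events(spec0$hypnogram, 20, c("C3", "C4"),
                               peak_multiplier = 7, stride = 2)
    di <- place_spindle_events(spec0$hypnogram, 20, c("C3", "C4"),
                               peak_multiplier = 3, stride = 2)
    di$onset_s <- di$onset_s + 30  # shifted one epoch: no collisions
    spec <- synth_spec(spindle_events = rbind(sp, di), seed = 11)
    gen <- generate_recording(spec)
    gen$true_events <- sp
    gen$distractors <- di
    gen$marked <- embed_stage_markers(gen$recording, gen$truth$hypnogram)
    gen
  })
}

# A plain (no-spindle) night for spectral/envelope tests.
night_plain <- function() {
  cached("night_plain", {
    gen <- generate_recording(synth_spec(seed = 21))
    gen$marked <- embed_stage_markers(gen$recording, gen$truth$hypnogram)
    gen
  })
}

# A small simulated two-participant cohort shared by the pipeline tests.
sim_cohort <- function() {
  cached("sim_cohort", {
    base <- file.path(tempdir(), "psgkit-sim-cohort")
    data_dir <- file.path(base, "data")
    cfg <- read_run_config(list(
      module = "simulate", out_dir = data_dir, seed = 5,
      simulate = list(n_participants = 2, dialects = "generic_csv",
                      n_spindles = 10,
                      spindle_channels = c("C3", "C4"))))
    run_pipeline(cfg)
    data_dir
  })
}

# Single-channel pure-tone recording.
tone_recording <- function(freq_hz, amplitude = 1, fs = 128,
                           dur_s = 120, channel = "C3") {
  t <- (seq_len(fs * dur_s) - 1) / fs
  new_recording(rbind(amplitude * sin(2 * pi * freq_hz * t)), fs, channel)
}

# Random hypnogram for round-trip / mask property tests.
random_hypnogram <- function(n_epochs = NULL) {
  if (is.null(n_epochs)) n_epochs <- sample(3:40, 1)
  hypnogram(sample(stage_levels(), n_epochs, replace = TRUE))
}

# Brute-force per-sample mask oracle for the stage-time restriction: a
# sample survives iff its epoch's stage is selected (and inside the
# chrono window), and, under a stage-time limit, iff the running count
# of surviving samples has not passed the limit.
oracle_stage_mask <- function(hyp, selection, fs, n_total) {
  el <- epoch_length(hyp)
  mask <- logical(n_total)
  for (i in seq_len(nrow(hyp))) {
    s0 <- round(hyp$onset_s[i] * fs)
    s1 <- min(round((hyp$onset_s[i] + el) * fs), n_total)
    if (s1 <= s0) next
    ok <- hyp$stage[i] %in% selection$stages
    if (ok && !is.null(selection$chrono_window_s)) {
      w <- selection$chrono_window_s
      ok <- hyp$onset_s[i] >= w[1] && (hyp$onset_s[i] + el) <= w[2]
    }
    if (ok) mask[(s0 + 1):s1] <- TRUE
  }
  if (!is.null(selection$stage_time_limit_min)) {
    lim <- round(selection$stage_time_limit_min * 60 * fs)
    mask[cumsum(mask) > lim] <- FALSE
  }
  mask
}

# Independent re-implementation of the dual-threshold spindle detector
# for one channel (plain loops, own filter call), used as the
# threshold-crossing oracle.
oracle_spindles_channel <- function(recording, hyp, channel,
                                    lower_mult = 2, upper_mult = 6,
                                    min_dur_s = 0.5, max_dur_s = 3,
                                    stages = c("N2", "N3")) {
  fs <- recording$fs
  i <- match(channel, recording$channel_labels)
  flt <- signal::butter(4, c(12, 16) / (fs / 2), type = "pass")
  x <- abs(signal::filtfilt(flt, recording$data[i, ]))
  n <- length(x)
  is_pk <- logical(n)
  is_pk[1L] <- is_pk[n] <- TRUE
  for (k in 2:(n - 1)) {
    is_pk[k] <- x[k] >= x[k - 1] && x[k] > x[k + 1]
  }
  peaks <- which(is_pk)
  env <- approx(peaks, x[peaks], xout = seq_len(n))$y
  el <- epoch_length(hyp)
  in_sel <- logical(n)
  for (e in seq_len(nrow(hyp))) {
    if (hyp$stage[e] %in% stages) {
      s0 <- round(hyp$onset_s[e] * fs)
      s1 <- min(round((hyp$onset_s[e] + el) * fs), n)
      if (s1 > s0) in_sel[(s0 + 1):s1] <- TRUE
    }
  }
  baseline <- mean(x[in_sel])
  above <- env > lower_mult * baseline
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  out <- NULL
  for (r in seq_along(starts)) {
    dur <- (ends[r] - starts[r] + 1) / fs
    if (dur < min_dur_s || dur > max_dur_s) next
    if (max(env[starts[r]:ends[r]]) <= upper_mult * baseline) next
    if (!any(in_sel[starts[r]:ends[r]])) next
    out <- rbind(out, data.frame(onset_sample = starts[r] - 1L,
                                 offset_sample = ends[r] - 1L))
  }
  out
}

# Minimal BrainVision triplet writer (test fixture only).
write_bv_fixture <- function(dir, data, fs, labels,
                             format = "INT_16",
                             orientation = "MULTIPLEXED",
                             resolutions = rep(1, nrow(data)),
                             units = rep("µV", nrow(data)),
                             base = "fix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eeg <- file.path(dir, paste0(base, ".eeg"))
  raw_vals <- sweep(data, 1, resolutions, "/")
  flat <- if (orientation == "MULTIPLEXED") as.vector(raw_vals) else
    as.vector(t(raw_vals))
  if (format == "INT_16") {
    writeBin(as.integer(round(flat)), eeg, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(flat), eeg, size = 4, endian = "little")
  }
  vmrk <- file.path(dir, paste0(base, ".vmrk"))
  writeLines(c("[Marker Infos]", "Mk1=New Segment,,1,1,0"), vmrk)
  vhdr <- file.path(dir, paste0(base, ".vhdr"))
  writeLines(c(
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    paste0("NumberOfChannels=", nrow(data)),
    paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
    "[Binary Infos]",
    paste0("BinaryFormat=", format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%g,%s", seq_len(nrow(data)), labels, resolutions,
            units)), vhdr)
  vhdr
}
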