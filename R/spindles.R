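#' Spindle detection parameters
#'
#' Parameters for the dual amplitude-threshold spindle detector (the
#' Ferrarelli-style approach): the sigma band to isolate, lower and upper
#' thresholds as multiples of the mean rectified sigma amplitude over the
#' selected stages, and a duration gate.
#'
#' @param sigma_band A [band_spec()] (default sigma, 12–16 Hz).
#' @param lower_mult Lower threshold multiplier (default 2): candidate
#'   events are maximal intervals where the rectified-signal envelope
#'   exceeds `lower_mult` x baseline.
#' @param upper_mult Upper threshold multiplier (default 6): a candidate
#'   is accepted only if its envelope peak exceeds `upper_mult` x
#'   baseline.
#' @param min_dur_s,max_dur_s Accepted duration range in seconds
#'   (defaults 0.5 and 3; set to `0`/`Inf` to disable the gate).
#' @param stages Stages over which the baseline is computed and within
#'   which events are kept (default N2 and N3).
#' @return A `spindle_params` object.
#' @export
spindle_params <- function(sigma_band = band_spec("sigma", 12, 16),
                           lower_mult = 2, upper_mult = 6,
                           min_dur_s = 0.5, max_dur_s = 3,
                           stages = c("N2", "N3")) {
  stopifnot(lower_mult > 0, lower_mult < upper_mult,
            min_dur_s >= 0, min_dur_s < max_dur_s)
  structure(list(sigma_band = sigma_band, lower_mult = lower_mult,
                 upper_mult = upper_mult, min_dur_s = min_dur_s,
                 max_dur_s = max_dur_s, stages = stages),
            class = "spindle_params")
}

#' Detect sleep spindles by dual amplitude thresholds
#'
#' Per channel: (1) band-pass the raw signal to the sigma band; (2)
#' rectify; (3) build the upper envelope by linear interpolation through
#' the rectified signal's local maxima; (4) compute the baseline as the
#' mean rectified amplitude over the selected stages' epochs (excluding
#' artifact-flagged ones); (5) take maximal intervals where the envelope
#' exceeds `lower_mult` x baseline as candidates; (6) accept a candidate
#' iff its envelope peak exceeds `upper_mult` x baseline and its duration
#' lies within the gate; (7) discard events that do not overlap the
#' selected stages. Events are reported with their lower-threshold
#' crossings as onset/offset.
#'
#' Because both thresholds are relative to the per-channel baseline, the
#' event list is invariant to a global amplitude rescaling of the
#' recording.
#'
#' @param recording The unfiltered `psg_recording` (the detector applies
#'   its own sigma filter).
#' @param marked A `stage_marked` object for the same recording.
#' @param params A [spindle_params()].
#' @param artifact_mask Optional `artifact_mask`; flagged epochs are
#'   excluded from the baseline.
#' @return Data frame of class `spindle_events`: `channel`, `onset_s`,
#'   `offset_s`, `peak_s`, `peak_amplitude_uv`, `duration_s`, `stage`
#'   (stage at the peak sample), sorted by onset. Baselines are attached
#'   as the `baseline_uv` attribute.
#' @export
detect_spindles <- function(recording, marked, params = spindle_params(),
                            artifact_mask = NULL) {
  stopifnot(inherits(recording, "psg_recording"),
            inherits(marked, "stage_marked"),
            inherits(params, "spindle_params"))
  fs <- recording$fs
  hyp <- marked$hypnogram
  eps <- .epoch_samples(hyp, fs, n_samples(recording))
  in_stage <- eps$stage %in% params$stages
  if (!is.null(artifact_mask)) {
    flagged <- apply(unclass(artifact_mask), 2, any)
    in_stage <- in_stage & !flagged
  }
  if (!any(in_stage)) {
    stop("no data in stages {", paste(params$stages, collapse = ","),
         "}", call. = FALSE)
  }
  base_idx <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                            eps$start[in_stage], eps$end[in_stage],
                            SIMPLIFY = FALSE))
  # sample stage lookup for event stage assignment / overlap filtering
  stage_of <- rep("UNSCORED", n_samples(recording))
  for (i in seq_len(nrow(eps))) {
    if (eps$end[i] > eps$start[i]) {
      stage_of[(eps$start[i] + 1L):eps$end[i]] <- eps$stage[i]
    }
  }
  filtered <- bandpass(recording, params$sigma_band)
  events <- list()
  baselines <- numeric(0)
  for (ch in seq_len(nrow(recording$data))) {
    x <- abs(filtered$data[ch, ])
    env <- .upper_envelope(x)
    baseline <- mean(x[base_idx])
    baselines[recording$channel_labels[ch]] <- baseline
    if (baseline <= 0) {
      stop("degenerate input: zero sigma baseline on channel ",
           recording$channel_labels[ch], call. = FALSE)
    }
    lower <- params$lower_mult * baseline
    upper <- params$upper_mult * baseline
    above <- env > lower
    runs <- .runs_true(above)
    if (nrow(runs) == 0L) next
    for (r in seq_len(nrow(runs))) {
      i0 <- runs$start[r]; i1 <- runs$end[r]
      dur <- (i1 - i0 + 1L) / fs
      if (dur < params$min_dur_s || dur > params$max_dur_s) next
      seg <- env[i0:i1]
      pk <- which.max(seg)
      if (seg[pk] <= upper) next
      ev_stages <- stage_of[i0:i1]
      if (!any(ev_stages %in% params$stages)) next
      peak_i <- i0 + pk - 1L
      events[[length(events) + 1L]] <- data.frame(
        channel = recording$channel_labels[ch],
        onset_s = (i0 - 1L) / fs, offset_s = (i1 - 1L) / fs,
        peak_s = (peak_i - 1L) / fs,
        peak_amplitude_uv = seg[pk],
        duration_s = dur,
        stage = stage_of[peak_i],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(events)) {
    do.call(rbind, events)
  } else {
    data.frame(channel = character(), onset_s = numeric(),
               offset_s = numeric(), peak_s = numeric(),
               peak_amplitude_uv = numeric(), duration_s = numeric(),
               stage = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$onset_s, out$channel), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_uv") <- baselines
  attr(out, "params") <- params
  class(out) <- c("spindle_events", "data.frame")
  out
}

# Upper envelope: linear interpolation through local maxima of the
# rectified signal (endpoints included so the envelope is total).
.upper_envelope <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  is_max <- c(TRUE, x[2:(n - 1)] >= x[1:(n - 2)] &
                    x[2:(n - 1)] > x[3:n], TRUE)
  idx <- which(is_max)
  approx(idx, x[idx], xout = seq_len(n))$y
}

# Maximal runs of TRUE as (start, end) 1-based inclusive indices.
.runs_true <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Spindle density and event summaries per channel
#'
#' Events per minute of selected-stage time, per channel, with mean
#' duration and mean peak amplitude (reported as `NA` for channels with
#' no events).
#'
#' @param events A `spindle_events` data frame.
#' @param hyp The [hypnogram] the detection ran against.
#' @param stages Stages defining the denominator minutes (default the
#'   detection stages).
#' @param channels Channels to report (default those present in
#'   `events`' baseline attribute, falling back to event channels).
#' @return Data frame: `channel`, `n_events`, `stage_minutes`,
#'   `density_per_min`, `mean_duration_s`, `mean_peak_uv`.
#' @export
spindle_density <- function(events, hyp, stages = NULL, channels = NULL) {
  if (is.null(stages)) {
    p <- attr(events, "params")
    stages <- if (!is.null(p)) p$stages else c("N2", "N3")
  }
  minutes <- sum(hyp$stage %in% stages) * epoch_length(hyp) / 60
  if (minutes <= 0) stop("zero minutes in stages {",
                         paste(stages, collapse = ","), "}", call. = FALSE)
  if (is.null(channels)) {
    channels <- names(attr(events, "baseline_uv"))
    if (is.null(channels)) channels <- unique(events$channel)
  }
  rows <- lapply(channels, function(ch) {
    ev <- events[events$channel == ch, , drop = FALSE]
    data.frame(channel = ch, n_events = nrow(ev), stage_minutes = minutes,
               density_per_min = nrow(ev) / minutes,
               mean_duration_s = if (nrow(ev)) mean(ev$duration_s) else NA_real_,
               mean_peak_uv = if (nrow(ev)) mean(ev$peak_amplitude_uv) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot detected spindles over the broadband and sigma-filtered signal
#'
#' Writes an overview panel (event boxes over both traces against
#' chronological time) and up to `max_zoom` per-event zoom panels.
#'
#' @param recording The unfiltered `psg_recording`.
#' @param events A `spindle_events` data frame.
#' @param channel Channel label to plot.
#' @param out_path Output figure path.
#' @param sigma_band Band used for the sigma trace (default 12–16 Hz).
#' @param max_zoom Maximum number of zoom panels (default 6).
#' @return `out_path`, invisibly.
#' @export
plot_spindle_overview <- function(recording, events, channel, out_path,
                                  sigma_band = band_spec("sigma", 12, 16),
                                  max_zoom = 6) {
  m <- match(toupper(channel), toupper(recording$channel_labels))
  if (is.na(m)) stop("unknown channel: ", channel, call. = FALSE)
  fs <- recording$fs
  broad <- recording$data[m, ]
  sig <- bandpass(recording, sigma_band)$data[m, ]
  ev <- events[events$channel == recording$channel_labels[m], ,
               drop = FALSE]
  nz <- min(nrow(ev), max_zoom)
  .open_device(out_path, 900, 250 * (1 + nz))
  on.exit(dev.off(), add = TRUE)
  par(mfrow = c(1 + nz, 1), mar = c(3, 4, 2, 1))
  t_s <- (seq_along(broad) - 1) / fs
  dec <- max(1L, ceiling(length(broad) / 20000))
  i <- seq(1L, length(broad), by = dec)
  plot(t_s[i], broad[i], type = "l", col = "blue", xlab = "Time (s)",
       ylab = "uV", main = paste0(channel, ": detected spindles"))
  lines(t_s[i], sig[i], col = "cyan")
  if (nrow(ev)) {
    rng <- range(broad)
    rect(ev$onset_s, rng[1], ev$offset_s, rng[2], border = "black")
  }
  for (k in seq_len(nz)) {
    w0 <- max(0, ev$onset_s[k] - 1)
    w1 <- min(t_s[length(t_s)], ev$offset_s[k] + 1)
    j <- which(t_s >= w0 & t_s <= w1)
    plot(t_s[j], sig[j], type = "l", col = "cyan", xlab = "Time (s)",
         ylab = "uV",
         main = sprintf("spindle %d: %.2f-%.2f s", k, ev$onset_s[k],
                        ev$offset_s[k]))
    abline(v = c(ev$onset_s[k], ev$offset_s[k]), lty = 2)
  }
  invisible(out_path)
}

#' Export spindle events as CSV
#' @param events A `spindle_events` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spindles_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
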