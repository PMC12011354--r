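#' Frequency band specification
#'
#' A named frequency band with its filter design and an optional per-band
#' artifact threshold. Two designs are supported: `"butterworth"`
#' (order-4 bandpass by default, applied forward-backward so the
#' effective order doubles and the phase is zero) and `"chebyshev2"`
#' (Chebyshev type II with stopband edges `transition_hz` outside the
#' passband and `stopband_db` attenuation — the design used for the theta
#' band, where steep delta rejection matters in deep sleep).
#'
#' @param name Band name.
#' @param low_hz,high_hz Passband edges in Hz (0 < low < high).
#' @param design `"butterworth"` or `"chebyshev2"`.
#' @param order Filter order (default 4).
#' @param stopband_db Chebyshev II stopband attenuation in dB (default 40).
#' @param transition_hz Chebyshev II transition width in Hz (default 1).
#' @param artifact_threshold_uv Optional artifact threshold in uV.
#' @return A `band_spec` object.
#' @export
band_spec <- function(name, low_hz, high_hz,
                      design = c("butterworth", "chebyshev2"),
                      order = 4L, stopband_db = 40, transition_hz = 1,
                      artifact_threshold_uv = NULL) {
  design <- match.arg(design)
  stopifnot(low_hz > 0, low_hz < high_hz)
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz,
                 design = design, order = order, stopband_db = stopband_db,
                 transition_hz = transition_hz,
                 artifact_threshold_uv = artifact_threshold_uv),
            class = "band_spec")
}

#' Default sleep EEG band table
#'
#' delta 0.5–4 Hz and sigma 12–16 Hz (the conventional slow-wave and
#' spindle bands), theta 4–8 Hz. Theta uses the Chebyshev II design to
#' keep high-amplitude delta activity out of the theta estimate; the
#' other bands use the order-4 Butterworth applied bidirectionally.
#'
#' @return Named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(
    delta = band_spec("delta", 0.5, 4),
    theta = band_spec("theta", 4, 8, design = "chebyshev2"),
    sigma = band_spec("sigma", 12, 16)
  )
}

#' Downsample a recording
#'
#' Anti-alias low-passes (Chebyshev II, stopband at the new Nyquist, 60 dB,
#' passband to ~0.45 x target rate, applied zero-phase) and then
#' resamples. Integer ratios decimate by indexing; rational ratios go
#' through polyphase resampling. Duration is preserved within one sample.
#'
#' @param recording A `psg_recording`.
#' @param target_fs Target sampling rate (< fs); equal to fs is a no-op.
#' @return Downsampled recording.
#' @export
downsample <- function(recording, target_fs) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$fs
  if (target_fs > fs) stop("target_fs must not exceed fs", call. = FALSE)
  if (target_fs == fs) {
    return(add_provenance(recording, "downsample[skip]"))
  }
  aa <- signal::cheby2(8, 60, (target_fs / 2) / (fs / 2), type = "low")
  filt <- t(apply(recording$data, 1, function(x) signal::filtfilt(aa, x)))
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, ncol(filt), by = round(ratio))
    out <- filt[, idx, drop = FALSE]
  } else {
    frac <- .as_fraction(target_fs / fs)
    out <- t(apply(filt, 1, function(x) {
      as.numeric(signal::resample(x, frac$p, frac$q))
    }))
  }
  rec <- new_recording(out, target_fs, recording$channel_labels,
                       recording$start_time, recording$positions,
                       recording$provenance)
  add_provenance(rec, sprintf("downsample[%g->%g]", fs, target_fs))
}

.as_fraction <- function(x, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(list(p = as.integer(round(p)), q = q))
  }
  stop("fs ratio is not rational within denominator ", max_den,
       call. = FALSE)
}

#' Re-reference a recording
#'
#' @param recording A `psg_recording`.
#' @param scheme `"average"` (subtract the per-sample mean over all
#'   channels), `"linked"` (subtract the mean of `channels`, e.g. linked
#'   mastoids), `"single"` (subtract one named channel), or `"none"`.
#' @param channels Reference channel label(s) for `"linked"`/`"single"`.
#' @return Re-referenced recording.
#' @export
rereference <- function(recording, scheme = c("average", "linked",
                                              "single", "none"),
                        channels = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(recording, "psg_recording"))
  d <- recording$data
  ref <- switch(scheme,
    none = NULL,
    average = colMeans(d),
    linked = ,
    single = {
      if (is.null(channels)) stop("reference channels required",
                                  call. = FALSE)
      if (scheme == "single" && length(channels) != 1L) {
        stop("single-channel reference needs exactly one channel",
             call. = FALSE)
      }
      m <- match(toupper(channels), toupper(recording$channel_labels))
      if (anyNA(m)) {
        stop("reference channel(s) not found: ",
             paste(channels[is.na(m)], collapse = ","), call. = FALSE)
      }
      colMeans(d[m, , drop = FALSE])
    })
  if (!is.null(ref)) d <- sweep(d, 2, ref)
  rec <- new_recording(d, recording$fs, recording$channel_labels,
                       recording$start_time, recording$positions,
                       recording$provenance)
  add_provenance(rec, paste0("reref[", scheme, "]"))
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed channels with a spherical-spline reconstruction
#' (order-4 Legendre kernel, terms to degree 50, ridge regularization
#' 1e-5 on the kernel diagonal) from the remaining located channels.
#' Requires electrode positions ([attach_montage()]) and at least four
#' good located channels. Good channels are left untouched.
#'
#' @param recording A `psg_recording` with positions attached.
#' @param bad_labels Channels to reconstruct.
#' @param spline_order Legendre kernel exponent m (default 4).
#' @param reg Regularization added to the kernel diagonal (default 1e-5).
#' @return Recording with bad channels replaced.
#' @export
interpolate_bad_channels <- function(recording, bad_labels,
                                     spline_order = 4, reg = 1e-5) {
  stopifnot(inherits(recording, "psg_recording"))
  if (is.null(recording$positions)) {
    stop("positions not attached; run attach_montage() first",
         call. = FALSE)
  }
  labels <- recording$channel_labels
  bad_idx <- match(toupper(bad_labels), toupper(labels))
  if (anyNA(bad_idx)) {
    stop("bad channel(s) not in recording: ",
         paste(bad_labels[is.na(bad_idx)], collapse = ","), call. = FALSE)
  }
  located <- labels[toupper(labels) %in% toupper(rownames(recording$positions))]
  good <- setdiff(located, labels[bad_idx])
  if (length(good) < 4L) {
    stop("need at least 4 good located channels for interpolation",
         call. = FALSE)
  }
  bad_located <- intersect(labels[bad_idx], located)
  if (length(bad_located) < length(bad_idx)) {
    stop("bad channel(s) without montage position cannot be interpolated",
         call. = FALSE)
  }
  pos <- recording$positions
  gp <- pos[match(toupper(good), toupper(rownames(pos))), , drop = FALSE]
  bp <- pos[match(toupper(bad_located), toupper(rownames(pos))), ,
            drop = FALSE]
  G <- .spline_g(tcrossprod(gp), spline_order) + diag(reg, nrow(gp))
  Gb <- .spline_g(tcrossprod(bp, gp), spline_order)
  ng <- nrow(gp)
  # solve [G 1; 1' 0] [c; d] = [z; 0] for every sample at once
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  gi <- match(good, labels)
  Z <- rbind(recording$data[gi, , drop = FALSE], 0)
  cd <- solve(A, Z)
  interp <- Gb %*% cd[seq_len(ng), , drop = FALSE] +
    matrix(cd[ng + 1L, ], nrow = nrow(bp), ncol = ncol(recording$data),
           byrow = TRUE)
  d <- recording$data
  d[match(bad_located, labels), ] <- interp
  rec <- new_recording(d, recording$fs, labels, recording$start_time,
                       recording$positions, recording$provenance)
  add_provenance(rec, paste0("bci[", paste(bad_located, collapse = ","), "]"))
}

# Spherical spline kernel g(cos angle) with Legendre sum to degree 50.
.spline_g <- function(cosang, m, max_degree = 50L) {
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  x <- as.vector(cosang)
  # Legendre recurrence, vectorized over x
  p_prev <- rep(1, length(x))  # P0
  p_cur <- x                   # P1
  total <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (l in 2:max_degree) {
    p_next <- ((2 * l - 1) * x * p_cur - (l - 1) * p_prev) / l
    total <- total + (2 * l + 1) / (l * (l + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  matrix(total / (4 * pi), nrow = nrow(cosang))
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) band-pass filtering with the band's
#' design: order-4 Butterworth bandpass or Chebyshev II with stopband
#' edges `transition_hz` outside the passband. Pole radii are checked and
#' an unstable design (poles on or outside the unit circle) is rejected
#' with a suggestion to widen the band or downsample first.
#'
#' @param recording A `psg_recording`.
#' @param bandspec A [band_spec()].
#' @return Filtered recording; provenance records the design and a
#'   coefficient hash.
#' @export
bandpass <- function(recording, bandspec) {
  stopifnot(inherits(recording, "psg_recording"),
            inherits(bandspec, "band_spec"))
  flt <- .design_filter(bandspec, recording$fs)
  d <- t(apply(recording$data, 1, function(x) signal::filtfilt(flt, x)))
  rec <- new_recording(d, recording$fs, recording$channel_labels,
                       recording$start_time, recording$positions,
                       recording$provenance)
  coef_hash <- sum(abs(c(flt$b, flt$a))) %% 1000
  add_provenance(rec, sprintf("filter[%s:%g-%g:%s:h%.3f]", bandspec$name,
                              bandspec$low_hz, bandspec$high_hz,
                              bandspec$design, coef_hash))
}

.design_filter <- function(bandspec, fs) {
  nyq <- fs / 2
  if (bandspec$high_hz >= nyq) {
    stop(sprintf("band %s upper edge %g Hz >= Nyquist %g Hz",
                 bandspec$name, bandspec$high_hz, nyq), call. = FALSE)
  }
  flt <- if (bandspec$design == "chebyshev2") {
    lo <- max(bandspec$low_hz - bandspec$transition_hz, 0.05)
    hi <- bandspec$high_hz + bandspec$transition_hz
    if (hi >= nyq) stop("chebyshev2 stopband edge exceeds Nyquist",
                        call. = FALSE)
    signal::cheby2(bandspec$order, bandspec$stopband_db,
                   c(lo, hi) / nyq, type = "pass")
  } else {
    signal::butter(bandspec$order,
                   c(bandspec$low_hz, bandspec$high_hz) / nyq,
                   type = "pass")
  }
  r <- max(Mod(polyroot(rev(flt$a))))
  if (r >= 1 - 1e-10) {
    stop(sprintf(
      "unstable %s design for band %s at fs %g Hz (pole radius %.6f); use a lower order, a wider transition, or downsample first",
      bandspec$design, bandspec$name, fs, r), call. = FALSE)
  }
  flt
}

#' Evaluate a band filter's frequency response
#'
#' Single-pass magnitude response of the band's filter design at `n`
#' frequencies (the zero-phase application squares this magnitude).
#'
#' @param bandspec A [band_spec()].
#' @param fs Sampling rate the filter would be designed for.
#' @param n Number of evaluation frequencies.
#' @return Data frame `freq_hz`, `gain` (single-pass magnitude).
#' @export
filter_response <- function(bandspec, fs, n = 4096) {
  flt <- .design_filter(bandspec, fs)
  H <- signal::freqz(flt, n = n, Fs = fs)
  data.frame(freq_hz = H$f, gain = Mod(H$h))
}

#' Detect high-amplitude artifacts per epoch
#'
#' Flags a channel x epoch cell when the maximum absolute band-filtered
#' amplitude within the epoch exceeds the threshold. The result feeds
#' [select_stage_time()], which drops flagged epochs.
#'
#' @param band_recording A band-filtered `psg_recording`.
#' @param marked The `stage_marked` object defining the epoch grid.
#' @param threshold_uv Positive threshold in uV (`Inf` flags nothing).
#' @return An `artifact_mask`: logical matrix channels x epochs with
#'   attributes `epochs` (epoch indices), `threshold_uv` and `method`.
#' @export
detect_artifacts <- function(band_recording, marked, threshold_uv) {
  stopifnot(inherits(band_recording, "psg_recording"),
            inherits(marked, "stage_marked"), threshold_uv > 0)
  hyp <- marked$hypnogram
  eps <- .epoch_samples(hyp, band_recording$fs, n_samples(band_recording))
  mask <- matrix(FALSE, nrow = nrow(band_recording$data),
                 ncol = nrow(eps),
                 dimnames = list(band_recording$channel_labels, NULL))
  for (i in seq_len(nrow(eps))) {
    if (eps$end[i] <= eps$start[i]) next
    seg <- band_recording$data[, (eps$start[i] + 1L):eps$end[i],
                               drop = FALSE]
    mask[, i] <- apply(abs(seg), 1, max) > threshold_uv
  }
  structure(mask, epochs = eps$epoch, threshold_uv = threshold_uv,
            method = "epoch_max_abs", class = "artifact_mask")
}

#' Write an artifact mask as CSV
#' @param mask An `artifact_mask`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_artifact_csv <- function(mask, path) {
  df <- expand.grid(channel = rownames(mask),
                    epoch = attr(mask, "epochs"), stringsAsFactors = FALSE)
  df$flagged <- as.vector(unclass(mask))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run a user-supplied preprocessing hook
#'
#' The hook slot in the common preprocessing chain: any function taking
#' and returning a `psg_recording`. Unless the hook declares structural
#' changes (`declares_changes = TRUE`), it must preserve the sampling
#' rate and channel labels; a violation is a contract error.
#'
#' @param recording A `psg_recording`.
#' @param hook Function `psg_recording -> psg_recording`.
#' @param hook_name Name recorded in provenance.
#' @param declares_changes Allow the hook to change fs/labels.
#' @return The hook's output with provenance appended.
#' @export
run_custom_hook <- function(recording, hook, hook_name = "custom",
                            declares_changes = FALSE) {
  stopifnot(inherits(recording, "psg_recording"), is.function(hook))
  out <- hook(recording)
  if (!inherits(out, "psg_recording")) {
    stop("hook must return a psg_recording", call. = FALSE)
  }
  if (!declares_changes) {
    if (!identical(out$fs, recording$fs) ||
        !identical(out$channel_labels, recording$channel_labels)) {
      stop("hook changed fs or channel labels without declaring changes",
           call. = FALSE)
    }
  }
  add_provenance(out, paste0("custom_hook[", hook_name, "]"))
}

#' The ICA slot in the preprocessing chain
#'
#' Independent components analysis itself is delegated to external
#' tooling; this slot either records that the step was skipped or applies
#' an externally computed unmixing/backprojection function and stores a
#' note in provenance, keeping the chain order auditable.
#'
#' @param recording A `psg_recording`.
#' @param decompose Optional function `psg_recording -> psg_recording`
#'   wrapping an external ICA clean-up.
#' @return Recording with the `ica_slot` provenance entry.
#' @export
ica_slot <- function(recording, decompose = NULL) {
  stopifnot(inherits(recording, "psg_recording"))
  if (is.null(decompose)) {
    return(add_provenance(recording, "ica_slot[skip]"))
  }
  out <- decompose(recording)
  stopifnot(inherits(out, "psg_recording"))
  add_provenance(out, "ica_slot[external]")
}
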