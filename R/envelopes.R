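#' Filter-Hilbert amplitude envelope
#'
#' Computes the instantaneous amplitude of an already band-filtered
#' recording as the magnitude of the analytic signal (FFT-based Hilbert
#' transform, per channel). The first and last `edge_s` seconds are
#' flagged as unreliable because of transform edge effects.
#'
#' @param band_recording A band-filtered `psg_recording` (see
#'   [bandpass()]).
#' @param hyp Optional [hypnogram] carried along for stage-aware
#'   summaries and ribbon overlays.
#' @param band Optional [band_spec()] recorded in the result.
#' @param edge_s Seconds flagged unreliable at each end (default 2).
#' @return An `envelope`: list with `data` (channels x samples, uV, all
#'   non-negative), `fs`, `band`, `hypnogram`, `edge_s`.
#' @export
hilbert_envelope <- function(band_recording, hyp = NULL, band = NULL,
                             edge_s = 2) {
  stopifnot(inherits(band_recording, "psg_recording"))
  env <- t(apply(band_recording$data, 1,
                 function(x) Mod(.analytic_signal(x))))
  dimnames(env) <- list(band_recording$channel_labels, NULL)
  structure(list(data = env, fs = band_recording$fs, band = band,
                 hypnogram = hyp, edge_s = edge_s,
                 channel_labels = band_recording$channel_labels),
            class = "envelope")
}

# FFT-based analytic signal: zero negative frequencies, double positive.
.analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Summarize an amplitude envelope by stage selection and channel groups
#'
#' Mean, median and SD of the envelope over the samples of the selected
#' epochs, per channel and per named channel group (e.g. the
#' frontocentral set F3, F4, C3, C4). Also returns a decimated full-bout
#' trace (at most `max_points` per channel) with per-epoch ribbon colors
#' for plotting.
#'
#' @param envelope An `envelope` with a hypnogram attached.
#' @param selection A [stage_selection()].
#' @param channel_groups Named list of character vectors, e.g.
#'   `list(frontocentral = c("F3", "F4", "C3", "C4"))`.
#' @param max_points Decimation target for the plotting trace.
#' @return List with `summary` (data frame: name, kind, mean/median/sd in
#'   uV, n_samples) and `trace` (data frame: time_s, one column per
#'   channel) plus `ribbon` codes.
#' @export
envelope_summary <- function(envelope, selection, channel_groups = list(),
                             max_points = 10000) {
  stopifnot(inherits(envelope, "envelope"),
            inherits(selection, "stage_selection"))
  hyp <- envelope$hypnogram
  if (is.null(hyp)) stop("envelope has no hypnogram attached",
                         call. = FALSE)
  keep <- .select_epochs(hyp, selection)
  if (!any(keep)) {
    stop("no epochs match stages {",
         paste(selection$stages, collapse = ","), "}", call. = FALSE)
  }
  eps <- .epoch_samples(hyp, envelope$fs, ncol(envelope$data))[keep, ,
                                                              drop = FALSE]
  eps <- eps[eps$end > eps$start, , drop = FALSE]
  idx <- unlist(mapply(function(s, e) seq.int(s + 1L, e), eps$start,
                       eps$end, SIMPLIFY = FALSE))
  sel <- envelope$data[, idx, drop = FALSE]
  rows <- list()
  for (ch in rownames(sel)) {
    v <- sel[ch, ]
    rows[[length(rows) + 1L]] <- data.frame(
      name = ch, kind = "channel", mean_uv = mean(v),
      median_uv = median(v), sd_uv = sd(v), n_samples = length(v),
      stringsAsFactors = FALSE)
  }
  for (g in names(channel_groups)) {
    m <- match(toupper(channel_groups[[g]]), toupper(rownames(sel)))
    if (anyNA(m)) {
      stop("group '", g, "' names unknown channel(s): ",
           paste(channel_groups[[g]][is.na(m)], collapse = ","),
           call. = FALSE)
    }
    v <- colMeans(sel[m, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      name = g, kind = "group", mean_uv = mean(v), median_uv = median(v),
      sd_uv = sd(v), n_samples = length(v), stringsAsFactors = FALSE)
  }
  n <- ncol(envelope$data)
  dec <- max(1L, ceiling(n / max_points))
  tidx <- seq(1L, n, by = dec)
  trace <- data.frame(time_s = (tidx - 1L) / envelope$fs)
  for (ch in rownames(envelope$data)) trace[[ch]] <- envelope$data[ch, tidx]
  list(summary = do.call(rbind, rows), trace = trace, ribbon = ribbon(hyp))
}

#' Morlet wavelet time-frequency representation
#'
#' Complex Morlet convolution magnitude per channel, frequency and
#' (decimated) time point. Each wavelet is normalized to unit energy so
#' amplitudes are comparable across frequencies. Defaults follow common
#' practice: log-spaced frequencies 0.5–30 Hz and
#' `n_cycles = max(3, f/2)`.
#'
#' @param recording A `psg_recording`.
#' @param freqs_hz Frequencies to analyze (default 24 log-spaced values,
#'   0.5–30 Hz, clipped below Nyquist).
#' @param n_cycles Cycles per wavelet: scalar or per-frequency vector
#'   (default `max(3, f/2)`).
#' @param time_step_s Spacing of the output time axis (default 0.5 s).
#' @return A `psg_tfr`: list with `freqs_hz`, `times_s`, `amplitude`
#'   (array channels x freqs x times, uV).
#' @export
morlet_tfr <- function(recording, freqs_hz = NULL, n_cycles = NULL,
                       time_step_s = 0.5) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$fs
  if (is.null(freqs_hz)) {
    freqs_hz <- exp(seq(log(0.5), log(min(30, fs / 2 * 0.9)),
                        length.out = 24))
  }
  stopifnot(all(freqs_hz > 0), all(freqs_hz < fs / 2))
  if (is.null(n_cycles)) n_cycles <- pmax(3, freqs_hz / 2)
  if (length(n_cycles) == 1L) n_cycles <- rep(n_cycles, length(freqs_hz))
  stopifnot(length(n_cycles) == length(freqs_hz))
  n <- n_samples(recording)
  tidx <- seq(1L, n, by = max(1L, as.integer(round(time_step_s * fs))))
  n_ch <- nrow(recording$data)
  out <- array(0, dim = c(n_ch, length(freqs_hz), length(tidx)),
               dimnames = list(recording$channel_labels, NULL, NULL))
  nfft <- stats::nextn(2L * n, 2)
  Xf <- apply(recording$data, 1, function(x) fft(c(x, numeric(nfft - n))))
  for (k in seq_along(freqs_hz)) {
    f <- freqs_hz[k]
    sigma_t <- n_cycles[k] / (2 * pi * f)
    half <- ceiling(3.5 * sigma_t * fs)
    tt <- (-half:half) / fs
    if (length(tt) > n) {
      stop(sprintf("wavelet at %.2f Hz (%d samples) longer than recording",
                   f, length(tt)), call. = FALSE)
    }
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))            # unit energy
    Wf <- fft(c(w, complex(real = numeric(nfft - length(w)))))
    for (ch in seq_len(n_ch)) {
      conv <- fft(Xf[, ch] * Wf, inverse = TRUE) / nfft
      vals <- Mod(conv[(half + 1L):(half + n)])   # center-aligned
      out[ch, k, ] <- vals[tidx]
    }
  }
  structure(list(freqs_hz = freqs_hz,
                 times_s = (tidx - 1L) / fs,
                 amplitude = out),
            class = "psg_tfr")
}

#' Plot an amplitude envelope with ribbon overlay
#'
#' Full-bout envelope trace (decimated) for one channel or a channel
#' average, with the color-coded ribbon hypnogram above.
#'
#' @param envelope An `envelope` with hypnogram.
#' @param out_path Output figure path.
#' @param channels Channels to average (default all).
#' @return `out_path`, invisibly.
#' @export
plot_envelope <- function(envelope, out_path, channels = NULL) {
  stopifnot(inherits(envelope, "envelope"))
  d <- envelope$data
  if (!is.null(channels)) {
    m <- match(toupper(channels), toupper(rownames(d)))
    if (anyNA(m)) stop("unknown channel(s)", call. = FALSE)
    d <- d[m, , drop = FALSE]
  }
  v <- colMeans(d)
  n <- length(v)
  dec <- max(1L, ceiling(n / 10000))
  idx <- seq(1L, n, by = dec)
  t_s <- (idx - 1L) / envelope$fs
  .open_device(out_path, 900, 300)
  on.exit(dev.off(), add = TRUE)
  par(mar = c(4, 4, 2, 1))
  ymax <- max(v[idx]) * 1.25
  plot(t_s, v[idx], type = "l", xlab = "Time (s)",
       ylab = "Amplitude (uV)", ylim = c(0, ymax))
  if (!is.null(envelope$hypnogram)) {
    rib <- ribbon(envelope$hypnogram)
    el <- epoch_length(envelope$hypnogram)
    rect(rib$onset_s, ymax * 0.92, rib$onset_s + el, ymax,
         col = rib$color, border = NA)
  }
  invisible(out_path)
}
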