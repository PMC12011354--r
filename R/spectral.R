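#' Stage-time-aware amplitude spectrum
#'
#' Welch-style averaged amplitude spectrum over a stage/time-restricted
#' [select_stage_time()] result. Analysis windows (Hamming-tapered,
#' `window_s` long, `overlap_frac` overlap) are placed only inside
#' individual segments, so no window ever spans a concatenation seam
#' between non-adjacent pieces of the night.
#'
#' Amplitude convention: per window the squared-magnitude spectrum is
#' corrected for the taper's coherent gain (`sum(w)`), averaged over
#' windows, then square-rooted and doubled for the one-sided spectrum.
#' A pure sinusoid of amplitude A whose frequency falls on a bin thus
#' reads A at that bin.
#'
#' @param segment_set A `segment_set` from [select_stage_time()].
#' @param window_s Window length in seconds (default 5; resolves the
#'   0.5 Hz delta edge within a 30-s epoch).
#' @param overlap_frac Fractional overlap between windows (default 0.5).
#' @param fmax_hz Highest frequency kept (default Nyquist).
#' @return A `spectrum_result`: list with `freqs_hz`, `amplitude`
#'   (channels x freqs matrix, uV), `n_windows`, `selection`.
#' @export
amplitude_spectrum <- function(segment_set, window_s = 5,
                               overlap_frac = 0.5, fmax_hz = NULL) {
  stopifnot(inherits(segment_set, "segment_set"),
            window_s > 0, overlap_frac >= 0, overlap_frac < 1)
  rec <- segment_set$concatenated
  fs <- rec$fs
  nwin <- as.integer(round(window_s * fs))
  step <- max(1L, as.integer(round(nwin * (1 - overlap_frac))))
  # window start offsets (0-based) that fit wholly inside one segment of
  # the concatenated axis
  lens <- segment_set$segments$end_sample - segment_set$segments$start_sample
  seg_off <- cumsum(c(0L, lens[-length(lens)]))
  starts <- unlist(mapply(function(off, len) {
    if (len < nwin) return(integer())
    seq.int(off, off + len - nwin, by = step)
  }, seg_off, lens, SIMPLIFY = FALSE))
  if (length(starts) == 0L) {
    stop(sprintf("no %g-s window fits inside any segment", window_s),
         call. = FALSE)
  }
  w <- .hamming(nwin)
  cg <- sum(w)
  freqs <- (seq_len(nwin %/% 2) ) / nwin * fs   # drop DC
  keep_f <- freqs > 0
  if (!is.null(fmax_hz)) keep_f <- keep_f & freqs <= fmax_hz
  n_ch <- nrow(rec$data)
  psum <- matrix(0, n_ch, sum(keep_f))
  for (s in starts) {
    seg <- rec$data[, (s + 1L):(s + nwin), drop = FALSE]
    X <- t(mvfft(t(seg * matrix(w, n_ch, nwin, byrow = TRUE))))
    P <- (Mod(X[, 2L:(nwin %/% 2 + 1L), drop = FALSE]) / cg)^2
    psum <- psum + P[, keep_f, drop = FALSE]
  }
  amp <- 2 * sqrt(psum / length(starts))
  dimnames(amp) <- list(rec$channel_labels, NULL)
  structure(list(freqs_hz = freqs[keep_f], amplitude = amp,
                 n_windows = length(starts),
                 selection = segment_set$selection),
            class = "spectrum_result")
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Average amplitude spectra across participants
#'
#' Element-wise mean of per-participant spectra; all inputs must share
#' the frequency axis and channel order exactly (no silent reordering).
#'
#' @param results List of `spectrum_result` objects.
#' @return A `spectrum_result` whose `n_windows` is the participant count.
#' @export
group_average_spectra <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "spectrum_result")))
  ref <- results[[1L]]
  for (r in results[-1L]) {
    if (!isTRUE(all.equal(r$freqs_hz, ref$freqs_hz))) {
      stop("frequency axes differ across participants", call. = FALSE)
    }
    if (!identical(rownames(r$amplitude), rownames(ref$amplitude))) {
      stop("channel sets/order differ across participants", call. = FALSE)
    }
  }
  amp <- Reduce(`+`, lapply(results, `[[`, "amplitude")) / length(results)
  structure(list(freqs_hz = ref$freqs_hz, amplitude = amp,
                 n_windows = length(results), selection = ref$selection),
            class = "spectrum_result")
}

#' Export a spectrum as CSV
#'
#' Long format: one row per channel x frequency.
#' @param spec A `spectrum_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  df <- data.frame(
    channel = rep(rownames(spec$amplitude), times = length(spec$freqs_hz)),
    freq_hz = rep(spec$freqs_hz, each = nrow(spec$amplitude)),
    amplitude_uv = as.vector(spec$amplitude))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot per-electrode amplitude spectra
#'
#' Writes a grid of per-channel spectra to PNG/SVG.
#'
#' @param spec A `spectrum_result`.
#' @param out_path Output figure path.
#' @return `out_path`, invisibly.
#' @export
plot_spectra <- function(spec, out_path) {
  n_ch <- nrow(spec$amplitude)
  nc <- ceiling(sqrt(n_ch))
  nr <- ceiling(n_ch / nc)
  .open_device(out_path, 250 * nc, 200 * nr)
  on.exit(dev.off(), add = TRUE)
  par(mfrow = c(nr, nc), mar = c(3, 3, 2, 1))
  for (i in seq_len(n_ch)) {
    plot(spec$freqs_hz, spec$amplitude[i, ], type = "l",
         xlab = "", ylab = "", main = rownames(spec$amplitude)[i])
  }
  invisible(out_path)
}
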