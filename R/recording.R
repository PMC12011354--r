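#' Construct an in-memory EEG recording
#'
#' The canonical container for multichannel signal data: a channels x
#' samples matrix in microvolts, a single sampling rate, channel labels,
#' optional unit-sphere electrode positions, a start clock time, and an
#' append-only provenance trail of processing steps.
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param start_time Clock time `"HH:MM:SS"` of recording start.
#' @param positions Optional matrix (channels x 3) of unit-sphere
#'   coordinates, rownames = labels.
#' @param provenance Character vector of applied processing steps.
#' @return A `psg_recording` object.
#' @export
new_recording <- function(data, fs, channel_labels,
                          start_time = "00:00:00", positions = NULL,
                          provenance = character()) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(fs) == 1L, fs > 0,
            nrow(data) == length(channel_labels))
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 positions = positions, start_time = start_time,
                 provenance = provenance),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(head(x$channel_labels, 12), collapse = " "),
      if (length(x$channel_labels) > 12) "...\n" else "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec A `psg_recording`.
#' @return Number of samples (`n_samples`) or duration in seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

# provenance is append-only; every pipeline step goes through this
add_provenance <- function(rec, step) {
  rec$provenance <- c(rec$provenance, step)
  rec
}

#' Built-in electrode montage
#'
#' Unit-sphere coordinates for the standard 10-20 electrode set (plus
#' mastoids), built from the proportional arc construction of the 10-20
#' system on a spherical head model: each 10% arc step is 18 degrees of
#' inclination from the vertex, so Fz/Pz/C3/C4 sit 36 degrees from Cz and
#' the outer ring (Fp1, F7, T7, ...) at 72 degrees. F3/F4/P3/P4 are the
#' spherical midpoints of their neighboring midline/ring electrodes.
#' Mastoids (M1/M2) sit below the ring at 100 degrees inclination.
#' Coordinates are x = right, y = anterior, z = up.
#'
#' @param name Montage name; only `"standard_1020"` is built in.
#' @return A `psg_montage`: list with `name` and `coordinates` (matrix
#'   labels x 3, all rows unit-norm).
#' @export
standard_montage <- function(name = "standard_1020") {
  if (!identical(name, "standard_1020")) {
    stop("unknown montage: ", name, call. = FALSE)
  }
  sph <- function(incl_deg, az_deg) {
    i <- incl_deg * pi / 180; a <- az_deg * pi / 180
    c(sin(i) * cos(a), sin(i) * sin(a), cos(i))
  }
  coords <- list(Cz = sph(0, 0),
                 Fz = sph(36, 90), Pz = sph(36, -90),
                 C3 = sph(36, 180), C4 = sph(36, 0),
                 Fpz = sph(72, 90), Oz = sph(72, -90),
                 Fp1 = sph(72, 108), Fp2 = sph(72, 72),
                 F7 = sph(72, 144), F8 = sph(72, 36),
                 T7 = sph(72, 180), T8 = sph(72, 0),
                 P7 = sph(72, -144), P8 = sph(72, -36),
                 O1 = sph(72, -108), O2 = sph(72, -72),
                 M1 = sph(100, 198), M2 = sph(100, -18))
  slerp_mid <- function(u, v) { w <- u + v; w / sqrt(sum(w^2)) }
  coords$F3 <- slerp_mid(coords$Fz, coords$F7)
  coords$F4 <- slerp_mid(coords$Fz, coords$F8)
  coords$P3 <- slerp_mid(coords$Pz, coords$P7)
  coords$P4 <- slerp_mid(coords$Pz, coords$P8)
  m <- do.call(rbind, coords)
  structure(list(name = name, coordinates = m), class = "psg_montage")
}

#' Attach electrode positions to a recording
#'
#' Matches channel labels (case-insensitively) against a montage table and
#' stores unit-sphere positions for every resolved channel. Channels not
#' in the montage (e.g. EMG) are left unlocated and listed in provenance;
#' zero matches is an error since it usually means the wrong montage.
#'
#' @param recording A `psg_recording`.
#' @param montage_name Built-in montage name (default `"standard_1020"`).
#' @return The recording with `positions` set (matrix, located channels x
#'   3, rownames = recording labels).
#' @export
attach_montage <- function(recording, montage_name = "standard_1020") {
  mon <- standard_montage(montage_name)
  idx <- match(toupper(recording$channel_labels),
               toupper(rownames(mon$coordinates)))
  located <- !is.na(idx)
  if (!any(located)) {
    stop("no channel labels matched montage '", montage_name,
         "' (wrong montage?)", call. = FALSE)
  }
  pos <- mon$coordinates[idx[located], , drop = FALSE]
  rownames(pos) <- recording$channel_labels[located]
  recording$positions <- pos
  unloc <- recording$channel_labels[!located]
  step <- if (length(unloc)) {
    paste0("montage[unlocated:", paste(unloc, collapse = ","), "]")
  } else "montage"
  add_provenance(recording, step)
}
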