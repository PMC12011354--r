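#' Read an EDF recording
#'
#' Reads a European Data Format (EDF, 16-bit) file into a
#' [new_recording()] container. Digital values are rescaled to physical
#' units via each signal's physical/digital ranges, and physical units are
#' normalized to microvolts (`mV` is scaled by 1000, `uV`/`µV` passed
#' through; unknown units are assumed uV with a warning). All selected
#' channels must share one sampling rate.
#'
#' @param path Path to the `.edf` file.
#' @param channels Optional character vector restricting which signal
#'   labels to load.
#' @return A `psg_recording` with `start_time` from the EDF header.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) {
    x <- readChar(con, n, useBytes = TRUE)
    if (nchar(x, type = "bytes") < n) {
      stop("corrupt EDF header in ", path, call. = FALSE)
    }
    trimws(x)
  }
  version <- rd(8)
  if (version != "0") stop("unsupported EDF version '", version, "'",
                           call. = FALSE)
  rd(80); rd(80)                     # patient / recording id
  rd(8)                              # start date
  start_time <- gsub("\\.", ":", rd(8))
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_records) || n_records < 1L) {
    stop("corrupt EDF header in ", path, call. = FALSE)
  }
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- field(16)
  field(80)                          # transducer
  units <- field(8)
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                          # prefilter
  spr <- as.integer(field(8))        # samples per record
  field(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    stop("corrupt EDF signal header in ", path, call. = FALSE)
  }
  seek(con, header_bytes)
  sel <- if (is.null(channels)) seq_len(ns) else {
    m <- match(toupper(channels), toupper(labels))
    if (anyNA(m)) stop("channel(s) not in EDF: ",
                       paste(channels[is.na(m)], collapse = ","),
                       call. = FALSE)
    m
  }
  if (length(unique(spr[sel])) != 1L) {
    stop("selected EDF channels have mixed sampling rates", call. = FALSE)
  }
  fs <- spr[sel[1L]] / record_dur
  raw <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * sum(spr)) {
    stop("EDF data shorter than header promises in ", path, call. = FALSE)
  }
  offs <- c(0L, cumsum(spr))
  total <- sum(spr)
  data <- matrix(0, nrow = length(sel), ncol = n_records * spr[sel[1L]])
  for (k in seq_along(sel)) {
    s <- sel[k]
    idx <- as.vector(outer(seq_len(spr[s]) + offs[s],
                           (seq_len(n_records) - 1L) * total, `+`))
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    vals <- (raw[idx] - dig_min[s]) * gain + phys_min[s]
    u <- tolower(units[s])
    if (u == "mv") {
      vals <- vals * 1000
    } else if (!u %in% c("uv", "µv", "")) {
      warning("unknown EDF unit '", units[s], "' for ", labels[s],
              "; assuming uV")
    }
    data[k, ] <- vals
  }
  new_recording(data, fs, labels[sel], start_time = start_time,
                provenance = paste0("import[edf:", basename(path), "]"))
}

#' Write a recording as EDF
#'
#' Writes 16-bit EDF with one-second data records (so the sampling rate
#' must be a positive integer and the duration a whole number of
#' seconds). Each channel's physical range is set symmetrically to its
#' absolute maximum, giving a quantization step of `2*max|x|/65535` uV.
#'
#' @param recording A `psg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer needs an integer sampling rate",
                            call. = FALSE)
  n <- n_samples(recording)
  if (n %% fs != 0) {
    stop("EDF writer needs a whole number of seconds", call. = FALSE)
  }
  n_records <- n %/% fs
  ns <- nrow(recording$data)
  phys_max <- pmax(apply(abs(recording$data), 1, max), 1)
  phys_max <- signif(phys_max * 1.0001, 6)  # keep extremes inside range
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  pad <- function(x, w) {
    x <- as.character(x)
    x <- substr(x, 1, w)
    writeChar(formatC(x, width = -w), con, eos = NULL)
  }
  pad("0", 8)
  pad("X X X X", 80)
  pad("Startdate X X X X", 80)
  pad("01.01.00", 8)
  pad(gsub(":", ".", recording$start_time), 8)
  header_bytes <- 256L + 256L * ns
  pad(header_bytes, 8)
  pad("", 44)
  pad(n_records, 8)
  pad("1", 8)
  pad(ns, 4)
  for (lab in recording$channel_labels) pad(lab, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(format(-phys_max[i]), 8)
  for (i in seq_len(ns)) pad(format(phys_max[i]), 8)
  for (i in seq_len(ns)) pad("-32768", 8)
  for (i in seq_len(ns)) pad("32767", 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(fs, 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- 65535 / (2 * phys_max)
  dig <- round((recording$data + phys_max) * gain) - 32768
  dig[dig > 32767] <- 32767L
  dig[dig < -32768] <- -32768L
  # interleave: per record, all samples of signal 1, then signal 2, ...
  out <- integer(n * ns)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, cols, drop = FALSE])
    out[((r - 1L) * fs * ns + 1L):(r * fs * ns)] <- as.integer(block)
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}
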