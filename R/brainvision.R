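#' Read a BrainVision recording
#'
#' Reads the BrainVision triplet (`.vhdr` header, `.eeg` binary data,
#' `.vmrk` markers). Supports `INT_16` and `IEEE_FLOAT_32` binary
#' formats in `MULTIPLEXED` or `VECTORIZED` orientation. Integer data are
#' scaled by each channel's resolution; units are normalized to uV
#' (1 mV = 1000 uV). Marker entries are summarized into provenance.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return A `psg_recording`.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) {
    stop("file not found: ", vhdr_path, call. = FALSE)
  }
  lines <- sub("\r$", "", readLines(vhdr_path, warn = FALSE))
  kv <- .bv_keyvals(lines)
  need <- function(key) {
    v <- kv[[tolower(key)]]
    if (is.null(v)) stop("missing ", key, " in ", vhdr_path, call. = FALSE)
    v
  }
  dir <- dirname(vhdr_path)
  data_file <- file.path(dir, need("DataFile"))
  marker_file <- kv[["markerfile"]]
  if (!file.exists(data_file)) {
    stop("BrainVision data file not found: ", data_file, call. = FALSE)
  }
  if (!identical(toupper(need("DataFormat")), "BINARY")) {
    stop("only BINARY DataFormat supported", call. = FALSE)
  }
  orientation <- toupper(need("DataOrientation"))
  if (!orientation %in% c("MULTIPLEXED", "VECTORIZED")) {
    stop("unsupported DataOrientation: ", orientation, call. = FALSE)
  }
  n_ch <- as.integer(need("NumberOfChannels"))
  fs <- 1e6 / as.numeric(need("SamplingInterval"))  # microseconds
  fmt <- toupper(need("BinaryFormat"))
  # [Channel Infos] lines: Chk=<label>,<ref>,<resolution>,<unit>
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != n_ch) {
    stop("channel info count does not match NumberOfChannels",
         call. = FALSE)
  }
  ord <- order(as.integer(sub("^Ch([0-9]+)=.*", "\\1", ch_lines)))
  ch_lines <- ch_lines[ord]
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE)
  labels <- vapply(parts, `[`, character(1), 1L)
  res <- vapply(parts, function(p) {
    if (length(p) >= 3L && nzchar(p[3L])) as.numeric(p[3L]) else 1
  }, numeric(1))
  unit <- vapply(parts, function(p) {
    if (length(p) >= 4L && nzchar(p[4L])) p[4L] else "µV"
  }, character(1))
  sz <- file.size(data_file)
  bytes_per <- if (fmt == "INT_16") 2L else if (fmt == "IEEE_FLOAT_32") 4L
    else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  n_total <- sz %/% bytes_per
  if (n_total %% n_ch != 0) {
    stop("BrainVision data size is not a multiple of the channel count",
         call. = FALSE)
  }
  n_samp <- n_total %/% n_ch
  con <- file(data_file, "rb")
  on.exit(close(con), add = TRUE)
  raw <- if (fmt == "INT_16") {
    readBin(con, "integer", n = n_total, size = 2, signed = TRUE,
            endian = "little")
  } else {
    readBin(con, "double", n = n_total, size = 4, endian = "little")
  }
  data <- if (orientation == "MULTIPLEXED") {
    matrix(raw, nrow = n_ch)            # sample-major on disk
  } else {
    t(matrix(raw, nrow = n_samp))       # channel blocks on disk
  }
  scale <- res
  is_mv <- tolower(unit) == "mv"
  scale[is_mv] <- scale[is_mv] * 1000
  data <- data * scale                  # column-recycled: rows = channels
  prov <- paste0("import[brainvision:", basename(vhdr_path), "]")
  if (!is.null(marker_file) && file.exists(file.path(dir, marker_file))) {
    mk <- readLines(file.path(dir, marker_file), warn = FALSE)
    n_mk <- sum(grepl("^Mk[0-9]+=", mk))
    prov <- c(prov, paste0("markers[", n_mk, "]"))
  }
  new_recording(data, fs, labels, provenance = prov)
}

.bv_keyvals <- function(lines) {
  kv <- list()
  for (ln in lines) {
    if (grepl("^[;\\[]", ln) || !grepl("=", ln, fixed = TRUE)) next
    eq <- regexpr("=", ln, fixed = TRUE)
    kv[[tolower(trimws(substr(ln, 1, eq - 1)))]] <-
      trimws(substr(ln, eq + 1, nchar(ln)))
  }
  kv
}
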