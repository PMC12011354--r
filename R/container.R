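# On-disk checkpoint container.
#
# Intermediate results (recordings, hypnograms, envelopes, spectra, TFRs)
# are persisted in a single self-describing binary layout:
#   magic "PSGK" | format version (int32) | payload length (int64 as
#   double) | payload (R serialization, version 3, xdr) | checksum (sum of
#   payload bytes mod 2^31, int32)
# The length and checksum make truncation and corruption detectable, and
# the version field rejects files written by an incompatible layout.

.container_magic <- charToRaw("PSGK")
.container_version <- 1L

#' Save / load an analysis object checkpoint
#'
#' `save_container()` writes any psgkit object (recording, hypnogram,
#' envelope, spectrum, TFR, ...) to a versioned, checksummed binary file;
#' `load_container()` restores it bit-identically. Loading verifies the
#' magic bytes, the format version, the stored payload length, and a
#' checksum, so truncated or corrupt files fail loudly instead of
#' deserializing garbage.
#'
#' @param obj Object to persist.
#' @param path File path (conventionally `.psgk`).
#' @return `save_container()` returns `path` invisibly; `load_container()`
#'   returns the restored object.
#' @export
save_container <- function(obj, path) {
  payload <- serialize(obj, NULL, version = 3, xdr = TRUE)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(.container_magic, con)
  writeBin(.container_version, con, size = 4, endian = "big")
  writeBin(as.double(length(payload)), con, size = 8, endian = "big")
  writeBin(payload, con)
  writeBin(.payload_checksum(payload), con, size = 4, endian = "big")
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4 || !identical(magic, .container_magic)) {
    stop("not a psgkit container: ", path, call. = FALSE)
  }
  ver <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (!identical(ver, .container_version)) {
    stop(sprintf("container version mismatch: file has %s, reader is %d",
                 ver, .container_version), call. = FALSE)
  }
  len <- readBin(con, "double", n = 1, size = 8, endian = "big")
  payload <- readBin(con, "raw", n = len)
  if (length(payload) < len) {
    stop("container truncated: ", path, call. = FALSE)
  }
  stored <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (length(stored) < 1 || stored != .payload_checksum(payload)) {
    stop("container checksum mismatch: ", path, call. = FALSE)
  }
  unserialize(payload)
}

.payload_checksum <- function(payload) {
  # chunked to keep the running sum in exact double territory
  total <- 0
  n <- length(payload)
  step <- 1e6
  for (start in seq(1, n, by = step)) {
    idx <- start:min(n, start + step - 1)
    total <- (total + sum(as.integer(payload[idx]))) %% 2147483647
  }
  as.integer(total)
}
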