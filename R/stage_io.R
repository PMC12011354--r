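#' Parse a sleep-stage notation file
#'
#' Reads a stage notation file in one of four text dialects and normalizes
#' it to a canonical [hypnogram]. All dialects score one stage per 30-s
#' epoch (configurable via `epoch_length_s`). See
#' [normalize_stage_label()] for the per-dialect label vocabularies.
#'
#' File grammars (UTF-8, LF or CRLF):
#' \describe{
#'   \item{generic_csv}{CSV with header; requires columns `epoch` (0-based)
#'     and `stage`; the canonical export adds `onset_s` and `duration_s`.}
#'   \item{hume_csv}{CSV with header `epoch,code`; `code` is the numeric
#'     stage code.}
#'   \item{remlogic_txt}{Event-list export: free header lines, a
#'     `Start Time: HH:MM:SS` line, a column-header line, then
#'     tab-separated rows `HH:MM:SS<TAB>SLEEP-Sx<TAB>duration`. Clock
#'     times are converted to seconds from the start time (wrapping past
#'     midnight).}
#'   \item{twin_txt}{Header line `Epoch<TAB>Stage`, then tab-separated
#'     rows with 1-based epoch numbers and TWin stage labels.}
#' }
#'
#' In lenient mode (`strict = FALSE`), missing epochs are filled as
#' `UNSCORED` and unknown labels map to `UNSCORED`; in strict mode either
#' is an error reporting the offending line.
#'
#' @param path Path to the notation file.
#' @param dialect One of `"generic_csv"`, `"hume_csv"`, `"remlogic_txt"`,
#'   `"twin_txt"`.
#' @param epoch_length_s Epoch length in seconds (default 30).
#' @param strict Error on gaps/unknown labels (default `TRUE`).
#' @return A [hypnogram].
#' @export
parse_hypnogram <- function(path, dialect, epoch_length_s = 30,
                            strict = TRUE) {
  dialect <- match.arg(dialect, names(.stage_dialects))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  epochs <- switch(dialect,
    generic_csv = .parse_generic_csv(lines, path),
    hume_csv = .parse_hume_csv(lines, path),
    remlogic_txt = .parse_remlogic(lines, path, epoch_length_s),
    twin_txt = .parse_twin(lines, path)
  )
  if (nrow(epochs) == 0L) stop("no stage rows in ", path, call. = FALSE)
  stages <- vapply(epochs$raw, normalize_stage_label, character(1),
                   dialect = dialect, strict = strict)
  idx <- epochs$epoch
  if (any(duplicated(idx))) {
    stop("duplicate epoch indices in ", path, call. = FALSE)
  }
  n <- max(idx) + 1L
  full <- rep(NA_character_, n)
  full[idx + 1L] <- stages
  if (anyNA(full)) {
    if (strict) {
      stop(sprintf("missing epoch(s) %s in %s",
                   paste(which(is.na(full)) - 1L, collapse = ","), path),
           call. = FALSE)
    }
    full[is.na(full)] <- "UNSCORED"
  }
  hypnogram(full, epoch_length_s)
}

.parse_generic_csv <- function(lines, path) {
  df <- .read_csv_lines(lines, path)
  need <- c("epoch", "stage")
  if (!all(need %in% names(df))) {
    stop("generic_csv needs columns epoch,stage in ", path, call. = FALSE)
  }
  data.frame(epoch = as.integer(df$epoch), raw = as.character(df$stage),
             stringsAsFactors = FALSE)
}

.parse_hume_csv <- function(lines, path) {
  df <- .read_csv_lines(lines, path)
  if (!all(c("epoch", "code") %in% names(df))) {
    stop("hume_csv needs columns epoch,code in ", path, call. = FALSE)
  }
  data.frame(epoch = as.integer(df$epoch), raw = as.character(df$code),
             stringsAsFactors = FALSE)
}

.read_csv_lines <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  out <- tryCatch(
    read.csv(text = paste(lines, collapse = "\n"), stringsAsFactors = FALSE,
             strip.white = TRUE),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  names(out) <- tolower(names(out))
  out
}

.parse_remlogic <- function(lines, path, epoch_length_s) {
  start_line <- grep("^Start Time:", lines, value = TRUE)
  if (length(start_line) != 1L) {
    stop("remlogic_txt needs exactly one 'Start Time:' line in ", path,
         call. = FALSE)
  }
  start_s <- .clock_to_s(trimws(sub("^Start Time:", "", start_line)), path, 0L)
  hdr <- grep("^Time", lines)
  if (length(hdr) == 0L) {
    stop("remlogic_txt column header line not found in ", path,
         call. = FALSE)
  }
  rows <- lines[seq(hdr[1L] + 1L, length(lines))]
  rows <- rows[nzchar(trimws(rows))]
  epochs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      stop(sprintf("malformed remlogic row at line %d of %s",
                   hdr[1L] + i, path), call. = FALSE)
    }
    t_s <- .clock_to_s(parts[1L], path, hdr[1L] + i)
    rel <- t_s - start_s
    if (rel < 0) rel <- rel + 86400  # past midnight
    ep <- rel / epoch_length_s
    if (abs(ep - round(ep)) > 1e-6) {
      stop(sprintf(
        "remlogic clock time not on the epoch grid at line %d of %s",
        hdr[1L] + i, path), call. = FALSE)
    }
    epochs[[i]] <- data.frame(epoch = as.integer(round(ep)),
                              raw = trimws(parts[2L]),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, epochs)
}

.clock_to_s <- function(txt, path, line_no) {
  m <- regmatches(txt, regexec("^([0-9]{1,2}):([0-9]{2}):([0-9]{2})$",
                               trimws(txt)))[[1L]]
  if (length(m) != 4L) {
    stop(sprintf("bad clock time '%s' at line %d of %s", txt, line_no,
                 path), call. = FALSE)
  }
  as.numeric(m[2L]) * 3600 + as.numeric(m[3L]) * 60 + as.numeric(m[4L])
}

.parse_twin <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^Epoch\t", lines)
  if (length(hdr) == 0L) {
    stop("twin_txt header 'Epoch<TAB>Stage' not found in ", path,
         call. = FALSE)
  }
  rows <- lines[seq(hdr[1L] + 1L, length(lines))]
  epochs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L || is.na(suppressWarnings(as.integer(parts[1L])))) {
      stop(sprintf("malformed twin row at line %d of %s", hdr[1L] + i,
                   path), call. = FALSE)
    }
    # TWin epochs are written 1-based
    epochs[[i]] <- data.frame(epoch = as.integer(parts[1L]) - 1L,
                              raw = trimws(parts[2L]),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, epochs)
}

#' Write a hypnogram in a given dialect
#'
#' Inverse of [parse_hypnogram()]: for every dialect,
#' `parse_hypnogram(write_hypnogram(h, ...))` returns a hypnogram equal to
#' `h` (round-trip law). The remlogic dialect needs a recording start
#' clock time to express epoch onsets as clock times.
#'
#' @param hyp A [hypnogram].
#' @param path Output path.
#' @param dialect Target dialect (see [parse_hypnogram()]).
#' @param start_time Clock time `"HH:MM:SS"` of recording start (used by
#'   `remlogic_txt`; default `"22:00:00"`).
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path, dialect, start_time = "22:00:00") {
  dialect <- match.arg(dialect, names(.stage_dialects))
  stopifnot(inherits(hyp, "hypnogram"))
  if (nrow(hyp) == 0L) stop("refusing to write an empty hypnogram",
                            call. = FALSE)
  lines <- switch(dialect,
    generic_csv = c("epoch,onset_s,duration_s,stage",
                    sprintf("%d,%g,%g,%s", hyp$epoch, hyp$onset_s,
                            hyp$duration_s, hyp$stage)),
    hume_csv = c("epoch,code",
                 sprintf("%d,%d", hyp$epoch,
                         unname(.hume_codes[hyp$stage]))),
    remlogic_txt = {
      start_s <- .clock_to_s(start_time, "<start_time>", 0L)
      clock <- .s_to_clock((start_s + hyp$onset_s) %% 86400)
      c("RemLogic Event Export",
        paste0("Start Time: ", start_time),
        "Time [hh:mm:ss]\tEvent\tDuration[s]",
        sprintf("%s\t%s\t%g", clock, unname(.remlogic_labels[hyp$stage]),
                hyp$duration_s))
    },
    twin_txt = c("Epoch\tStage",
                 sprintf("%d\t%s", hyp$epoch + 1L,
                         unname(.twin_labels[hyp$stage])))
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

.s_to_clock <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}
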