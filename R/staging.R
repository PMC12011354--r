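#' Stage/time selection specification
#'
#' Describes which part of a night an analysis should see: a set of sleep
#' stages, an optional stage-time limit ("only the first N minutes of
#' selected-stage time"), and an optional chronological clock window.
#' When both are given, the clock window is intersected with the stage
#' filter first and the stage-time limit then counts only the surviving
#' epochs, which is what "the first 30 min of N2 or N3 sleep" means.
#'
#' @param stages Non-empty character vector of canonical stage labels.
#' @param stage_time_limit_min Optional positive number of minutes of
#'   selected-stage time to keep (must be a multiple of half the epoch
#'   length, i.e. 0.5 min at 30-s epochs — epochs are never split).
#' @param chrono_window_s Optional numeric `c(start, end)` clock window in
#'   seconds from recording start (half-open).
#' @return A `stage_selection` object.
#' @export
stage_selection <- function(stages, stage_time_limit_min = NULL,
                            chrono_window_s = NULL) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("stages must be non-empty", call. = FALSE)
  bad <- setdiff(stages, stage_levels())
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ","),
                        call. = FALSE)
  if (!is.null(stage_time_limit_min) && stage_time_limit_min <= 0) {
    stop("stage_time_limit_min must be positive", call. = FALSE)
  }
  if (!is.null(chrono_window_s)) {
    stopifnot(length(chrono_window_s) == 2L,
              chrono_window_s[1L] < chrono_window_s[2L])
  }
  structure(list(stages = stages,
                 stage_time_limit_min = stage_time_limit_min,
                 chrono_window_s = chrono_window_s),
            class = "stage_selection")
}

#' Embed stage markers into a recording
#'
#' Converts a hypnogram into per-epoch signal markers: one marker at each
#' epoch-onset sample (`round(onset_s * fs)`). The hypnogram may overhang
#' the recording by less than one epoch (the trailing epoch is then
#' truncated with a warning); a full epoch of overhang is an error.
#'
#' @param recording A `psg_recording`.
#' @param hyp A [hypnogram].
#' @return A `stage_marked` object: list with `recording`, `markers`
#'   (data frame `sample_index` 0-based, `stage`), and `hypnogram`.
#' @export
embed_stage_markers <- function(recording, hyp) {
  stopifnot(inherits(recording, "psg_recording"), inherits(hyp, "hypnogram"))
  if (nrow(hyp) == 0L) stop("empty hypnogram", call. = FALSE)
  fs <- recording$fs
  el <- epoch_length(hyp)
  rec_dur <- duration_s(recording)
  hyp_end <- hyp$onset_s[nrow(hyp)] + el
  if (hyp_end - rec_dur >= el) {
    stop(sprintf(
      "hypnogram (%.0f s) exceeds recording (%.1f s) by a full epoch",
      hyp_end, rec_dur), call. = FALSE)
  }
  if (hyp_end > rec_dur + 1e-9) {
    warning("final epoch overhangs the recording and will be truncated")
  }
  markers <- data.frame(sample_index = as.integer(round(hyp$onset_s * fs)),
                        stage = hyp$stage, stringsAsFactors = FALSE)
  rec <- add_provenance(recording, "stage_markers")
  structure(list(recording = rec, markers = markers, hypnogram = hyp),
            class = "stage_marked")
}

# Sample range of epoch i (0-based), half-open [start, end), clipped to
# the recording.
.epoch_samples <- function(hyp, fs, n_total) {
  start <- as.integer(round(hyp$onset_s * fs))
  end <- pmin(as.integer(round((hyp$onset_s + hyp$duration_s) * fs)),
              n_total)
  data.frame(epoch = hyp$epoch, start = start, end = end,
             stage = hyp$stage, stringsAsFactors = FALSE)
}

# Shared epoch-selection rule: chrono window first (epochs are atomic and
# must lie fully inside the window), then stage filter, then artifact
# drop, then the stage-time limit in chronological order.
.select_epochs <- function(hyp, selection, exclude_epochs = NULL) {
  el <- epoch_length(hyp)
  keep <- hyp$stage %in% selection$stages
  if (!is.null(selection$chrono_window_s)) {
    w <- selection$chrono_window_s
    keep <- keep & hyp$onset_s >= w[1L] & (hyp$onset_s + el) <= w[2L]
  }
  if (!is.null(exclude_epochs)) keep <- keep & !(hyp$epoch %in% exclude_epochs)
  if (!is.null(selection$stage_time_limit_min)) {
    lim <- selection$stage_time_limit_min * 60
    if (abs(lim / el - round(lim / el)) > 1e-9) {
      stop(sprintf(
        "stage_time_limit_min must be a multiple of %g min (epochs are atomic)",
        el / 60), call. = FALSE)
    }
    n_keep <- as.integer(round(lim / el))
    sel_idx <- which(keep)
    if (length(sel_idx) > n_keep) keep[sel_idx[-seq_len(n_keep)]] <- FALSE
  }
  keep
}

#' Restrict a recording jointly by sleep stage and time
#'
#' The stage-time restriction engine. Epochs are filtered to the selected
#' stages (intersected with the chronological window first, if any);
#' artifact-flagged epochs are dropped; if a stage-time limit is set, the
#' surviving epochs are kept in chronological order until the limit is
#' reached (epochs are atomic and never split). Adjacent kept epochs are
#' merged into segments and the segment data concatenated, recording the
#' seam positions so downstream windowed analyses can avoid spanning
#' non-contiguous data.
#'
#' @param marked A `stage_marked` object from [embed_stage_markers()].
#' @param selection A [stage_selection()].
#' @param artifact_mask Optional artifact mask from [detect_artifacts()];
#'   an epoch flagged on any channel is dropped.
#' @return A `segment_set`: list with `segments` (data frame
#'   `start_sample`, `end_sample` half-open 0-based, `stage` of the first
#'   epoch in the run), `epochs` (kept epoch indices), `concatenated` (a
#'   `psg_recording` of the joined data), and `boundary_samples` (0-based
#'   indices into the concatenated data where non-adjacent segments abut;
#'   excludes 0).
#' @export
select_stage_time <- function(marked, selection, artifact_mask = NULL) {
  stopifnot(inherits(marked, "stage_marked"),
            inherits(selection, "stage_selection"))
  hyp <- marked$hypnogram
  rec <- marked$recording
  exclude <- NULL
  if (!is.null(artifact_mask)) {
    flagged <- apply(unclass(artifact_mask), 2, any)
    exclude <- attr(artifact_mask, "epochs")[flagged]
  }
  keep <- .select_epochs(hyp, selection, exclude)
  if (!any(keep)) {
    stop("no epochs match stages {",
         paste(selection$stages, collapse = ","), "}", call. = FALSE)
  }
  eps <- .epoch_samples(hyp, rec$fs, n_samples(rec))[keep, , drop = FALSE]
  eps <- eps[eps$end > eps$start, , drop = FALSE]  # drop fully-overhanging
  # merge sample-contiguous runs
  new_run <- c(TRUE, eps$start[-1L] != eps$end[-nrow(eps)])
  run_id <- cumsum(new_run)
  segs <- do.call(rbind, lapply(split(eps, run_id), function(d) {
    data.frame(start_sample = d$start[1L], end_sample = d$end[nrow(d)],
               stage = d$stage[1L], stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL
  lens <- segs$end_sample - segs$start_sample
  idx <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                       segs$start_sample, segs$end_sample,
                       SIMPLIFY = FALSE))
  conc <- new_recording(rec$data[, idx, drop = FALSE], rec$fs,
                        rec$channel_labels, rec$start_time,
                        rec$positions,
                        c(rec$provenance,
                          sprintf("stage_restriction[%s]",
                                  paste(selection$stages, collapse = "|"))))
  boundaries <- if (nrow(segs) > 1L) cumsum(lens)[-nrow(segs)] else integer()
  structure(list(segments = segs, epochs = eps$epoch,
                 concatenated = conc,
                 boundary_samples = as.integer(boundaries),
                 selection = selection),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments, %d samples (%.1f s) @ %g Hz\n",
              nrow(x$segments), n_samples(x$concatenated),
              duration_s(x$concatenated), x$concatenated$fs))
  invisible(x)
}

#' Export a segment table as CSV
#' @param segset A `segment_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segset, path) {
  fs <- segset$concatenated$fs
  df <- data.frame(start_s = segset$segments$start_sample / fs,
                   end_s = segset$segments$end_sample / fs,
                   stage = segset$segments$stage)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
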