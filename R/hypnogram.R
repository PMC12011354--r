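#' Construct a hypnogram
#'
#' A hypnogram is the ordered sequence of sleep stages assigned to
#' consecutive fixed-length scoring epochs (30 s by convention). It is
#' represented as a data frame with columns `epoch` (0-based index),
#' `stage` (one of [stage_levels()]), `onset_s`, and `duration_s`, plus an
#' `epoch_length_s` attribute.
#'
#' @param stages Character vector of canonical stage labels, one per epoch.
#' @param epoch_length_s Epoch length in seconds (default 30).
#' @return A `hypnogram` object.
#' @export
hypnogram <- function(stages, epoch_length_s = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), stage_levels())
  if (length(bad) > 0L) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(stages)
  out <- data.frame(
    epoch = seq_len(n) - 1L,
    stage = stages,
    onset_s = (seq_len(n) - 1) * epoch_length_s,
    duration_s = rep(epoch_length_s, n),
    stringsAsFactors = FALSE
  )
  attr(out, "epoch_length_s") <- epoch_length_s
  class(out) <- c("hypnogram", "data.frame")
  out
}

#' Epoch length of a hypnogram
#' @param hyp A [hypnogram].
#' @return Epoch length in seconds.
#' @export
epoch_length <- function(hyp) attr(hyp, "epoch_length_s")

#' Generate a hypnogram from a stage plan
#'
#' Expands an ordered stage plan (runs of identical stages) into a
#' contiguous hypnogram starting at time 0, with one entry per 30-s epoch.
#'
#' @param stage_plan Data frame with columns `stage` and `n_epochs`, or a
#'   list of `c(stage, n)` pairs.
#' @param epoch_length_s Epoch length in seconds (default 30).
#' @return A [hypnogram].
#' @export
#' @examples
#' h <- generate_hypnogram(data.frame(stage = c("W", "N2"),
#'                                    n_epochs = c(2, 4)))
#' nrow(h)        # 6
#' h$onset_s      # 0 30 60 90 120 150
generate_hypnogram <- function(stage_plan, epoch_length_s = 30) {
  plan <- as.data.frame(stage_plan, stringsAsFactors = FALSE)
  if (nrow(plan) == 0L) stop("stage_plan must be non-empty", call. = FALSE)
  stopifnot(all(c("stage", "n_epochs") %in% names(plan)))
  if (any(plan$n_epochs < 1)) stop("n_epochs must be >= 1", call. = FALSE)
  hypnogram(rep(plan$stage, plan$n_epochs), epoch_length_s)
}

#' Summarize a hypnogram
#'
#' Standard per-night summary measures: minutes in each stage, total sleep
#' time (N1 + N2 + N3 + REM), sleep onset latency (onset of the first
#' epoch that is neither wake nor movement), and wake after sleep onset.
#' Latency and WASO are `NA` when the night contains no sleep.
#'
#' @param hyp A [hypnogram].
#' @return A list with `stage_minutes` (named numeric), `total_sleep_min`,
#'   `sleep_onset_latency_min` and `waso_min`.
#' @export
hypnogram_summary <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (nrow(hyp) == 0L) stop("empty hypnogram", call. = FALSE)
  per_epoch_min <- epoch_length(hyp) / 60
  mins <- setNames(numeric(length(stage_levels())), stage_levels())
  tab <- table(hyp$stage) * per_epoch_min
  mins[names(tab)] <- as.numeric(tab)
  sleep_stages <- c("N1", "N2", "N3", "REM")
  tst <- sum(mins[sleep_stages])
  is_sleep <- hyp$stage %in% sleep_stages
  if (any(is_sleep)) {
    first <- which(is_sleep)[1L]
    latency <- hyp$onset_s[first] / 60
    after_onset <- hyp$stage[first:nrow(hyp)]
    waso <- sum(after_onset %in% c("W", "MOVEMENT")) * per_epoch_min
  } else {
    latency <- NA_real_
    waso <- NA_real_
  }
  list(stage_minutes = mins, total_sleep_min = tst,
       sleep_onset_latency_min = latency, waso_min = waso)
}

# y-axis position per stage for the step plot: deeper sleep lower
.hypnogram_y <- c(W = 5, REM = 4, N1 = 3, N2 = 2, N3 = 1,
                  MOVEMENT = 5, UNSCORED = 5)

#' Step-plot data for a hypnogram
#'
#' The y-axis orders stages by depth (top to bottom: W, REM, N1, N2, N3);
#' movement and unscored epochs are drawn at the wake level.
#'
#' @param hyp A [hypnogram].
#' @return Data frame `time_s`, `y`, `stage` with one row per epoch.
#' @keywords internal
hypnogram_steps <- function(hyp) {
  data.frame(time_s = hyp$onset_s, y = unname(.hypnogram_y[hyp$stage]),
             stage = hyp$stage, stringsAsFactors = FALSE)
}

#' Plot a hypnogram with its ribbon
#'
#' Writes a step plot of stage depth against chronological time (deeper
#' stages lower on the y-axis) with the color-coded ribbon rendering above
#' it, to PNG or SVG depending on the file extension.
#'
#' @param hyp A [hypnogram].
#' @param out_path Output file (`.png` or `.svg`).
#' @param width,height Device size in pixels (PNG) or inches (SVG).
#' @return `out_path`, invisibly.
#' @export
plot_hypnogram <- function(hyp, out_path, width = 900, height = 350) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (nrow(hyp) == 0L) stop("empty hypnogram", call. = FALSE)
  rib <- ribbon(hyp)
  steps <- hypnogram_steps(hyp)
  el <- epoch_length(hyp)
  total_s <- nrow(hyp) * el
  .open_device(out_path, width, height)
  on.exit(dev.off(), add = TRUE)
  par(mar = c(4, 4, 2, 1))
  plot.new()
  plot.window(xlim = c(0, total_s), ylim = c(0.5, 6.8))
  # ribbon band above the step trace
  rect(rib$onset_s, 6.1, rib$onset_s + el, 6.7, col = rib$color,
       border = NA)
  rect(0, 6.1, total_s, 6.7, border = "black")
  # step trace
  x <- c(rep(steps$time_s, each = 2)[-1], total_s)
  y <- rep(steps$y, each = 2)
  lines(x, y, lwd = 1.5)
  axis(1)
  axis(2, at = c(5, 4, 3, 2, 1), labels = c("W", "REM", "N1", "N2", "N3"),
       las = 1)
  title(xlab = "Time (s)", ylab = "Stage")
  invisible(out_path)
}

.open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext == "svg") {
      svg(path, width = max(4, width / 100), height = max(3, height / 100))
    } else {
      png(path, width = width, height = height)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot open graphics device for ", path, call. = FALSE)
}
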