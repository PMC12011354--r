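#' Canonical sleep stage labels
#'
#' The closed set of stage marks used throughout psgkit: wake (`W`), the
#' three NREM stages (`N1`, `N2`, `N3`), `REM`, `MOVEMENT` (movement
#' time), and `UNSCORED`. Every hypnogram parser normalizes its dialect's
#' raw labels into this set.
#'
#' @return Character vector of the seven canonical stage labels.
#' @export
stage_levels <- function() {
  c("W", "N1", "N2", "N3", "REM", "MOVEMENT", "UNSCORED")
}

# numeric stage codes used by the hume_csv dialect (legacy R&K codes:
# 4 = S4 folds into N3)
.hume_codes <- c(W = 0L, N1 = 1L, N2 = 2L, N3 = 3L, REM = 5L,
                 MOVEMENT = 7L, UNSCORED = 9L)

.remlogic_labels <- c(W = "SLEEP-S0", N1 = "SLEEP-S1", N2 = "SLEEP-S2",
                      N3 = "SLEEP-S3", REM = "SLEEP-REM",
                      MOVEMENT = "SLEEP-MT", UNSCORED = "SLEEP-UNSCORED")

.twin_labels <- c(W = "W", N1 = "1", N2 = "2", N3 = "3", REM = "REM",
                  MOVEMENT = "MT", UNSCORED = "U")

#' Normalize a raw stage label to the canonical stage set
#'
#' Each supported dialect carries its own label vocabulary; this maps a
#' raw label (case-insensitively) onto [stage_levels()]. Legacy
#' Rechtschaffen–Kales stage 4 labels (`"S4"`, hume code 4) fold into
#' `N3`, following the AASM convention.
#'
#' Dialect vocabularies:
#' \describe{
#'   \item{generic_csv}{`W`/`WAKE`, `N1`/`S1`, `N2`/`S2`, `N3`/`S3`/`S4`,
#'     `REM`/`R`, `MOVEMENT`/`MVT`/`MT`, `UNSCORED`/`U`/`?`.}
#'   \item{hume_csv}{integer codes 0 = W, 1–3 = N1–N3, 4 = N3 (legacy S4),
#'     5 = REM, 7 = MOVEMENT, 9 = UNSCORED.}
#'   \item{remlogic_txt}{`SLEEP-S0` … `SLEEP-S3`, `SLEEP-S4` (→ N3),
#'     `SLEEP-REM`, `SLEEP-MT`, `SLEEP-UNSCORED`.}
#'   \item{twin_txt}{`W`, `1`, `2`, `3`, `4` (→ N3), `REM`/`R`, `MT`, `U`.}
#' }
#'
#' @param raw_label Character (or integer code, for `hume_csv`) stage label.
#' @param dialect One of `"generic_csv"`, `"hume_csv"`, `"remlogic_txt"`,
#'   `"twin_txt"`.
#' @param strict If `TRUE` (default), an unmapped label is an error naming
#'   the label; otherwise it becomes `UNSCORED`.
#' @return A single canonical stage label.
#' @export
#' @examples
#' normalize_stage_label("Wake", "generic_csv")
#' normalize_stage_label("SLEEP-S2", "remlogic_txt")
#' normalize_stage_label("4", "hume_csv")   # legacy S4 -> N3
normalize_stage_label <- function(raw_label, dialect = "generic_csv",
                                  strict = TRUE) {
  dialect <- match.arg(dialect, names(.stage_dialects))
  key <- toupper(trimws(as.character(raw_label)))
  table <- .stage_label_tables[[dialect]]
  hit <- table[[key]]
  if (is.null(hit)) {
    if (strict) {
      stop(sprintf("unknown stage label '%s' for dialect '%s'",
                   raw_label, dialect), call. = FALSE)
    }
    return("UNSCORED")
  }
  hit
}

.stage_dialects <- list(generic_csv = "csv", hume_csv = "csv",
                        remlogic_txt = "txt", twin_txt = "txt")

.make_label_table <- function(pairs) {
  out <- list()
  for (i in seq_along(pairs)) out[[toupper(names(pairs)[i])]] <- pairs[[i]]
  out
}

.stage_label_tables <- list(
  generic_csv = .make_label_table(c(
    W = "W", WAKE = "W", N1 = "N1", S1 = "N1", N2 = "N2", S2 = "N2",
    N3 = "N3", S3 = "N3", S4 = "N3", SWS = "N3", REM = "REM", R = "REM",
    MOVEMENT = "MOVEMENT", MVT = "MOVEMENT", MT = "MOVEMENT",
    UNSCORED = "UNSCORED", U = "UNSCORED", "?" = "UNSCORED")),
  hume_csv = .make_label_table(c(
    "0" = "W", "1" = "N1", "2" = "N2", "3" = "N3", "4" = "N3",
    "5" = "REM", "7" = "MOVEMENT", "9" = "UNSCORED")),
  remlogic_txt = .make_label_table(c(
    "SLEEP-S0" = "W", "SLEEP-S1" = "N1", "SLEEP-S2" = "N2",
    "SLEEP-S3" = "N3", "SLEEP-S4" = "N3", "SLEEP-REM" = "REM",
    "SLEEP-MT" = "MOVEMENT", "SLEEP-UNSCORED" = "UNSCORED")),
  twin_txt = .make_label_table(c(
    W = "W", WAKE = "W", "1" = "N1", "2" = "N2", "3" = "N3", "4" = "N3",
    REM = "REM", R = "REM", MT = "MOVEMENT", U = "UNSCORED"))
)

#' Ribbon hypnogram color mapping
#'
#' The compact one-row hypnogram rendering codes each 30-s epoch by stage:
#' cyan = N1, grey = N2, blue = N3, green = REM, white = wake or movement.
#' Unscored epochs default to white with a hatch flag so they remain
#' distinguishable in exported ribbon data.
#'
#' @param hyp A [hypnogram] object.
#' @param unscored_color Color used for `UNSCORED` epochs (default white).
#' @return Data frame with one row per epoch: `epoch`, `onset_s`, `stage`,
#'   `color`, and logical `hatch` (TRUE only for `UNSCORED`).
#' @export
ribbon <- function(hyp, unscored_color = "white") {
  stopifnot(inherits(hyp, "hypnogram"))
  if (nrow(hyp) == 0L) stop("empty hypnogram", call. = FALSE)
  map <- c(W = "white", N1 = "cyan", N2 = "grey", N3 = "blue",
           REM = "green", MOVEMENT = "white", UNSCORED = unscored_color)
  data.frame(
    epoch = hyp$epoch,
    onset_s = hyp$onset_s,
    stage = hyp$stage,
    color = unname(map[hyp$stage]),
    hatch = hyp$stage == "UNSCORED",
    stringsAsFactors = FALSE
  )
}
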