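test_that("stage markers land on epoch-onset samples", {
  rec <- new_recording(matrix(0, 1, 100 * 90), 100, "C3")
  h <- hypnogram(c("W", "N2", "N3"))
  m <- embed_stage_markers(rec, h)
  expect_equal(m$markers$sample_index, c(0L, 3000L, 6000L))
  rec256 <- new_recording(matrix(0, 1, 256 * 90), 256, "C3")
  m2 <- embed_stage_markers(rec256, h)
  expect_equal(m2$markers$sample_index[3], 15360L)
})

test_that("hypnogram/recording length mismatches are handled", {
  rec <- new_recording(matrix(0, 1, 100 * 45), 100, "C3")
  expect_error(embed_stage_markers(rec, hypnogram(rep("N2", 3))),
               "exceeds")
  expect_warning(embed_stage_markers(rec, hypnogram(rep("N2", 2))),
                 "truncated")
  expect_error(embed_stage_markers(rec, hypnogram(character(0))), "empty")
})

test_that("stage filtering merges adjacent epochs into segments", {
  fs <- 100
  rec <- new_recording(rbind(seq_len(fs * 150)), fs, "C3")
  h <- hypnogram(c("W", "N2", "N3", "N2", "REM"))
  m <- embed_stage_markers(rec, h)
  ss <- select_stage_time(m, stage_selection(c("N2", "N3")))
  expect_equal(nrow(ss$segments), 1L)
  expect_equal(ss$segments$start_sample, 3000L)
  expect_equal(ss$segments$end_sample, 12000L)
  expect_equal(n_samples(ss$concatenated), 9000L)
  expect_length(ss$boundary_samples, 0L)
  # disjoint stages produce a seam
  h2 <- hypnogram(c("N2", "W", "N2"))
  rec2 <- new_recording(rbind(seq_len(fs * 90)), fs, "C3")
  ss2 <- select_stage_time(embed_stage_markers(rec2, h2),
                           stage_selection("N2"))
  expect_equal(ss2$boundary_samples, 3000L)
  expect_equal(n_samples(ss2$concatenated), 6000L)
})

test_that("empty selections error naming the stages", {
  rec <- new_recording(matrix(0, 1, 100 * 60), 100, "C3")
  m <- embed_stage_markers(rec, hypnogram(c("W", "W")))
  expect_error(select_stage_time(m, stage_selection("N3")), "N3")
})

test_that("selecting everything with no limits is the identity", {
  gen <- night_plain()
  ss <- select_stage_time(gen$marked, stage_selection(stage_levels()))
  expect_identical(ss$concatenated$data, gen$recording$data)
})

test_that("the 30-min N2/N3 stage-time restriction keeps exactly 60 epochs", {
  gen <- night_plain()
  sel <- stage_selection(c("N2", "N3"), stage_time_limit_min = 30)
  ss <- select_stage_time(gen$marked, sel)
  expect_length(ss$epochs, 60L)
  expect_equal(n_samples(ss$concatenated), 1800L * gen$recording$fs)
  # the kept epochs are the chronologically first 60 selected ones
  all_sel <- which(gen$truth$hypnogram$stage %in% c("N2", "N3")) - 1L
  expect_equal(ss$epochs, all_sel[1:60])
})

test_that("stage-time limits are monotone and epoch-atomic", {
  gen <- night_plain()
  kept <- lapply(c(5, 10, 30), function(lim) {
    select_stage_time(gen$marked,
                      stage_selection(c("N2", "N3"),
                                      stage_time_limit_min = lim))$epochs
  })
  expect_true(all(kept[[1]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[3]]))
  expect_error(
    select_stage_time(gen$marked,
                      stage_selection("N2", stage_time_limit_min = 0.25)),
    "multiple")
})

test_that("segment extraction equals the brute-force per-sample mask", {
  set.seed(77)
  fs <- 32
  for (rep in 1:50) {
    h <- random_hypnogram(sample(4:20, 1))
    n <- nrow(h) * 30 * fs
    rec <- new_recording(rbind(rnorm(n)), fs, "C3")
    m <- embed_stage_markers(rec, h)
    stages <- sample(stage_levels(), sample(1:3, 1))
    lim <- if (runif(1) < 0.5) sample(1:10, 1) * 0.5 else NULL
    win <- if (runif(1) < 0.3) sort(sample(0:nrow(h), 2)) * 30 else NULL
    if (!is.null(win) && win[1] == win[2]) win <- NULL
    sel <- stage_selection(stages, stage_time_limit_min = lim,
                           chrono_window_s = win)
    mask <- oracle_stage_mask(h, sel, fs, n)
    res <- tryCatch(select_stage_time(m, sel), error = function(e) NULL)
    if (is.null(res)) {
      expect_equal(sum(mask), 0)
    } else {
      expect_identical(res$concatenated$data[1, ],
                       rec$data[1, mask])
    }
  }
})

test_that("artifact-flagged epochs are dropped from the selection", {
  fs <- 100
  x <- rep(0, fs * 90)
  x[fs * 40] <- 500  # spike in epoch 1
  rec <- new_recording(rbind(x), fs, "C3")
  h <- hypnogram(rep("N2", 3))
  m <- embed_stage_markers(rec, h)
  mask <- detect_artifacts(rec, m, threshold_uv = 300)
  expect_equal(as.vector(unclass(mask)), c(FALSE, TRUE, FALSE))
  ss <- select_stage_time(m, stage_selection("N2"), artifact_mask = mask)
  expect_equal(ss$epochs, c(0L, 2L))
  expect_equal(n_samples(ss$concatenated), 6000L)
})

test_that("segment table exports in seconds", {
  fs <- 100
  rec <- new_recording(rbind(seq_len(fs * 90)), fs, "C3")
  ss <- select_stage_time(embed_stage_markers(rec, hypnogram(
    c("N2", "W", "N3"))), stage_selection(c("N2", "N3")))
  p <- withr::local_tempfile(fileext = ".csv")
  write_segments_csv(ss, p)
  tab <- read.csv(p)
  expect_equal(tab$start_s, c(0, 60))
  expect_equal(tab$end_s, c(30, 90))
})
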