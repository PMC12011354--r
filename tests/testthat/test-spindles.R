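test_that("detection at the 2/6 thresholds recovers exactly the true events", {
  gen <- night_with_spindles()
  det <- detect_spindles(gen$recording, gen$marked)
  truth <- gen$true_events
  # precision: every detection overlaps a true event
  matched_det <- logical(nrow(det))
  matched_truth <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- det$channel == truth$channel[i] &
      det$onset_s < truth$onset_s[i] + truth$duration_s[i] &
      det$offset_s > truth$onset_s[i]
    matched_truth[i] <- sum(hit) == 1L
    matched_det <- matched_det | hit
  }
  expect_equal(sum(matched_truth), nrow(truth))  # recall = 1
  expect_equal(sum(matched_det), nrow(det))      # precision = 1
  expect_equal(nrow(det), nrow(truth))
  # events sorted by onset, invariants hold
  expect_true(!is.unsorted(det$onset_s))
  expect_true(all(det$onset_s <= det$peak_s & det$peak_s <= det$offset_s))
  expect_true(all(det$duration_s >= 0.5 & det$duration_s <= 3))
  expect_true(all(det$stage %in% c("N2", "N3")))
})

test_that("onsets and offsets match the threshold-crossing oracle", {
  gen <- night_with_spindles()
  det <- detect_spindles(gen$recording, gen$marked)
  fs <- gen$recording$fs
  for (ch in c("C3", "C4")) {
    oracle <- oracle_spindles_channel(gen$recording,
                                      gen$truth$hypnogram, ch)
    mine <- det[det$channel == ch, ]
    expect_equal(nrow(mine), nrow(oracle))
    expect_true(all(abs(round(mine$onset_s * fs) -
                          oracle$onset_sample) <= 2))
    expect_true(all(abs(round(mine$offset_s * fs) -
                          oracle$offset_sample) <= 2))
  }
})

test_that("sub-threshold and too-short bursts are rejected", {
  spec0 <- synth_spec(seed = 31)
  ev4 <- place_spindle_events(spec0$hypnogram, 6, "C3",
                              peak_multiplier = 4, stride = 3)
  short <- place_spindle_events(spec0$hypnogram, 6, "C4",
                                peak_multiplier = 8, duration_s = 0.2,
                                stride = 3)
  gen <- generate_recording(synth_spec(spindle_events = rbind(ev4, short),
                                       seed = 31))
  marked <- embed_stage_markers(gen$recording, gen$truth$hypnogram)
  det <- detect_spindles(gen$recording, marked)
  expect_equal(nrow(det), 0L)
})

test_that("raising the upper threshold never adds events", {
  gen <- night_with_spindles()
  counts <- sapply(c(4, 6, 8), function(u) {
    nrow(detect_spindles(gen$recording, gen$marked,
                         spindle_params(upper_mult = u)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("the event list is invariant to global amplitude rescaling", {
  gen <- night_with_spindles()
  det1 <- detect_spindles(gen$recording, gen$marked)
  scaled <- new_recording(gen$recording$data * 3.7, gen$recording$fs,
                          gen$recording$channel_labels)
  marked2 <- embed_stage_markers(scaled, gen$truth$hypnogram)
  det2 <- detect_spindles(scaled, marked2)
  expect_equal(det2$onset_s, det1$onset_s)
  expect_equal(det2$offset_s, det1$offset_s)
  expect_equal(det2$channel, det1$channel)
  expect_equal(det2$peak_amplitude_uv, det1$peak_amplitude_uv * 3.7,
               tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  fs <- 128
  rec <- new_recording(matrix(0, 1, fs * 60), fs, "C3")
  m <- embed_stage_markers(rec, hypnogram(c("N2", "N2")))
  expect_error(detect_spindles(rec, m), "degenerate|baseline")
  m_w <- embed_stage_markers(rec, hypnogram(c("W", "W")))
  expect_error(detect_spindles(rec, m_w), "no data in stages")
})

test_that("density is events per minute of selected-stage time", {
  gen <- night_with_spindles()
  det <- detect_spindles(gen$recording, gen$marked)
  dens <- spindle_density(det, gen$truth$hypnogram)
  # 90 N2/N3 epochs = 45 min
  expect_equal(unique(dens$stage_minutes), 45)
  expect_equal(dens$n_events[dens$channel == "C3"], 10L)
  expect_equal(dens$density_per_min[dens$channel == "C3"], 10 / 45)
  # zero-event channels report density 0 and missing means
  f3 <- dens[dens$channel == "F3", ]
  expect_equal(f3$density_per_min, 0)
  expect_true(is.na(f3$mean_duration_s))
  expect_error(spindle_density(det, gen$truth$hypnogram,
                               stages = "UNSCORED"), "zero minutes")
})

test_that("the spindle overview figure is written with event boxes", {
  gen <- night_with_spindles()
  det <- detect_spindles(gen$recording, gen$marked)
  p <- withr::local_tempfile(fileext = ".png")
  plot_spindle_overview(gen$recording, det, "C3", p, max_zoom = 2)
  expect_true(file.exists(p) && file.size(p) > 0)
  expect_error(plot_spindle_overview(gen$recording, det, "Qz",
                                     tempfile()), "unknown channel")
  # zero events still renders
  p2 <- withr::local_tempfile(fileext = ".png")
  plot_spindle_overview(gen$recording, det[0, ], "F3", p2)
  expect_true(file.exists(p2))
})
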