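test_that("synth specs validate their invariants", {
  expect_error(synth_spec(stage_plan = data.frame(stage = "NAP",
                                                  n_epochs = 2)),
               "unknown stage")
  expect_error(synth_spec(fs = 20), "twice the highest band edge")
  # spindle events must lie inside N2/N3 epochs of the plan
  plan <- data.frame(stage = c("W", "N2"), n_epochs = c(2, 2))
  bad_ev <- data.frame(channel = "C3", onset_s = 10, duration_s = 1,
                       peak_multiplier = 7)
  expect_error(synth_spec(stage_plan = plan, spindle_events = bad_ev),
               "N2/N3")
  late_ev <- data.frame(channel = "C3", onset_s = 200, duration_s = 1,
                        peak_multiplier = 7)
  expect_error(synth_spec(stage_plan = plan, spindle_events = late_ev),
               "outside the recording")
})

test_that("a fixed seed reproduces the recording bit-identically", {
  spec <- synth_spec(stage_plan = data.frame(stage = c("N2", "N3"),
                                             n_epochs = c(2, 2)),
                     seed = 99)
  g1 <- generate_recording(spec)
  g2 <- generate_recording(spec)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$truth$baseline_uv, g2$truth$baseline_uv)
  g3 <- generate_recording(synth_spec(
    stage_plan = data.frame(stage = c("N2", "N3"), n_epochs = c(2, 2)),
    seed = 100))
  expect_false(identical(g1$recording$data, g3$recording$data))
})

test_that("noise-free generation yields pure stage-dependent tones", {
  spec <- synth_spec(
    stage_plan = data.frame(stage = c("W", "N3"), n_epochs = c(1, 1)),
    channel_labels = "C3",
    band_amplitudes = list(N3 = c(delta = 4)),
    noise_sd = 0, seed = 1)
  gen <- generate_recording(spec)
  fs <- spec$fs
  w_part <- gen$recording$data[1, 1:(30 * fs)]
  n3_part <- gen$recording$data[1, (30 * fs + 1):(60 * fs)]
  expect_equal(max(abs(w_part)), 0)
  expect_equal(max(abs(n3_part)), 4, tolerance = 1e-3)
  # a 4 uV tone at the delta center frequency
  sp <- stats::spec.pgram(n3_part, plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)] * fs, 2.25, tolerance = 0.05)
})

test_that("injected spindles honor the peak-multiplier ground truth", {
  gen <- night_with_spindles()
  ev <- gen$truth$spindle_events
  expect_equal(nrow(ev), 40L)
  expect_true(all(!is.na(ev$peak_amplitude_uv)))
  # realized peak = multiplier x per-channel baseline
  expect_equal(ev$peak_amplitude_uv,
               ev$peak_multiplier * ev$baseline_uv, tolerance = 1e-12)
  # every truth onset lies inside an N2/N3 epoch
  hyp <- gen$truth$hypnogram
  stage_at <- hyp$stage[floor(ev$onset_s / 30) + 1]
  expect_true(all(stage_at %in% c("N2", "N3")))
})

test_that("stage-conditional spectra separate injected from absent bands", {
  gen <- night_plain()
  amps <- gen$truth$band_amplitudes
  expect_gt(amps$N3[["delta"]], 3 * 5)  # >= 3x noise_sd: testable regime
  sp_n3 <- amplitude_spectrum(
    select_stage_time(gen$marked, stage_selection("N3")), window_s = 4)
  sp_w <- amplitude_spectrum(
    select_stage_time(gen$marked, stage_selection("W")), window_s = 4)
  i <- which.min(abs(sp_n3$freqs_hz - 2.25))
  expect_gt(min(sp_n3$amplitude[, i] / sp_w$amplitude[, i]), 1.5)
})

test_that("fixtures round-trip through EDF and every hypnogram dialect", {
  spec <- synth_spec(stage_plan = data.frame(
    stage = c("W", "N2", "N3"), n_epochs = c(1, 3, 2)), seed = 5)
  gen <- generate_recording(spec)
  for (d in c("generic_csv", "hume_csv", "remlogic_txt", "twin_txt")) {
    out <- withr::local_tempdir()
    paths <- write_fixture(gen$recording, gen$truth$hypnogram, d, out,
                           truth = gen$truth)
    expect_true(all(file.exists(paths)))
    r2 <- read_edf(paths[["edf"]])
    quant <- 2 * max(abs(gen$recording$data)) / 65535
    expect_lt(max(abs(r2$data - gen$recording$data)), quant)
    h2 <- parse_hypnogram(paths[["hypnogram"]], d)
    expect_equal(h2$stage, gen$truth$hypnogram$stage)
    # manifest lists every injected event (none here) and baselines
    manifest <- jsonlite::read_json(paths[["truth"]],
                                    simplifyVector = TRUE)
    expect_named(manifest, c("spindle_events", "baseline_uv",
                             "stage_plan"), ignore.order = TRUE)
  }
  # EDF has fs samples per second per channel
  out <- withr::local_tempdir()
  paths <- write_fixture(gen$recording, gen$truth$hypnogram,
                         "generic_csv", out)
  r2 <- read_edf(paths[["edf"]])
  expect_equal(ncol(r2$data), spec$duration_s * spec$fs)
  expect_error(write_fixture(gen$recording, gen$truth$hypnogram,
                             "xml", out), "arg")
})
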