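test_that("the envelope of a band-center tone is its amplitude", {
  fs <- 128
  rec <- tone_recording(14, amplitude = 5, fs = fs, dur_s = 60)
  filt <- bandpass(rec, band_spec("sigma", 12, 16))
  env <- hilbert_envelope(filt)
  inner <- (2 * fs):(58 * fs)
  expect_equal(mean(env$data[1, inner]), 5, tolerance = 0.01)
  expect_lt(max(abs(env$data[1, inner] - 5)) / 5, 0.01)
  # zero in, zero out
  z <- new_recording(matrix(0, 1, fs * 10), fs, "C3")
  expect_equal(max(hilbert_envelope(z)$data), 0)
})

test_that("the envelope tracks slow amplitude modulation", {
  fs <- 128
  t <- (0:(fs * 120 - 1)) / fs
  A <- 3 + 2 * sin(2 * pi * 0.2 * t)
  rec <- new_recording(rbind(A * sin(2 * pi * 10 * t)), fs, "C3")
  env <- hilbert_envelope(bandpass(rec, band_spec("alpha", 8, 12)))
  inner <- (5 * fs):(115 * fs)
  rel_rms <- sqrt(mean((env$data[1, inner] - A[inner])^2)) /
    sqrt(mean(A[inner]^2))
  expect_lt(rel_rms, 0.05)
})

test_that("the envelope dominates the signal at tone peaks", {
  fs <- 128
  rec <- tone_recording(14, amplitude = 2, fs = fs, dur_s = 30)
  filt <- bandpass(rec, band_spec("sigma", 12, 16))
  env <- hilbert_envelope(filt)
  inner <- (2 * fs):(28 * fs)
  expect_true(all(env$data[1, inner] >=
                    abs(filt$data[1, inner]) - 1e-6))
})

test_that("envelope summaries aggregate channels, groups, selections", {
  fs <- 64
  n <- fs * 120
  hyp <- hypnogram(c("N2", "N2", "W", "N3"))
  labs <- c("F3", "F4", "C3", "C4", "O1")
  env <- structure(list(
    data = matrix(rep(1:5, times = n), nrow = 5,
                  dimnames = list(labs, NULL)),
    fs = fs, band = NULL, hypnogram = hyp, edge_s = 2,
    channel_labels = labs), class = "envelope")
  su <- envelope_summary(env, stage_selection(c("N2", "N3")),
                         channel_groups = list(
                           frontocentral = c("F3", "F4", "C3", "C4")))
  chan_rows <- su$summary[su$summary$kind == "channel", ]
  expect_equal(chan_rows$mean_uv, 1:5)
  expect_equal(chan_rows$sd_uv, rep(0, 5))
  grp <- su$summary[su$summary$kind == "group", ]
  expect_equal(grp$mean_uv, mean(1:4))
  # selected samples = 3 epochs x 30 s x fs
  expect_equal(unique(su$summary$n_samples), 3 * 30 * fs)
  expect_error(envelope_summary(env, stage_selection("REM")), "REM")
  expect_error(
    envelope_summary(env, stage_selection("N2"),
                     channel_groups = list(g = "Pz")), "Pz")
})

test_that("the first-30-min selection averages exactly the chosen epochs", {
  gen <- night_plain()
  sigma <- default_bands()$sigma
  filt <- bandpass(gen$recording, sigma)
  env <- hilbert_envelope(filt, hyp = gen$truth$hypnogram, band = sigma)
  sel <- stage_selection(c("N2", "N3"), stage_time_limit_min = 30)
  su <- envelope_summary(env, sel)
  # cross-check against the staging engine's own sample selection
  ss <- select_stage_time(gen$marked, sel)
  expect_equal(unique(su$summary$n_samples), n_samples(ss$concatenated))
  fs <- env$fs
  eps <- ss$epochs
  idx <- unlist(lapply(eps, function(e) (e * 30 * fs + 1):((e + 1) * 30 * fs)))
  manual <- mean(env$data["C3", idx])
  expect_equal(su$summary$mean_uv[su$summary$name == "C3"], manual)
})

test_that("stage-dependent band amplitudes show up in the envelope", {
  gen <- night_plain()
  delta <- default_bands()$delta
  env <- hilbert_envelope(bandpass(gen$recording, delta),
                          hyp = gen$truth$hypnogram, band = delta)
  m_n3 <- envelope_summary(env, stage_selection("N3"))$summary
  m_w <- envelope_summary(env, stage_selection("W"))$summary
  expect_gt(m_n3$mean_uv[m_n3$name == "C3"],
            2 * m_w$mean_uv[m_w$name == "C3"])
})

test_that("the TFR ridge follows stationary tones and chirps", {
  fs <- 128
  t <- (0:(fs * 120 - 1)) / fs
  rec6 <- new_recording(rbind(sin(2 * pi * 6 * t)), fs, "C3")
  tfr <- morlet_tfr(rec6, freqs_hz = c(2, 4, 6, 8, 10, 12),
                    time_step_s = 1)
  ridge <- tfr$freqs_hz[apply(tfr$amplitude[1, , ], 2, which.max)]
  inner <- 6:115
  expect_true(all(ridge[inner] == 6))
  # linear chirp 2 -> 12 Hz: ridge is monotone non-decreasing
  chirp <- sin(2 * pi * (2 * t + (12 - 2) / (2 * 120) * t^2))
  tfrc <- morlet_tfr(new_recording(rbind(chirp), fs, "C3"),
                     freqs_hz = seq(2, 12, by = 1), time_step_s = 5)
  rc <- tfrc$freqs_hz[apply(tfrc$amplitude[1, , ], 2, which.max)]
  rc <- rc[2:(length(rc) - 1)]
  expect_true(all(diff(rc) >= 0))
  expect_gt(max(rc) - min(rc), 5)
  # zero in, zero out
  z <- new_recording(matrix(0, 1, fs * 60), fs, "C3")
  expect_equal(max(morlet_tfr(z, freqs_hz = c(4, 8),
                              time_step_s = 1)$amplitude), 0)
})

test_that("overlong wavelets are rejected", {
  fs <- 128
  rec <- new_recording(matrix(0, 1, fs * 4), fs, "C3")
  expect_error(morlet_tfr(rec, freqs_hz = 0.3, n_cycles = 10),
               "longer than")
})
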