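amp_mid <- function(x) {
  n <- length(x)
  max(abs(x[round(n * 0.2):round(n * 0.8)]))
}

test_that("downsampling preserves in-band tones and kills aliases", {
  fs0 <- 500
  t <- (0:(fs0 * 30 - 1)) / fs0
  rec <- new_recording(rbind(sin(2 * pi * 5 * t),
                             sin(2 * pi * 60 * t)), fs0, c("A", "B"))
  rd <- downsample(rec, 100)
  expect_equal(rd$fs, 100)
  expect_equal(ncol(rd$data), 3000L)
  expect_equal(amp_mid(rd$data[1, ]), 1, tolerance = 0.01)
  expect_lt(amp_mid(rd$data[2, ]), 0.01)
  # no-op and error cases
  expect_match(tail(downsample(rec, fs0)$provenance, 1), "skip")
  expect_error(downsample(rec, 1000), "exceed")
})

test_that("re-referencing schemes satisfy their algebraic identities", {
  set.seed(9)
  d <- matrix(rnorm(4 * 500), 4)
  d[3, ] <- d[4, ]  # M1 == M2
  rec <- new_recording(d, 100, c("C3", "C4", "M1", "M2"))
  ra <- rereference(rec, "average")
  expect_lt(max(abs(colSums(ra$data))), 1e-9)
  rs <- rereference(rec, "single", channels = "C4")
  expect_equal(max(abs(rs$data[2, ])), 0)
  rl <- rereference(rec, "linked", channels = c("M1", "M2"))
  expect_equal(rl$data[1, ], d[1, ] - d[3, ], tolerance = 1e-12)
  expect_identical(rereference(rec, "none")$data, rec$data)
  expect_error(rereference(rec, "single", channels = "Oz"), "not found")
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  mon <- standard_montage()
  chans <- setdiff(rownames(mon$coordinates), c("M1", "M2"))
  pos <- mon$coordinates[chans, ]
  # constant field: interpolation must be exact
  recc <- attach_montage(new_recording(matrix(7, length(chans), 50), 100,
                                       chans))
  rc <- interpolate_bad_channels(recc, "Cz")
  expect_equal(rc$data[match("Cz", chans), ], rep(7, 50),
               tolerance = 1e-6)
  # good channels untouched
  expect_identical(rc$data[match("F3", chans), ], recc$data[
    match("F3", chans), ])
  # smooth dipolar field, one channel held out
  dip <- c(0.3, 0.8, 0.52)
  dip <- dip / sqrt(sum(dip^2))
  vals <- as.numeric(exp(2 * (pos %*% dip - 1)))
  sig <- outer(vals, sin(2 * pi * 3 * (0:255) / 128)) * 30
  rec <- attach_montage(new_recording(sig, 128, chans))
  for (held in c("C3", "Fz", "Pz")) {
    r2 <- interpolate_bad_channels(rec, held)
    i <- match(held, chans)
    rel <- sqrt(mean((r2$data[i, ] - sig[i, ])^2)) /
      sqrt(mean(sig[i, ]^2))
    expect_lt(rel, 0.15)
  }
  expect_error(interpolate_bad_channels(rec, "Qz"), "not in recording")
  few <- attach_montage(new_recording(matrix(0, 3, 10), 100,
                                      c("C3", "C4", "Cz")))
  expect_error(interpolate_bad_channels(few, "Cz"), "at least 4")
})

test_that("band-pass filters meet passband and stopband requirements", {
  fs <- 128
  delta <- band_spec("delta", 0.5, 4)
  sigma <- band_spec("sigma", 12, 16)
  t2 <- tone_recording(2, fs = fs)
  t14 <- tone_recording(14, fs = fs)
  t26 <- tone_recording(26, fs = fs)
  # delta passes 2 Hz within 5%, attenuates 14 Hz by >= 40 dB
  expect_equal(amp_mid(bandpass(t2, delta)$data[1, ]), 1,
               tolerance = 0.05)
  expect_lt(amp_mid(bandpass(t14, delta)$data[1, ]), 10^(-40 / 20))
  # sigma passes 14 Hz, attenuates 2 Hz and 26 Hz by >= 40 dB
  expect_equal(amp_mid(bandpass(t14, sigma)$data[1, ]), 1,
               tolerance = 0.05)
  expect_lt(amp_mid(bandpass(t2, sigma)$data[1, ]), 10^(-40 / 20))
  expect_lt(amp_mid(bandpass(t26, sigma)$data[1, ]), 10^(-40 / 20))
})

test_that("theta Chebyshev II design meets its 40 dB stopband spec", {
  theta <- default_bands()$theta
  expect_equal(theta$design, "chebyshev2")
  resp <- filter_response(theta, fs = 128)
  stop_idx <- resp$freq_hz <= (theta$low_hz - theta$transition_hz) |
    resp$freq_hz >= (theta$high_hz + theta$transition_hz)
  # single-pass attenuation within numerical evaluation error of spec
  expect_lt(max(resp$gain[stop_idx]), 10^(-39.99 / 20))
  # passband center passes
  mid_idx <- which.min(abs(resp$freq_hz - 6))
  expect_equal(resp$gain[mid_idx], 1, tolerance = 0.05)
})

test_that("filtering is zero-phase and near-idempotent in the passband", {
  fs <- 128
  sigma <- band_spec("sigma", 12, 16)
  rec <- tone_recording(14, fs = fs, dur_s = 60)
  y1 <- bandpass(rec, sigma)
  # zero lag: cross-correlation of input and output peaks at 0
  n <- n_samples(rec)
  mid <- (fs * 10):(fs * 50)
  ccf_vals <- sapply(-5:5, function(lag) {
    sum(rec$data[1, mid] * y1$data[1, mid + lag])
  })
  expect_equal(which.max(ccf_vals), 6L)  # lag 0
  # idempotence at band center within 5%
  y2 <- bandpass(y1, sigma)
  expect_equal(amp_mid(y2$data[1, ]), amp_mid(y1$data[1, ]),
               tolerance = 0.05)
})

test_that("invalid or unstable filter designs are rejected", {
  expect_error(band_spec("bad", 8, 4))
  rec <- tone_recording(2, fs = 100, dur_s = 10)
  expect_error(bandpass(rec, band_spec("wide", 1, 60)), "Nyquist")
})

test_that("artifact detection flags only epochs exceeding the threshold", {
  fs <- 100
  x <- rep(0, fs * 90)
  rec0 <- new_recording(rbind(x), fs, "C3")
  m0 <- embed_stage_markers(rec0, hypnogram(rep("N2", 3)))
  expect_false(any(unclass(detect_artifacts(rec0, m0, 50))))
  x[fs * 35] <- 500
  rec <- new_recording(rbind(x), fs, "C3")
  m <- embed_stage_markers(rec, hypnogram(rep("N2", 3)))
  mask <- detect_artifacts(rec, m, 300)
  expect_equal(as.vector(unclass(mask)), c(FALSE, TRUE, FALSE))
  expect_false(any(unclass(detect_artifacts(rec, m, Inf))))
})

test_that("custom hooks are contract-checked", {
  rec <- tone_recording(5, fs = 100, dur_s = 5)
  same <- run_custom_hook(rec, identity, hook_name = "id")
  expect_identical(same$data, rec$data)
  expect_match(tail(same$provenance, 1), "custom_hook")
  doubled <- run_custom_hook(rec, function(r) {
    r$data <- r$data * 2
    r
  }, hook_name = "x2")
  expect_identical(doubled$data, rec$data * 2)
  dropper <- function(r) {
    new_recording(r$data[-1, , drop = FALSE], r$fs,
                  r$channel_labels[-1])
  }
  expect_error(run_custom_hook(rec, dropper), "without declaring")
})
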