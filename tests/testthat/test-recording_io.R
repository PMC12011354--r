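test_that("EDF write/read round-trips within 16-bit quantization", {
  set.seed(3)
  fs <- 100
  data <- rbind(100 * sin(2 * pi * 2 * (0:(fs * 60 - 1)) / fs),
                rnorm(fs * 60, sd = 40))
  rec <- new_recording(data, fs, c("C3", "C4"), start_time = "23:15:00")
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  r2 <- read_edf(p)
  expect_equal(dim(r2$data), c(2L, 6000L))
  expect_equal(r2$fs, fs)
  expect_equal(r2$channel_labels, c("C3", "C4"))
  expect_equal(r2$start_time, "23:15:00")
  quant <- 2 * max(abs(data)) / 65535
  expect_lt(max(abs(r2$data - data)), quant)
})

test_that("EDF scaling follows the physical/digital linear law", {
  # one channel whose extremes touch the digital range
  fs <- 10
  x <- seq(-1000, 1000, length.out = fs * 10)
  rec <- new_recording(rbind(x), fs, "Pz")
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  r2 <- read_edf(p)
  expect_equal(max(r2$data), 1000, tolerance = 1e-3)
  expect_equal(min(r2$data), -1000, tolerance = 1e-3)
})

test_that("EDF reader rejects non-EDF and truncated files", {
  p <- withr::local_tempfile()
  writeLines("this is not an edf", p)
  expect_error(read_edf(p), "EDF")
  expect_error(read_edf(tempfile()), "not found")
})

test_that("BrainVision INT_16 multiplexed reads with resolution scaling", {
  set.seed(4)
  # channel 1 holds multiples of its 0.1 resolution, channel 2 integers
  dat <- rbind(sample(-500:500, 400, TRUE) * 0.1,
               as.numeric(sample(-500:500, 400, TRUE)))
  dir <- withr::local_tempdir()
  vhdr <- write_bv_fixture(dir, dat, fs = 200, labels = c("Fz", "Cz"),
                           resolutions = c(0.1, 1))
  # on disk the first channel is stored as integers dat/0.1
  rec <- read_brainvision(vhdr)
  expect_equal(rec$fs, 200)
  expect_equal(dim(rec$data), c(2L, 400L))
  expect_equal(rec$channel_labels, c("Fz", "Cz"))
  expect_equal(rec$data[1, ], dat[1, ])
  expect_equal(rec$data[2, ], dat[2, ])
  # digital value x resolution: raw 10 at 0.1 uV/bit reads as 1.0 uV
  raw10 <- matrix(1.0, 1, 4)
  vhdr2 <- write_bv_fixture(dir, raw10, fs = 100, labels = "Pz",
                            resolutions = 0.1, base = "fix2")
  stored <- readBin(file.path(dir, "fix2.eeg"), "integer", 4, size = 2,
                    endian = "little")
  expect_equal(stored, rep(10L, 4))
  expect_equal(as.vector(read_brainvision(vhdr2)$data), rep(1, 4))
})

test_that("BrainVision float32 vectorized and mV units read correctly", {
  dat <- matrix(round(rnorm(3 * 100), 3), 3)
  dir <- withr::local_tempdir()
  vhdr <- write_bv_fixture(dir, dat, fs = 100,
                           labels = c("F3", "F4", "O1"),
                           format = "IEEE_FLOAT_32",
                           orientation = "VECTORIZED",
                           units = c("µV", "mV", "µV"))
  rec <- read_brainvision(vhdr)
  expect_equal(rec$data[1, ], dat[1, ], tolerance = 1e-6)
  expect_equal(rec$data[2, ], dat[2, ] * 1000, tolerance = 1e-6)
  expect_equal(rec$data[3, ], dat[3, ], tolerance = 1e-6)
})

test_that("BrainVision missing companion data file is a named error", {
  dir <- withr::local_tempdir()
  vhdr <- write_bv_fixture(dir, matrix(0, 1, 10), fs = 100, labels = "Cz")
  unlink(file.path(dir, "fix.eeg"))
  expect_error(read_brainvision(vhdr), "fix.eeg")
})

test_that("container round-trip is bit-exact and integrity-checked", {
  gen <- night_plain()
  rec <- gen$recording
  p <- withr::local_tempfile(fileext = ".psgk")
  save_container(rec, p)
  r2 <- load_container(p)
  expect_identical(r2$data, rec$data)
  expect_identical(r2$provenance, rec$provenance)
  # truncation is detected
  sz <- file.size(p)
  raw <- readBin(p, "raw", sz)
  p_tr <- withr::local_tempfile()
  writeBin(raw[1:(sz - 100)], p_tr)
  expect_error(load_container(p_tr), "truncated|checksum")
  # corruption is detected
  raw2 <- raw
  raw2[200] <- as.raw(bitwXor(as.integer(raw2[200]), 255L))
  p_cor <- withr::local_tempfile()
  writeBin(raw2, p_cor)
  expect_error(load_container(p_cor), "checksum|truncated")
  # wrong magic
  p_bad <- withr::local_tempfile()
  writeBin(charToRaw("NOPEnope"), p_bad)
  expect_error(load_container(p_bad), "not a psgkit container")
})

test_that("montage attaches frontocentral channels and skips non-EEG", {
  rec <- new_recording(matrix(0, 5, 10), 100,
                       c("F3", "F4", "c3", "C4", "EMG1"))
  rec <- attach_montage(rec)
  expect_setequal(rownames(rec$positions), c("F3", "F4", "c3", "C4"))
  # positions are unit-norm
  expect_equal(unname(sqrt(rowSums(rec$positions^2))), rep(1, 4),
               tolerance = 1e-9)
  expect_match(tail(rec$provenance, 1), "unlocated:EMG1")
  expect_error(attach_montage(new_recording(matrix(0, 1, 5), 10, "X99")),
               "wrong montage")
})
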