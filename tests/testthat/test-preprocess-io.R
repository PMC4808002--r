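test_that("text round trip preserves a record within text rounding", {
  rec <- make_tiny_record()
  tf <- withr::local_tempfile(fileext = ".txt")
  write_eeg_text(rec, tf)
  rec2 <- read_eeg_text(tf)
  expect_equal(rec2$fs, rec$fs)
  expect_equal(dim(rec2$data), dim(rec$data))
  expect_lt(max(abs(rec2$data - rec$data)), 1e-9)
  # body shape: rows = samples, columns = channels
  lines <- readLines(tf)
  expect_length(lines, ncol(rec$data) + 1L)
  expect_length(strsplit(trimws(lines[2]), " +")[[1]], nrow(rec$data))
})

test_that("header and duration arithmetic are honoured on read", {
  tf <- withr::local_tempfile(fileext = ".txt")
  set.seed(2)
  writeLines(c("# fs=256 channels=24",
               apply(matrix(rnorm(24 * 100), nrow = 100), 1,
                     paste, collapse = " ")), tf)
  rec <- read_eeg_text(tf)
  expect_equal(nrow(rec$data), 24)
  expect_equal(ncol(rec$data), 100)
  expect_equal(rec$T, 100 / 256)
})

test_that("format errors name the offending line", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# fs=10 channels=3", "1 2 3", "4 5", "6 7 8"), tf)
  expect_error(read_eeg_text(tf), "line 3")
  writeLines(c("no header", "1 2 3"), tf)
  expect_error(read_eeg_text(tf), "line 1")
  writeLines(c("# fs=10 channels=2", "1 2", "1 oops"), tf)
  expect_error(read_eeg_text(tf), "line 3")
})

test_that("decimation yields 35 samples per second and unit DC gain", {
  out <- make_seizure(seed = 1, n_channels = 1)
  dec <- lowpass_decimate(out$record)
  expect_identical(ncol(dec$data), 6300L)
  expect_equal(dec$fs, 35)
  # duration preserved within one output sample
  expect_lt(abs(dec$T - out$record$T), 1 / 35)
  # constant record passes unchanged
  const <- eeg_record(matrix(3.25, nrow = 1, ncol = 2560), fs = 256)
  cd <- lowpass_decimate(const)
  expect_lt(max(abs(cd$data - 3.25)) / 3.25, 1e-9)
})

test_that("a 50 Hz tone is strongly attenuated by the 35 Hz filter", {
  t <- seq(0, 10, by = 1 / 256)[-1]
  tone <- eeg_record(matrix(sin(2 * pi * 50 * t), nrow = 1), fs = 256)
  dec <- lowpass_decimate(tone)
  rms_in <- sqrt(mean(tone$data^2))
  rms_out <- sqrt(mean(dec$data^2))
  expect_lt(rms_out, 0.1 * rms_in)
})

test_that("invalid decimation parameters error", {
  rec <- make_tiny_record(fs = 30)
  expect_error(lowpass_decimate(rec, target_fs = 64), "exceeds")
  expect_error(lowpass_decimate(rec, cutoff = 35, target_fs = 15),
               "twice the cutoff")
})

test_that("dominant-channel selection maximises peak-to-peak with low-index ties", {
  set.seed(3)
  data <- matrix(rnorm(24 * 500), nrow = 24)
  data[7, ] <- data[7, ] * 10
  expect_identical(select_dominant_channel(eeg_record(data, fs = 100)), 7L)
  same <- eeg_record(matrix(rep(sin(1:200), 4), nrow = 4, byrow = TRUE),
                     fs = 100)
  expect_identical(select_dominant_channel(same), 1L)
  # generator ground truth
  out <- make_seizure(seed = 6)
  expect_identical(select_dominant_channel(out$record),
                   attr(out$record, "dominant_channel"))
})

test_that("trial averaging is an element-wise mean with shape checks", {
  rec <- make_tiny_record()
  expect_equal(average_trials(list(rec, rec, rec))$data, rec$data)
  neg <- eeg_record(-rec$data, fs = rec$fs)
  expect_true(all(average_trials(list(rec, neg))$data == 0))
  short <- eeg_record(rec$data[, 1:5], fs = rec$fs)
  expect_error(average_trials(list(rec, short)), "alignment")
  # channel selection commutes with averaging for identically shaped trials
  recs <- lapply(1:3, function(s) make_tiny_record(seed = s))
  recs <- lapply(recs, function(r) {
    r$data[2, ] <- r$data[2, ] * 10
    r
  })
  expect_identical(select_dominant_channel(average_trials(recs)), 2L)
})

test_that("annotations round-trip through CSV", {
  ann <- event_annotation(50, 80, 160)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_annotation(ann, tf)
  expect_equal(unclass(read_annotation(tf)), unclass(ann))
})
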