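test_that("EDF round trip stays within the 16-bit quantization bound", {
  set.seed(11)
  x <- matrix(rnorm(128 * 10 * 6, 0, 40), 1280, 6)
  rec <- recording(x, 128, sprintf("ch%d", 1:6), "M1")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  r2 <- read_edf(f)
  expect_equal(r2$fs, 128)
  expect_equal(r2$channel_labels, rec$channel_labels)
  expect_equal(r2$reference, "M1")
  # physical range is 2 * max|x| (up to header rounding); 16-bit quantization
  bound <- 2 * max(abs(x)) * 1.01 / 2^16
  expect_lt(max(abs(r2$data - rec$data)), bound)
})

test_that("zero recordings and small sines round-trip within format bounds", {
  rec0 <- recording(matrix(0, 256, 2), 128, c("a", "b"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec0, f)
  expect_equal(max(abs(read_edf(f)$data)), 0)

  t <- (0:1279) / 128
  rs <- recording(matrix(sin(2 * pi * 10 * t)), 128, "s")
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rs, f2)
  expect_lt(max(abs(read_edf(f2)$data - rs$data)), 2 / 2^15)
})

test_that("long labels are truncated with a warning", {
  rec <- recording(matrix(0, 128, 1), 128, "a_very_long_electrode_label")
  f <- withr::local_tempfile(fileext = ".edf")
  expect_warning(write_edf(rec, f), "truncating")
  expect_equal(read_edf(f)$channel_labels, "a_very_long_elec")
})

test_that("annotations survive via sidecar and via the EDF+ TAL channel", {
  ann <- list(phase_annotation("II", "eyes_closed", 0, 4),
              phase_annotation("IV", "eyes_closed", 4, 6))
  rec <- recording(matrix(rnorm(1280), ncol = 1), 128, "c1", "average", ann)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  viaside <- read_edf(f)
  expect_length(viaside$annotations, 2)
  file.remove(paste0(f, ".json"))
  viatal <- read_edf(f)
  expect_length(viatal$annotations, 2)
  expect_equal(viatal$annotations[[1]]$phase_id, "II")
  expect_equal(viatal$annotations[[2]]$condition, "eyes_closed")
  expect_equal(viatal$annotations[[2]]$onset, 4)
  expect_equal(viatal$annotations[[2]]$duration, 6)
})

test_that("truncated or malformed files raise format errors", {
  rec <- recording(matrix(rnorm(1280), ncol = 1), 128, "c1")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  fbad <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:600], fbad)
  expect_error(read_edf(fbad), "truncated")
  fjunk <- withr::local_tempfile(fileext = ".edf")
  writeBin(as.raw(rep(65, 2000)), fjunk)
  expect_error(read_edf(fjunk), "malformed|valid EDF")
  expect_error(read_edf(withr::local_tempfile(fileext = ".edf")), "not found")
})

test_that("non-finite data is refused on write", {
  rec <- recording(matrix(1, 128, 1), 128, "a")
  rec$data[5, 1] <- Inf
  expect_error(write_edf(rec, withr::local_tempfile(fileext = ".edf")),
               "non-finite")
})

test_that("millivolt-dimensioned signals are converted to microvolts", {
  rec <- recording(matrix(seq(-1, 1, length.out = 128), ncol = 1), 128, "c1")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  # flip the physical-dimension field of signal 1 from uV to mV
  # (header layout: all labels, then all transducers, then all dimensions)
  con <- file(f, "r+b")
  seek(con, 256 + 1 * 16 + 1 * 80, rw = "write")
  writeBin(charToRaw("mV      "), con)
  close(con)
  file.remove(paste0(f, ".json"))
  r2 <- read_edf(f)
  expect_equal(r2$data[, 1], rec$data[, 1] * 1e3, tolerance = 1e-3)
})

test_that("heterogeneous per-signal sampling rates are refused", {
  rec <- recording(matrix(rnorm(256 * 2), ncol = 2), 128, c("a", "b"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  # rewrite signal 2's samples-per-record field (128 -> 64)
  ns <- 2
  off <- 256 + ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) + 1 * 8
  con <- file(f, "r+b")
  seek(con, off, rw = "write")
  writeBin(charToRaw(formatC("64", width = -8)), con)
  close(con)
  expect_error(read_edf(f, sidecar = FALSE), "heterogeneous")
})
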