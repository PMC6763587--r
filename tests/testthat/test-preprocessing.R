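test_that("constructed channel failures are detected with the right reason", {
  set.seed(31)
  fs <- 128
  n <- 120 * fs
  x <- matrix(rnorm(n * 5, 0, 10), n, 5)
  x[, 2] <- 3.7                                  # isoelectric (constant)
  x[seq_len(40 * fs), 3] <- 500                  # stuck at +rail for 40 s
  x[seq_len(40 * fs), 4] <- x[seq_len(40 * fs), 4] * 12  # artifactual 40 s
  x[seq_len(29 * fs), 5] <- 500                  # at rail only 29 s: stays good
  qc <- detect_bad_channels(recording(x, fs, sprintf("c%d", 1:5)))
  expect_equal(qc$status, c("good", "bad", "bad", "bad", "good"))
  expect_equal(qc$reason, c("none", "isoelectric", "saturated",
                            "artifactual", "none"))
  expect_gte(qc$artifact_seconds[3], 40)
  expect_lte(qc$artifact_seconds[1], 1)
})

test_that("QC is deterministic, order-independent, and needs 30 s", {
  set.seed(32)
  fs <- 64
  x <- matrix(rnorm(40 * fs * 4), ncol = 4)
  x[, 3] <- 0
  rec <- recording(x, fs, c("a", "b", "c", "d"))
  q1 <- detect_bad_channels(rec)
  q2 <- detect_bad_channels(rec)
  expect_identical(q1, q2)
  perm <- c(3, 1, 4, 2)
  qp <- detect_bad_channels(recording(x[, perm], fs, c("c", "a", "d", "b")))
  expect_equal(qp$status[match(q1$channel, qp$channel)], q1$status)
  expect_error(detect_bad_channels(recording(x[1:(20 * fs), ], fs,
                                             letters[1:4])), "too short")
})

test_that("failure-free synthetic channels pass QC (low false-positive rate)", {
  mont <- small_montage(16)
  flagged <- 0L; total <- 0L
  for (seed in 1:8) {
    sp <- synth_phase_spec("II", "eyes_closed", 60, 10.3,
                           artifact_burst_rate = 0, bad_channel_rate = 0)
    res <- synthesize_recording(sp, mont, 0, seed = seed, fs = 128)
    qc <- detect_bad_channels(segment_by_phase(res$recording)[["II"]],
                              min_bad_s = 20)
    flagged <- flagged + sum(!qc_good(qc))
    total <- total + nrow(qc)
  }
  expect_lt(flagged / total, 0.01)
})

test_that("average reference zeroes the good-channel mean and is idempotent", {
  set.seed(33)
  m <- small_montage(8)
  x <- matrix(rnorm(500 * 8), ncol = 8)
  x[, 2] <- x[, 2] + 1e6                          # huge offset on a bad channel
  qc <- qc_all_good(m$labels)
  qc$status[2] <- "bad"; qc$reason[2] <- "isoelectric"
  rec <- recording(x, 128, m$labels)
  rr <- average_reference(rec, qc)
  expect_lt(max(abs(rowMeans(rr$data[, qc_good(qc)]))), 1e-10)
  # the bad channel's offset did not leak into the subtracted mean
  expect_lt(max(abs(rr$data[, 1] - (x[, 1] - rowMeans(x[, -2])))), 1e-9)
  rr2 <- average_reference(rr, qc)
  expect_equal(rr2$data, rr$data, tolerance = 1e-12)
  qc$status[] <- "bad"
  expect_error(average_reference(rec, qc), "at least 2")
})

test_that("spherical-spline interpolation is exact on constant fields", {
  m <- montage_tentwenty64()
  qc <- qc_all_good(m$labels)
  qc$status[c(3, 40)] <- "bad"; qc$reason[c(3, 40)] <- "artifactual"
  rec <- recording(matrix(7.25, 50, 64), 128, m$labels)
  out <- interpolate_bad(rec, qc, m)
  expect_lt(max(abs(out$data[, c(3, 40)] - 7.25)), 1e-6)
  expect_equal(attr(out, "interpolated"), m$labels[c(3, 40)])
})

test_that("leave-one-out spline error is below 5% on smooth fields", {
  m <- montage_tentwenty64()
  # field built from spherical harmonics of degree <= 3
  p <- m$positions
  v <- 1.3 * p[, 1] * p[, 2] + 0.7 * p[, 3]^2 - 0.4 * p[, 2] +
    0.2 * p[, 1] * (5 * p[, 3]^2 - 1)
  for (ch in c("Cz", "C3", "Pz", "PO3", "F4")) {
    qc <- qc_all_good(m$labels)
    i <- which(m$labels == ch)
    qc$status[i] <- "bad"; qc$reason[i] <- "artifactual"
    rec <- recording(matrix(v, 2, 64, byrow = TRUE), 128, m$labels)
    out <- interpolate_bad(rec, qc, m)
    expect_lt(abs(out$data[1, i] - v[i]) / stats::sd(v), 0.05)
    # good channels untouched
    expect_identical(out$data[, -i], rec$data[, -i])
  }
})

test_that("edge electrodes interpolate to finite values", {
  m <- montage_tentwenty64()
  set.seed(34)
  qc <- qc_all_good(m$labels)
  i <- which(m$labels == "M1")                    # below the equator
  qc$status[i] <- "bad"; qc$reason[i] <- "saturated"
  rec <- recording(matrix(rnorm(64 * 20), 20, 64), 128, m$labels)
  out <- interpolate_bad(rec, qc, m)
  expect_true(all(is.finite(out$data)))
})

test_that("interpolation refuses when too few good channels remain", {
  m <- small_montage(12)
  qc <- qc_all_good(m$labels)
  qc$status[1:5] <- "bad"; qc$reason[1:5] <- "isoelectric"
  rec <- recording(matrix(rnorm(12 * 10), 10, 12), 128, m$labels)
  expect_error(interpolate_bad(rec, qc, m), "refused")
})

test_that("QC reports round-trip through delimited text", {
  qc <- qc_all_good(c("a", "b"))
  qc$status[2] <- "bad"; qc$reason[2] <- "saturated"; qc$artifact_seconds[2] <- 45
  f <- withr::local_tempfile(fileext = ".tsv")
  write_qc(qc, f)
  q2 <- read_qc(f)
  expect_equal(as.data.frame(q2), as.data.frame(qc))
})
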