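test_that("Welch locates tones and preserves variance (Parseval)", {
  rec <- tone_recording(10, fs = 256, seconds = 60)
  sr <- welch_psd(rec)
  expect_equal(sr$freqs[which.max(sr$psd[, 1])], 10)
  df <- sr$freqs[2] - sr$freqs[1]
  expect_equal(df, 0.25)
  # unit sine has variance 1/2
  expect_equal(sum(sr$psd[, 1]) * df, 0.5, tolerance = 0.02)
  expect_true(all(sr$psd >= 0))
  expect_equal(sr$n_intervals, 2L)
})

test_that("Welch refuses segments shorter than one interval", {
  rec <- tone_recording(10, fs = 128, seconds = 20)
  expect_error(welch_psd(rec), "too short")
})

test_that("disjoint white-noise realizations give consistent PSDs", {
  set.seed(41)
  fs <- 256
  mk <- function() {
    welch_psd(recording(matrix(rnorm(300 * fs)), fs, "a"))
  }
  s1 <- mk(); s2 <- mk()
  keep <- s1$freqs >= 1 & s1$freqs <= 40
  rel_rms <- sqrt(mean(((s1$psd[keep, 1] - s2$psd[keep, 1]) /
                          ((s1$psd[keep, 1] + s2$psd[keep, 1]) / 2))^2))
  expect_lt(rel_rms, 0.15)
})

test_that("the whole-head mean PSD is a plain channel average", {
  set.seed(42)
  fs <- 128
  x <- matrix(rnorm(30 * fs * 4), ncol = 4)
  sr <- welch_psd(recording(x, fs, letters[1:4]))
  expect_equal(mean_psd(sr), rowMeans(sr$psd))
  # permutation invariance
  srp <- welch_psd(recording(x[, c(3, 1, 4, 2)], fs, letters[c(3, 1, 4, 2)]))
  expect_equal(mean_psd(srp), mean_psd(sr), tolerance = 1e-12)
  # restricting to good channels via QC
  qc <- qc_all_good(letters[1:4]); qc$status[4] <- "bad"
  expect_equal(mean_psd(sr, qc), rowMeans(sr$psd[, 1:3]))
  # linearity: one channel carrying a bump of height h contributes h/n
  p <- sr$psd; p[, ] <- 1
  p[20, 2] <- 1 + 4
  sr2 <- sr; sr2$psd <- p
  expect_equal(mean_psd(sr2)[20], 1 + 4 / 4)
})

test_that("the presence gate applies the 1.3x threshold inclusively", {
  freqs <- seq(0, 64, by = 0.25)
  flat <- rep(2, length(freqs))
  m <- alpha_presence(freqs, flat)
  expect_equal(m$presence_ratio, 1)
  expect_false(m$alpha_present)
  # boundary: alpha peak exactly 1.3x the neighbour average -> present
  bump <- flat; bump[freqs == 10] <- 2.6
  mb <- alpha_presence(freqs, bump)
  expect_equal(mb$presence_ratio, 1.3, tolerance = 1e-12)
  expect_true(mb$alpha_present)
  # asymmetric neighbours: peak 10 against theta 1 and beta 3 -> 10 / 2
  spec <- rep(0, length(freqs))
  spec[freqs >= 4 & freqs <= 7.5] <- 1
  spec[freqs >= 13 & freqs <= 30] <- 3
  spec[freqs == 10] <- 10
  ma <- alpha_presence(freqs, spec)
  expect_equal(ma$presence_ratio, 5, tolerance = 1e-12)
  expect_true(ma$alpha_present)
  # zero neighbour power: infinite ratio, present, with a warning
  z <- rep(0, length(freqs)); z[freqs == 10] <- 1
  expect_warning(mz <- alpha_presence(freqs, z), "infinite")
  expect_true(is.infinite(mz$presence_ratio))
  expect_true(mz$alpha_present)
  expect_error(alpha_presence(seq(5, 20, 0.25), rep(1, 61)), "cover")
})

test_that("the COG matches a brute-force weighted mean to 1e-12", {
  set.seed(43)
  freqs <- seq(0, 64, by = 0.25)
  for (i in 1:20) {
    p <- stats::runif(length(freqs))^2 * 10
    expect_equal(compute_iapf(freqs, p), cog_oracle(freqs, p),
                 tolerance = 1e-12)
  }
  # point mass at the bin nearest 10 Hz
  p0 <- rep(0, length(freqs)); p0[which.min(abs(freqs - 10))] <- 3
  expect_equal(compute_iapf(freqs, p0), 10)
  # symmetric spectrum about 10.25 Hz
  ps <- exp(-(freqs - 10.25)^2 / 0.8)
  expect_equal(compute_iapf(freqs, ps), 10.25, tolerance = 1e-9)
})

test_that("COG bounds, scale invariance and monotonicity hold", {
  set.seed(44)
  freqs <- seq(0, 64, by = 0.25)
  for (i in 1:20) {
    p <- stats::runif(length(freqs)) + 0.01
    cog <- compute_iapf(freqs, p)
    expect_gte(cog, 7.5); expect_lte(cog, 13)
    expect_equal(compute_iapf(freqs, p * stats::runif(1, 0.1, 50)), cog,
                 tolerance = 1e-12)
    # adding power above the current COG increases it; below, decreases
    up <- p; up[freqs == 12.5] <- up[freqs == 12.5] + 5
    dn <- p; dn[freqs == 8] <- dn[freqs == 8] + 5
    expect_gt(compute_iapf(freqs, up), cog)
    expect_lt(compute_iapf(freqs, dn), cog)
  }
  expect_error(compute_iapf(freqs, rep(0, length(freqs))), "alpha")
  expect_error(compute_iapf(freqs, rep(-1, length(freqs))), "nonnegative")
})

test_that("alpha_metrics only reports an iAPF when the gate passes", {
  freqs <- seq(0, 64, by = 0.25)
  flat <- rep(1, length(freqs))
  m <- alpha_metrics(freqs, flat)
  expect_false(m$alpha_present)
  expect_true(is.na(m$iapf))
  bump <- flat + 5 * exp(-(freqs - 10.3)^2)
  m2 <- alpha_metrics(freqs, bump)
  expect_true(m2$alpha_present)
  expect_equal(m2$iapf, compute_iapf(freqs, bump))
})
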