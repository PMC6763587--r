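test_that("background noise has the requested spectral slope and scale", {
  fs <- 256
  for (be in c(0, 1)) {
    x <- make_background(120 * fs, fs, exponent = be, scale = 2, seed = 51)
    sr <- welch_psd(recording(matrix(x), fs, "a"))
    expect_equal(psd_slope(sr$freqs, sr$psd[, 1]), -be, tolerance = 0.1)
  }
  # deterministic under the seed
  expect_identical(make_background(1000, 128, 1, 1, seed = 5),
                   make_background(1000, 128, 1, 1, seed = 5))
  expect_false(identical(make_background(1000, 128, 1, 1, seed = 5),
                         make_background(1000, 128, 1, 1, seed = 6)))
  expect_equal(mean(make_background(5000, 128, 1, 1, seed = 7)), 0,
               tolerance = 0.5)
})

test_that("the alpha component is centred where requested", {
  fs <- 256
  # zero power -> all-zero signal
  expect_equal(make_alpha(1000, fs, 10.25, 2, power = 0, seed = 1),
               numeric(1000))
  # the pipeline's own COG on a long realization recovers f0
  x <- make_alpha(300 * fs, fs, 10.25, 2, power = 5, seed = 52)
  sr <- welch_psd(recording(matrix(x), fs, "a"))
  expect_equal(compute_iapf(sr$freqs, sr$psd[, 1]), 10.25, tolerance = 0.05)
  expect_equal(var(x), 5, tolerance = 0.15)
  # two equal-power generators at 9 and 11 Hz -> COG at 10 by symmetry
  y <- make_alpha(300 * fs, fs, 9, 1.5, power = 3, seed = 53) +
    make_alpha(300 * fs, fs, 11, 1.5, power = 3, seed = 54)
  sry <- welch_psd(recording(matrix(y), fs, "a"))
  expect_equal(compute_iapf(sry$freqs, sry$psd[, 1]), 10, tolerance = 0.05)
  # band leaving (7.5, 13) is a configuration error
  expect_error(make_alpha(1000, fs, 12.5, 2, 1, 1), "inside")
})

test_that("failure-free recordings pass the bad-channel detector", {
  mont <- small_montage(16)
  sp <- synth_phase_spec("II", "eyes_closed", 40, 10.3,
                         artifact_burst_rate = 0, bad_channel_rate = 0)
  for (seed in 1:4) {
    res <- synthesize_recording(sp, mont, 0, seed = seed, fs = 128)
    qc <- detect_bad_channels(segment_by_phase(res$recording)[["II"]],
                              min_bad_s = 20)
    expect_true(all(qc_good(qc)))
    expect_length(res$ground_truth$failed_channels, 0)
  }
})

test_that("injected failures are constructed as their detectable class", {
  mont <- small_montage(16)
  sp <- synth_phase_spec("II", "eyes_closed", 120, 10.3,
                         artifact_burst_rate = 0, bad_channel_rate = 0.5)
  res <- synthesize_recording(sp, mont, 0, seed = 55, fs = 128)
  gt <- res$ground_truth
  expect_gt(length(gt$failed_channels), 0)
  seg <- segment_by_phase(res$recording)[["II"]]
  qc <- detect_bad_channels(seg)
  for (ch in gt$failed_channels) {
    i <- which(seg$channel_labels == ch)
    type <- gt$failure_types[[ch]]
    if (type == "isoelectric") {
      expect_equal(stats::sd(seg$data[, i]), 0)
    }
    expect_equal(qc$status[i], "bad")
    expect_equal(qc$reason[i], type)
  }
  # non-injected channels stay good
  ok <- setdiff(seg$channel_labels, gt$failed_channels)
  expect_true(all(qc$status[match(ok, qc$channel)] == "good"))
})

test_that("eyes-open alpha power is 3.5x below eyes-closed", {
  mont <- small_montage(24)
  mk <- function(cond, scale, seed) {
    sp <- synth_phase_spec("I", cond, 120, 10.3, alpha_power_scale = scale,
                           artifact_burst_rate = 0, bad_channel_rate = 0)
    res <- synthesize_recording(sp, mont, 0, seed = seed, fs = 128)
    seg <- segment_by_phase(res$recording)[[paste0("I_", sub("eyes_", "", cond))]]
    sr <- welch_psd(seg)
    mp <- mean_psd(sr)
    # alpha power above the 1/f floor, floor fitted log-log on side bands
    f <- sr$freqs
    side <- (f >= 2 & f <= 6) | (f >= 15 & f <= 30)
    fit <- stats::lm(lp ~ lf, data.frame(lf = log(f[side]), lp = log(mp[side])))
    aidx <- f >= 7.5 & f <= 13
    floor_a <- exp(stats::predict(fit, data.frame(lf = log(f[aidx]))))
    sum(pmax(mp[aidx] - floor_a, 0)) * (f[2] - f[1])
  }
  ec <- mk("eyes_closed", 1, 56)
  eo <- mk("eyes_open", 1 / 3.5, 56)
  expect_equal(ec / eo, 3.5, tolerance = 0.2)
})

test_that("study synthesis is seed-reproducible with the configured counts", {
  cfg <- synth_study_config(n_subjects = 2, n_excluded_no_alpha = 1,
                           seed = 57, fs = 128, phase3_s = 35)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synthesize_study(cfg, d1)
  synthesize_study(cfg, d2)
  # 2 subjects x 2 caps x 5 phases = 20 recordings
  expect_length(list.files(d1, pattern = "\\.edf$"), 20)
  m1 <- readLines(file.path(d1, "manifest.json"))
  m2 <- readLines(file.path(d2, "manifest.json"))
  expect_identical(m1, m2)
  # per-file byte identity
  f <- "sub01_dry_phaseII.edf"
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_length(man$units, 20)
  expect_length(man$deficient_subjects, 1)
  # subject offsets centred to exact zero mean
  expect_equal(sum(unlist(man$subject_offsets)), 0, tolerance = 1e-12)
})

test_that("deficient subjects carry zero alpha in exactly one analyzed phase", {
  cfg <- synth_study_config(n_subjects = 6, n_excluded_no_alpha = 3, seed = 58)
  defic <- alphacog:::deficient_assignment(cfg)
  expect_named(defic, c("4", "5", "6"))
  expect_true(all(unlist(defic) %in% c("II", "IV", "V")))
  specs <- alphacog:::subject_phase_specs(cfg, "dry", 4)
  ph <- vapply(specs, `[[`, "", "phase_id")
  sc <- vapply(specs, `[[`, 0, "alpha_power_scale")
  expect_equal(sum(sc[ph == defic[["4"]]] == 0), 1)
  expect_true(all(sc[!ph %in% defic[["4"]]] > 0))
})

test_that("simulated iAPF tables follow the additive model", {
  means <- matrix(c(10.23, 10.37, 10.43, 10.22, 10.36, 10.41), 2, 3,
                  byrow = TRUE)
  y <- simulate_iapf_table(200, means, subject_sd = 0.26, noise_sd = 0.05,
                           seed = 59)
  expect_equal(dim(y), c(200L, 6L))
  expect_equal(unname(colMeans(y)),
               c(10.23, 10.37, 10.43, 10.22, 10.36, 10.41), tolerance = 0.1)
  # rows correlate through the shared subject effect
  expect_gt(cor(y[, 1], y[, 4]), 0.8)
  expect_identical(simulate_iapf_table(5, 10, seed = 3),
                   simulate_iapf_table(5, 10, seed = 3))
})

test_that("synthetic impedances match the reported start/end moments", {
  cfg <- synth_study_config(n_subjects = 40, seed = 60)
  imp <- synthesize_impedances(cfg)
  expect_equal(nrow(imp), 40 * 64)
  expect_equal(mean(imp$start_kohm), 455, tolerance = 0.1)
  expect_equal(stats::sd(imp$start_kohm), 251, tolerance = 0.15)
  expect_equal(mean(imp$end_kohm), 132, tolerance = 0.1)
})
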