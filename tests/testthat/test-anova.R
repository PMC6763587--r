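# oracles shared via helper-oracles.R

test_that("F, p, Mauchly W and GG epsilon match independent oracles", {
  set.seed(61)
  for (i in 1:5) {
    y <- matrix(rnorm(13 * 6, 10.3, 0.3), 13, 6) + rnorm(13, 0, 0.25)
    colnames(y) <- c("gel_II", "gel_IV", "gel_V", "dry_II", "dry_IV", "dry_V")
    rep <- rm_anova_2x3(y)
    eff <- rep$effects
    ao <- aov_oracle(y)
    expect_equal(eff$F[eff$effect == "cap"], ao$cap[[1]], tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "phase"], ao$phase[[1]], tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "cap:phase"], ao$inter[[1]],
                 tolerance = 1e-8)
    expect_equal(eff$p_uncorrected[eff$effect == "phase"], ao$phase[[2]],
                 tolerance = 1e-8)
    co <- suppressWarnings(car_oracle(y))
    expect_equal(eff$mauchly_W[eff$effect == "phase"],
                 unname(co$sph["phase", "Test statistic"]), tolerance = 1e-8)
    expect_equal(eff$mauchly_p[eff$effect == "phase"],
                 unname(co$sph["phase", "p-value"]), tolerance = 1e-6)
    expect_equal(eff$gg_epsilon[eff$effect == "phase"],
                 unname(co$adj["phase", "GG eps"]), tolerance = 1e-8)
    expect_equal(eff$gg_epsilon[eff$effect == "cap:phase"],
                 unname(co$adj["cap:phase", "GG eps"]), tolerance = 1e-8)
    expect_equal(eff$p_gg[eff$effect == "phase"],
                 unname(co$adj["phase", "Pr(>F[GG])"]), tolerance = 1e-8)
  }
})

test_that("no-effect data yields zero F and two-level factors epsilon 1", {
  # subjects differ only by additive offsets; all six cell means equal
  y <- matrix(10.3, 8, 6) + rnorm(8, 0, 0.3)
  colnames(y) <- c("gel_II", "gel_IV", "gel_V", "dry_II", "dry_IV", "dry_V")
  rep <- expect_error(rm_anova_2x3(y), "degenerate")
  # with tiny independent noise the F values collapse toward zero
  set.seed(62)
  y2 <- y + matrix(rnorm(48, 0, 1e-6), 8, 6)
  rep2 <- rm_anova_2x3(y2)
  expect_lt(max(rep2$effects$F), 10)       # no systematic effect variance
  expect_equal(rep2$effects$gg_epsilon[rep2$effects$effect == "cap"], 1)
  expect_true(all(rep2$effects$partial_eta_sq >= 0 &
                    rep2$effects$partial_eta_sq <= 1))
})

test_that("epsilon stays within its theoretical bounds for k = 3", {
  set.seed(63)
  for (i in 1:20) {
    y <- simulate_iapf_table(10, 10.3, subject_sd = 0.2, noise_sd = 0.1,
                             seed = 630 + i)
    eff <- rm_anova_2x3(y)$effects
    eps <- eff$gg_epsilon[eff$effect == "phase"]
    expect_gte(eps, 0.5); expect_lte(eps, 1)
    expect_true(all(eff$p >= 0 & eff$p <= 1))
  }
})

test_that("the report is invariant to subject shifts and global scaling", {
  y <- simulate_iapf_table(9, 10.3, seed = 64)
  r0 <- rm_anova_2x3(y)
  y1 <- y; y1[4, ] <- y1[4, ] + 5
  r1 <- rm_anova_2x3(y1)
  keep <- c("F", "p", "gg_epsilon", "partial_eta_sq")
  expect_equal(r1$effects[, keep], r0$effects[, keep], tolerance = 1e-9)
  expect_equal(r1$pairwise$cohens_d, r0$pairwise$cohens_d, tolerance = 1e-9)
  y2 <- y * 3.7
  r2 <- rm_anova_2x3(y2)
  expect_equal(r2$effects[, keep], r0$effects[, keep], tolerance = 1e-9)
  expect_equal(r2$pairwise$cohens_d, r0$pairwise$cohens_d, tolerance = 1e-9)
})

test_that("phase effects injected at study scale are detected; cap stays null", {
  means <- matrix(c(10.23, 10.37, 10.43, 10.22, 10.36, 10.41), 2, 3,
                  byrow = TRUE)
  hits_phase <- 0; hits_cap <- 0; nsim <- 40
  for (i in seq_len(nsim)) {
    y <- simulate_iapf_table(13, means, subject_sd = 0.26, noise_sd = 0.08,
                             seed = 6400 + i)
    eff <- rm_anova_2x3(y)$effects
    hits_phase <- hits_phase + (eff$p[eff$effect == "phase"] < 0.05)
    hits_cap <- hits_cap + (eff$p[eff$effect == "cap"] < 0.05)
  }
  expect_gt(hits_phase / nsim, 0.9)
  expect_lt(hits_cap / nsim, 0.3)
})

test_that("pairwise comparisons match a direct paired-t oracle", {
  set.seed(65)
  y <- simulate_iapf_table(11, 10.3, seed = 65)
  pw <- pairwise_bonferroni(y)
  capavg <- (unclass(y)[, 1:3] + unclass(y)[, 4:6]) / 2
  prs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(prs)) {
    tt <- stats::t.test(capavg[, prs[[k]][2]], capavg[, prs[[k]][1]],
                        paired = TRUE)
    expect_equal(pw$t[k], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pw$p_raw[k], tt$p.value, tolerance = 1e-10)
    expect_equal(pw$p_bonferroni[k], min(1, 3 * tt$p.value), tolerance = 1e-10)
  }
  # d_z arithmetic: differences (1, 2, 3) across 3 subjects -> d = 2 / 1
  y3 <- matrix(c(0, 0, 0, 1, 2, 3), 3, 2)
  tab <- cbind(y3[, 1], y3[, 2], y3[, 2], y3[, 1], y3[, 2], y3[, 2])
  colnames(tab) <- c("gel_II", "gel_IV", "gel_V", "dry_II", "dry_IV", "dry_V")
  pw3 <- pairwise_bonferroni(tab)
  expect_equal(pw3$cohens_d[pw3$phase_a == "II" & pw3$phase_b == "IV"], 2)
  # identical phase columns -> zero difference, d = 0, p = 1
  same <- matrix(rnorm(6), 6, 6) + 10
  colnames(same) <- colnames(tab)
  pws <- pairwise_bonferroni(same)
  expect_equal(pws$mean_diff, rep(0, 3))
  expect_equal(pws$cohens_d, rep(0, 3))
  expect_equal(pws$p_bonferroni, rep(1, 3))
})

test_that("effect sizes classify with inclusive thresholds", {
  expect_equal(classify_effect_size(0.609, "partial_eta_sq"), "large")
  expect_equal(classify_effect_size(0.629, "cohens_d"), "medium")
  expect_equal(classify_effect_size(0.10, "cohens_d"), "negligible")
  expect_equal(classify_effect_size(0.14, "partial_eta_sq"), "large")
  expect_equal(classify_effect_size(0.06, "partial_eta_sq"), "medium")
  expect_equal(classify_effect_size(0.01, "partial_eta_sq"), "small")
  expect_equal(classify_effect_size(0.8, "cohens_d"), "large")
  expect_error(classify_effect_size(0.5, "omega"))
})

test_that("degenerate tables are refused with clear messages", {
  y <- simulate_iapf_table(2, 10.3, seed = 66)
  expect_error(rm_anova_2x3(y), "at least 3")
  y4 <- simulate_iapf_table(4, 10.3, seed = 67)
  y4[2, 3] <- NA
  expect_error(rm_anova_2x3(y4), "complete")
})

test_that("long-format tables reshape to complete-case wide tables", {
  y <- simulate_iapf_table(5, 10.3, seed = 68)
  long <- expand.grid(subject = 1:5, cap = c("gel", "dry"),
                      phase = c("II", "IV", "V"), stringsAsFactors = FALSE)
  long$iapf <- mapply(function(s, cp, ph) y[s, paste(cp, ph, sep = "_")],
                      long$subject, long$cap, long$phase)
  tab <- as_iapf_table(long)
  expect_equal(unclass(tab), unclass(y), ignore_attr = TRUE)
  # a subject with a missing cell is dropped
  long2 <- long[!(long$subject == 3 & long$phase == "IV" & long$cap == "dry"), ]
  tab2 <- as_iapf_table(long2)
  expect_equal(nrow(tab2), 4)
})
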