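#' iAPF table for the 2 x 3 within-subject design
#'
#' Complete-case table: one row per subject, six columns for the cap-by-
#' phase cells in the fixed order `gel_II, gel_IV, gel_V, dry_II, dry_IV,
#' dry_V`. Build one from a long table with [as_iapf_table()].
#'
#' @param x numeric matrix or data.frame with those six columns.
#' @return an `iapf_table` matrix.
#' @export
iapf_table <- function(x) {
  cols <- c("gel_II", "gel_IV", "gel_V", "dry_II", "dry_IV", "dry_V")
  x <- as.matrix(as.data.frame(x)[, cols])
  if (any(!is.finite(x))) stop("iapf_table must be complete (no missing cells)",
                               call. = FALSE)
  structure(x, class = c("iapf_table", "matrix"))
}

#' @param long data.frame with columns `subject`, `cap` (gel/dry), `phase`
#'   (II/IV/V), `iapf`. Subjects with any missing cell are dropped.
#' @rdname iapf_table
#' @export
as_iapf_table <- function(long) {
  stopifnot(all(c("subject", "cap", "phase", "iapf") %in% names(long)))
  long$cell <- paste(long$cap, long$phase, sep = "_")
  wide <- stats::reshape(long[, c("subject", "cell", "iapf")],
                         idvar = "subject", timevar = "cell",
                         direction = "wide")
  names(wide) <- sub("^iapf\\.", "", names(wide))
  cols <- c("gel_II", "gel_IV", "gel_V", "dry_II", "dry_IV", "dry_V")
  miss <- setdiff(cols, names(wide))
  if (length(miss)) stop("long table lacks cells: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  keep <- stats::complete.cases(wide[, cols])
  out <- iapf_table(wide[keep, cols])
  rownames(out) <- wide$subject[keep]
  out
}

# orthonormal polynomial-free contrast basis for k levels (k x (k-1))
orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# Mauchly's W and Greenhouse-Geisser epsilon from the covariance of
# orthonormal within-subject contrast scores (rows = subjects)
sphericity_stats <- function(scores) {
  p <- ncol(scores)
  n <- nrow(scores)
  S <- stats::cov(scores)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / (p * sum(lam^2))
  if (p < 2) return(list(W = 1, p = NA_real_, epsilon = 1))
  W <- det(S) / (sum(diag(S)) / p)^p
  fmult <- (2 * p^2 + p + 2) / (6 * p)
  chi <- -(n - 1 - fmult) * log(max(W, .Machine$double.xmin))
  list(W = W, p = stats::pchisq(chi, p * (p + 1) / 2 - 1, lower.tail = FALSE),
       epsilon = eps)
}

#' Two-by-three within-subject repeated-measures ANOVA
#'
#' Univariate decomposition of the cap (2 levels) by phase (3 levels)
#' fully-within design, computed from explicit sums of squares: effects for
#' cap, phase and their interaction, each tested against its own
#' subject-by-effect error stratum. Sphericity of the phase and interaction
#' strata is tested with Mauchly's W on the covariance of orthonormal
#' contrast scores; the Greenhouse-Geisser epsilon from the same covariance
#' corrects the degrees of freedom, and the corrected p-value is the one
#' reported whenever Mauchly's test is significant at `sphericity_alpha`
#' (the two-level cap factor is spherical by construction, epsilon = 1).
#' Effect size is partial eta squared `SS_effect / (SS_effect + SS_error)`;
#' observed power uses the noncentral F with noncentrality
#' `lambda = F * df_num` (the convention of common statistics packages,
#' declared in the report's `conventions`).
#'
#' @param table an [iapf_table()] (n >= 3 complete subjects).
#' @param sphericity_alpha Mauchly significance level that triggers the
#'   correction (default 0.05).
#' @param alpha_level test level used for the observed-power computation.
#' @return object of class `"anova_report"`: list with `effects` (one row
#'   per effect), `pairwise` (Bonferroni post hocs from
#'   [pairwise_bonferroni()]), `n`, and `conventions`.
#' @export
rm_anova_2x3 <- function(table, sphericity_alpha = 0.05, alpha_level = 0.05) {
  y <- unclass(iapf_table(table))
  n <- nrow(y)
  if (n < 3) stop("need at least 3 complete subjects", call. = FALSE)
  a <- 2L; b <- 3L
  cap_of <- rep(1:2, each = 3)
  ph_of <- rep(1:3, times = 2)

  grand <- mean(y)
  subj <- rowMeans(y)
  capm <- vapply(1:a, function(k) mean(y[, cap_of == k]), 0)
  phm <- vapply(1:b, function(k) mean(y[, ph_of == k]), 0)
  cellm <- matrix(colMeans(y), nrow = 1)
  sc <- vapply(1:a, function(k) rowMeans(y[, cap_of == k, drop = FALSE]), numeric(n))
  sp <- vapply(1:b, function(k) rowMeans(y[, ph_of == k, drop = FALSE]), numeric(n))

  ss_total <- sum((y - grand)^2)
  ss_subj <- a * b * sum((subj - grand)^2)
  ss_a <- n * b * sum((capm - grand)^2)
  ss_b <- n * a * sum((phm - grand)^2)
  ss_ab <- n * sum((colMeans(y) - capm[cap_of] - phm[ph_of] + grand)^2)
  ss_as <- b * sum((sc - outer(subj, rep(1, a)) -
                      outer(rep(1, n), capm) + grand)^2)
  ss_bs <- a * sum((sp - outer(subj, rep(1, b)) -
                      outer(rep(1, n), phm) + grand)^2)
  ss_abs <- ss_total - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs
  ss_abs <- max(ss_abs, 0)

  C2 <- orthonormal_contrasts(2)
  C3 <- orthonormal_contrasts(3)
  # transform matrices on the 6 cells (cap-major column order)
  M_b <- kronecker(matrix(1 / a, a, 1), C3)
  M_ab <- kronecker(C2, C3)
  sph_b <- sphericity_stats(y %*% M_b)
  sph_ab <- sphericity_stats(y %*% M_ab)

  mk_effect <- function(name, ss_eff, ss_err, df1, df2, sph) {
    if (ss_err <= 0) stop("degenerate data: zero error variance for the ",
                          name, " effect", call. = FALSE)
    Fv <- (ss_eff / df1) / (ss_err / df2)
    p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    eps <- sph$epsilon
    p_cor <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    correct <- !is.na(sph$p) && sph$p < sphericity_alpha
    df1_r <- if (correct) df1 * eps else df1
    df2_r <- if (correct) df2 * eps else df2
    p_rep <- if (correct) p_cor else p_unc
    lambda <- Fv * df1
    pow <- stats::pf(stats::qf(1 - alpha_level, df1_r, df2_r),
                     df1_r, df2_r, ncp = lambda, lower.tail = FALSE)
    data.frame(
      effect = name, df_num = df1, df_den = df2, F = Fv,
      p_uncorrected = p_unc, mauchly_W = sph$W, mauchly_p = sph$p,
      gg_epsilon = eps, df_num_corrected = df1 * eps,
      df_den_corrected = df2 * eps, p_gg = p_cor,
      correction_applied = correct, p = p_rep,
      partial_eta_sq = ss_eff / (ss_eff + ss_err),
      observed_power = pow, stringsAsFactors = FALSE
    )
  }

  effects <- rbind(
    mk_effect("cap", ss_a, ss_as, a - 1, (a - 1) * (n - 1),
              list(W = 1, p = NA_real_, epsilon = 1)),
    mk_effect("phase", ss_b, ss_bs, b - 1, (b - 1) * (n - 1), sph_b),
    mk_effect("cap:phase", ss_ab, ss_abs, (a - 1) * (b - 1),
              (a - 1) * (b - 1) * (n - 1), sph_ab)
  )
  effects$effect_label <- vapply(effects$partial_eta_sq, classify_effect_size,
                                 "", kind = "partial_eta_sq")
  structure(
    list(effects = effects, pairwise = pairwise_bonferroni(table), n = n,
         conventions = list(
           cohens_d = "d_z: mean(paired differences) / SD(paired differences)",
           observed_power = "noncentral F with lambda = F * df_num",
           correction = "Greenhouse-Geisser, applied when Mauchly p < 0.05"
         )),
    class = "anova_report"
  )
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("Within-subject 2x3 RM-ANOVA (n = %d)\n", x$n))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-10s F(%.3f, %.3f) = %.3f, p = %.4g, eta_p^2 = %.3f (%s), power = %.3f\n",
                eff$effect[i],
                if (eff$correction_applied[i]) eff$df_num_corrected[i] else eff$df_num[i],
                if (eff$correction_applied[i]) eff$df_den_corrected[i] else eff$df_den[i],
                eff$F[i], eff$p[i], eff$partial_eta_sq[i], eff$effect_label[i],
                eff$observed_power[i]))
  }
  cat("  Bonferroni pairwise (phases, cap-averaged):\n")
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("    %s - %s: diff = %+.4f, p = %.4g, d = %.3f (%s)\n",
                pw$phase_a[i], pw$phase_b[i], pw$mean_diff[i],
                pw$p_bonferroni[i], pw$cohens_d[i], pw$d_label[i]))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise phase comparisons
#'
#' Paired t-tests on the cap-averaged phase values for the three phase
#' pairs; raw p-values are multiplied by 3 and clipped at 1. Cohen's d is
#' the d_z convention: mean of the paired differences divided by their SD.
#' When a difference vector has zero variance and zero mean (identical
#' columns) the comparison is reported as d = 0, p = 1; zero variance with
#' a nonzero mean is an error.
#'
#' @param table an [iapf_table()].
#' @return data.frame with one row per phase pair: `phase_a`, `phase_b`,
#'   `mean_diff` (b minus a), `t`, `p_raw`, `p_bonferroni`, `cohens_d`,
#'   `d_label`.
#' @export
pairwise_bonferroni <- function(table) {
  y <- unclass(iapf_table(table))
  n <- nrow(y)
  phases <- c("II", "IV", "V")
  capavg <- (y[, 1:3, drop = FALSE] + y[, 4:6, drop = FALSE]) / 2
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  rows <- lapply(pairs, function(pr) {
    d <- capavg[, pr[2]] - capavg[, pr[1]]
    sdd <- stats::sd(d)
    if (sdd == 0) {
      if (all(abs(d) < .Machine$double.eps * 100)) {
        tval <- 0; p <- 1; dz <- 0
      } else {
        stop("zero-variance paired differences with nonzero mean: Cohen's d undefined",
             call. = FALSE)
      }
    } else {
      tval <- mean(d) / (sdd / sqrt(n))
      p <- 2 * stats::pt(-abs(tval), n - 1)
      dz <- mean(d) / sdd
    }
    data.frame(phase_a = phases[pr[1]], phase_b = phases[pr[2]],
               mean_diff = mean(d), t = tval, p_raw = p,
               p_bonferroni = min(1, 3 * p), cohens_d = dz,
               d_label = classify_effect_size(abs(dz), "cohens_d"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify an effect size
#'
#' Conventional labels with inclusive thresholds: partial eta squared 0.01 /
#' 0.06 / 0.14 and Cohen's d 0.20 / 0.50 / 0.80 for small / medium / large;
#' values below the first threshold are "negligible".
#'
#' @param value nonnegative effect-size value.
#' @param kind `"partial_eta_sq"` or `"cohens_d"`.
#' @return one of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
classify_effect_size <- function(value, kind = c("partial_eta_sq", "cohens_d")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  th <- if (kind == "partial_eta_sq") c(0.01, 0.06, 0.14) else c(0.20, 0.50, 0.80)
  c("negligible", "small", "medium", "large")[findInterval(value, th) + 1L]
}
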