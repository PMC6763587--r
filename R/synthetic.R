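# Synthetic five-phase cycling study with known ground truth.
#
# Signal model per channel: posterior-weighted narrowband alpha (common
# source realization, symmetric spectrum) + independent 1/f^beta background
# + optional movement-artifact bursts, plus injected channel failures
# (isoelectric / saturated / artifactual). The ground-truth iAPF of a
# recording is the centre of gravity of the *total* expected whole-head
# spectrum over 7.5-13 Hz; the generator solves for the alpha-component
# centre that makes this mixture COG hit the configured target, since the
# 1/f background alone has a band COG near 10 Hz and would otherwise bias
# the target by a few hundredths of a Hz.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# synthesize a real signal with one-sided target PSD S(f) via hermitian
# frequency-domain synthesis; psd_fun(f) evaluated on the FFT grid
synth_from_psd <- function(n, fs, psd_fun) {
  nh <- (n - 1L) %/% 2L
  f <- (1:nh) * fs / n
  S <- psd_fun(f)
  amp <- sqrt(S * fs * n / 2)
  X <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) / sqrt(2) * amp
  spec <- complex(length.out = n)
  spec[2:(nh + 1)] <- X
  spec[n:(n - nh + 1)] <- Conj(X)
  # DC and (for even n) Nyquist left at zero
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# matrix variant: ncols independent realizations of the same target PSD,
# synthesized with a single inverse mvfft
synth_from_psd_mat <- function(n, fs, psd_fun, ncols) {
  nh <- (n - 1L) %/% 2L
  f <- (1:nh) * fs / n
  amp <- sqrt(psd_fun(f) * fs * n / 2)
  X <- matrix(complex(real = stats::rnorm(nh * ncols),
                      imaginary = stats::rnorm(nh * ncols)) / sqrt(2),
              nh, ncols) * amp
  spec <- matrix(complex(length.out = 1), n, ncols)
  spec[2:(nh + 1), ] <- X
  spec[n:(n - nh + 1), ] <- Conj(X)
  Re(stats::mvfft(spec, inverse = TRUE)) / n
}

#' Synthetic 1/f^beta background noise
#'
#' Zero-mean signal whose one-sided PSD is `scale * (f / 10)^-exponent`
#' uV^2/Hz (so `scale` is the density at 10 Hz), synthesized in the
#' frequency domain with Gaussian coefficients. `exponent = 0` gives white
#' noise, `exponent = 1` the pink 1/f background typical of resting EEG.
#'
#' @param n_samples number of samples (> 0).
#' @param fs sampling rate in Hz.
#' @param exponent spectral exponent beta in `[0, 2]`.
#' @param scale PSD at 10 Hz, uV^2/Hz.
#' @param seed integer seed (same seed, same signal).
#' @return numeric vector of length `n_samples`.
#' @export
make_background <- function(n_samples, fs, exponent = 1, scale = 1, seed = 1) {
  stopifnot(n_samples > 0, exponent >= 0, exponent <= 2, scale >= 0)
  with_seed(seed, synth_from_psd(n_samples, fs, function(f) {
    scale * (f / 10)^(-exponent)
  }))
}

# truncated-Gaussian alpha spectral shape: symmetric about f0, support
# f0 +/- halfwidth, unit integral; returns a function of frequency
alpha_shape <- function(f0, bandwidth, band = c(7.5, 13)) {
  sigma <- bandwidth / (2 * sqrt(2 * log(2)))   # FWHM convention
  halfwidth <- min(f0 - band[1], band[2] - f0, 3.5 * sigma)
  # normalization over the truncated support
  znorm <- stats::pnorm(halfwidth / sigma) - stats::pnorm(-halfwidth / sigma)
  list(
    fun = function(f) {
      out <- stats::dnorm(f, f0, sigma) / znorm
      out[abs(f - f0) > halfwidth] <- 0
      out
    },
    halfwidth = halfwidth, sigma = sigma
  )
}

#' Synthetic narrowband alpha component
#'
#' Band-filtered noise whose one-sided PSD is a truncated Gaussian,
#' symmetric about `f0` with full width at half maximum `bandwidth` and
#' support wholly inside the alpha band, so its spectral centre of gravity
#' over 7.5-13 Hz equals `f0`. `power` is the integrated power (variance,
#' uV^2) of the component; `power = 0` returns an all-zero signal.
#'
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz.
#' @param f0 centre frequency; `[f0 - bandwidth/2, f0 + bandwidth/2]` must
#'   lie strictly inside (7.5, 13) Hz.
#' @param bandwidth FWHM of the spectral bump in Hz.
#' @param power integrated power in uV^2.
#' @param seed integer seed.
#' @return numeric vector of length `n_samples`.
#' @export
make_alpha <- function(n_samples, fs, f0, bandwidth = 2, power = 1, seed = 1) {
  stopifnot(n_samples > 0, bandwidth > 0, power >= 0)
  if (f0 - bandwidth / 2 <= 7.5 || f0 + bandwidth / 2 >= 13) {
    stop("alpha band [f0 - bw/2, f0 + bw/2] must lie inside (7.5, 13) Hz",
         call. = FALSE)
  }
  if (power == 0) return(numeric(n_samples))
  sh <- alpha_shape(f0, bandwidth)
  with_seed(seed, synth_from_psd(n_samples, fs, function(f) power * sh$fun(f)))
}

# band power and band COG of the background PSD, by fine trapezoid quadrature
background_band_stats <- function(exponent, scale, band = c(7.5, 13)) {
  f <- seq(band[1], band[2], by = 0.001)
  S <- scale * (f / 10)^(-exponent)
  w <- trapezoid_weights(f)
  P <- sum(w * S)
  list(power = P, cog = sum(w * S * f) / P)
}

#' Phase specification for the synthetic generator
#'
#' Describes one paradigm segment: its condition, duration, ground-truth
#' iAPF (the alpha-band COG of the total expected spectrum), alpha bump
#' shape and relative power, 1/f background, movement-artifact burst rate
#' and expected bad-channel fraction.
#'
#' @param phase_id `"I".."V"`.
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param duration_s segment duration in seconds.
#' @param true_iapf ground-truth band COG in Hz (in (7.5, 13)).
#' @param alpha_bandwidth FWHM of the alpha bump, Hz.
#' @param alpha_power_scale relative alpha power (1 = the eyes-closed
#'   reference level; eyes-open defaults to 1/3.5; 0 = no alpha).
#' @param background_exponent 1/f^beta exponent.
#' @param background_scale background PSD at 10 Hz, uV^2/Hz.
#' @param artifact_burst_rate movement-artifact bursts per minute.
#' @param bad_channel_rate expected fraction of failed channels in `[0, 1)`.
#' @return object of class `"synth_phase_spec"`.
#' @export
synth_phase_spec <- function(phase_id, condition, duration_s, true_iapf,
                             alpha_bandwidth = 2, alpha_power_scale = 1,
                             background_exponent = 1, background_scale = 1,
                             artifact_burst_rate = 0.2, bad_channel_rate = 0) {
  stopifnot(true_iapf > 7.5, true_iapf < 13, alpha_bandwidth > 0,
            alpha_power_scale >= 0, artifact_burst_rate >= 0,
            bad_channel_rate >= 0, bad_channel_rate < 1, duration_s > 0)
  structure(list(
    phase_id = match.arg(phase_id, c("I", "II", "III", "IV", "V")),
    condition = match.arg(condition, c("eyes_open", "eyes_closed")),
    duration_s = duration_s, true_iapf = true_iapf,
    alpha_bandwidth = alpha_bandwidth, alpha_power_scale = alpha_power_scale,
    background_exponent = background_exponent,
    background_scale = background_scale,
    artifact_burst_rate = artifact_burst_rate,
    bad_channel_rate = bad_channel_rate
  ), class = "synth_phase_spec")
}

#' Default per-phase ground-truth iAPF values
#'
#' Analyzed phases (II, IV, V) follow the study's reference means per cap
#' type: 10.22 / 10.36 / 10.41 Hz (dry) and 10.23 / 10.37 / 10.43 Hz (gel).
#' Phases I and III are not analyzed for iAPF; their defaults are the Phase
#' II value (baseline) and a value midway to Phase IV (cycling).
#'
#' @param cap_type `"dry"` or `"gel"`.
#' @return named numeric vector over phases I..V.
#' @export
default_true_iapf <- function(cap_type = c("dry", "gel")) {
  cap_type <- match.arg(cap_type)
  if (cap_type == "dry") {
    c(I = 10.22, II = 10.22, III = 10.29, IV = 10.36, V = 10.41)
  } else {
    c(I = 10.23, II = 10.23, III = 10.30, IV = 10.37, V = 10.43)
  }
}

# per-phase bad-channel rates: one minus the study's reliability fractions
# for phases I/III/V, with interpolated values for II and IV
default_bad_channel_rates <- function(cap_type = c("dry", "gel")) {
  cap_type <- match.arg(cap_type)
  if (cap_type == "dry") {
    c(I = 0.20, II = 0.15, III = 0.34, IV = 0.12, V = 0.09)
  } else {
    c(I = 0.05, II = 0.10, III = 0.15, IV = 0.16, V = 0.18)
  }
}

default_artifact_rates <- c(I = 0.2, II = 0.2, III = 6, IV = 2, V = 0.2)

#' Default phase-segment specifications for one cap session
#'
#' Builds the six paradigm segments (Phase I eyes open + eyes closed, then
#' Phases II-V) with the default ground-truth iAPFs, bad-channel rates and
#' artifact rates for the cap type. Eyes-open segments carry 1/3.5 of the
#' eyes-closed alpha power (the eyes-closed / eyes-open alpha peak contrast).
#'
#' @param cap_type `"dry"` or `"gel"`.
#' @param phase3_s cycling-phase duration in seconds.
#' @param bad_channel_rates named per-phase rates (default per cap type);
#'   set to 0 for failure-free data.
#' @return list of [synth_phase_spec()]s.
#' @export
default_phase_specs <- function(cap_type = c("dry", "gel"), phase3_s = 180,
                                bad_channel_rates = NULL) {
  cap_type <- match.arg(cap_type)
  iapf <- default_true_iapf(cap_type)
  if (is.null(bad_channel_rates)) bad_channel_rates <- default_bad_channel_rates(cap_type)
  eo <- 1 / 3.5
  mk <- function(ph, cond, dur, scale) {
    synth_phase_spec(ph, cond, dur, iapf[[ph]],
                     alpha_power_scale = scale,
                     artifact_burst_rate = default_artifact_rates[[ph]],
                     bad_channel_rate = bad_channel_rates[[ph]])
  }
  list(
    mk("I", "eyes_open", 120, eo), mk("I", "eyes_closed", 120, 1),
    mk("II", "eyes_closed", 120, 1), mk("III", "eyes_open", phase3_s, eo),
    mk("IV", "eyes_closed", 120, 1), mk("V", "eyes_closed", 120, 1)
  )
}

# per-channel alpha amplitude weights: posterior-dominant magnitude with
# zero spatial mean (a dipolar-like field, as a physical source projects
# both polarities onto the scalp), normalized to unit mean square so the
# whole-head mean alpha PSD equals the configured component PSD. The zero
# mean makes the component invariant under average re-referencing.
alpha_channel_weights <- function(mont) {
  y <- mont$positions[, "y"]                     # +1 anterior
  w <- sqrt(0.25 + 1.5 * ((1 - y) / 2)^2)
  w <- w - mean(w)
  w / sqrt(mean(w^2))
}

#' Synthesize one phase recording with ground truth
#'
#' Generates the multichannel signal for one or more back-to-back phase
#' segments (Phase I passes both its eyes-open and eyes-closed specs):
#' a common narrowband alpha source with a dipolar-like, posterior-dominant
#' scalp weighting (zero spatial mean, so the component is invariant under
#' average re-referencing), independent
#' 1/f background per channel, Poisson-timed movement-artifact bursts
#' (0.5-3 s of 5x-amplitude broadband noise on a random fifth of the
#' channels), and injected channel failures held fixed across the segments
#' of one recording: isoelectric (constant), saturated (rail-clipped) or
#' artifactual (a > 30 s stretch of 12x amplitude).
#'
#' @param specs a [synth_phase_spec()] or list of them (concatenated).
#' @param mont a [montage()].
#' @param subject_offset additive subject iAPF offset in Hz.
#' @param seed integer seed.
#' @param fs sampling rate (default 1024).
#' @param alpha_power_ec eyes-closed whole-head alpha power in uV^2
#'   (integrated over the band; default 17, giving a whole-head alpha peak
#'   density of about 8 uV^2/Hz at 2 Hz bandwidth).
#' @param rail_uv saturation rail in microvolts.
#' @param alpha_coherence fraction of alpha power carried by the common
#'   source (the rest is per-channel independent with the same spectrum;
#'   default 0.5, emulating the partial inter-electrode coherence of scalp
#'   alpha).
#' @return list with `recording` (annotated) and `ground_truth` (per
#'   segment: target iAPF = configured + offset; plus failed channels).
#' @export
synthesize_recording <- function(specs, mont, subject_offset = 0, seed = 1,
                                 fs = 1024, alpha_power_ec = 17, rail_uv = 500,
                                 alpha_coherence = 0.5) {
  if (inherits(specs, "synth_phase_spec")) specs <- list(specs)
  nch <- length(mont$labels)
  wamp <- alpha_channel_weights(mont)

  with_seed(seed, {
    # channel failures: fixed for the whole recording
    rate <- max(vapply(specs, `[[`, 0, "bad_channel_rate"))
    fail <- stats::runif(nch) < rate
    fail_type <- ifelse(fail, sample(c("isoelectric", "saturated", "artifactual"),
                                     nch, replace = TRUE), "none")
    iso_const <- stats::rnorm(nch, 0, 10)

    seg_data <- list(); annots <- list(); gt <- list(); t0 <- 0
    for (sp in specs) {
      n <- as.integer(round(sp$duration_s * fs))
      target <- sp$true_iapf + subject_offset
      apow <- alpha_power_ec * sp$alpha_power_scale
      bg <- background_band_stats(sp$background_exponent, sp$background_scale)
      f0 <- if (apow > 0) target + (bg$power / apow) * (target - bg$cog) else target
      x <- matrix(0, n, nch)
      if (apow > 0) {
        # partially coherent alpha: a common source plus per-channel
        # independent components (scalp alpha is only partially coherent
        # across electrodes; the independent part also averages down the
        # whole-head Welch noise)
        sh <- alpha_shape(f0, sp$alpha_bandwidth)
        apsd <- function(f) apow * sh$fun(f)
        rho <- alpha_coherence
        alpha <- synth_from_psd(n, fs, apsd)
        x <- x + outer(sqrt(rho) * alpha, wamp)
        if (rho < 1) {
          x <- x + synth_from_psd_mat(n, fs, apsd, nch) *
            matrix(sqrt(1 - rho) * wamp, n, nch, byrow = TRUE)
        }
      }
      x <- x + synth_from_psd_mat(n, fs, function(f) {
        sp$background_scale * (f / 10)^(-sp$background_exponent)
      }, nch)
      # movement-artifact bursts
      nburst <- stats::rpois(1, sp$artifact_burst_rate * sp$duration_s / 60)
      if (nburst > 0) {
        for (b in seq_len(nburst)) {
          dur <- stats::runif(1, 0.5, 3)
          st <- stats::runif(1, 0, max(0, sp$duration_s - dur))
          i0 <- floor(st * fs) + 1L
          i1 <- min(n, i0 + as.integer(dur * fs))
          hit <- sample(nch, max(1L, round(0.2 * nch)))
          amp <- 5 * stats::sd(x[, hit[1]])
          x[i0:i1, hit] <- x[i0:i1, hit] +
            matrix(stats::rnorm(length(i0:i1) * length(hit), 0, amp),
                   ncol = length(hit))
        }
      }
      # inject channel failures per segment (QC inspects each segment)
      for (c in which(fail)) {
        if (fail_type[c] == "isoelectric") {
          x[, c] <- iso_const[c]
        } else if (fail_type[c] == "saturated") {
          sdc <- stats::sd(x[, c])
          x[, c] <- pmin(rail_uv, pmax(-rail_uv, x[, c] * (20 * rail_uv / sdc)))
        } else {
          len <- as.integer(min(n, max(31, 0.35 * sp$duration_s) * fs))
          i0 <- sample.int(n - len + 1L, 1)
          x[i0:(i0 + len - 1L), c] <- x[i0:(i0 + len - 1L), c] * 12
        }
      }
      seg_data[[length(seg_data) + 1L]] <- x
      annots[[length(annots) + 1L]] <-
        phase_annotation(sp$phase_id, sp$condition, t0, sp$duration_s)
      gt[[length(gt) + 1L]] <- list(
        phase_id = sp$phase_id, condition = sp$condition,
        true_iapf = target, alpha_power = apow,
        alpha_present_expected = apow > 0
      )
      t0 <- t0 + sp$duration_s
    }
    x <- do.call(rbind, seg_data)
    rec <- recording(x, fs, mont$labels, "average", annots)
    list(
      recording = rec,
      ground_truth = list(
        segments = gt, subject_offset = subject_offset,
        failed_channels = mont$labels[fail],
        failure_types = stats::setNames(fail_type[fail], mont$labels[fail])
      )
    )
  })
}

#' Study-level synthetic configuration
#'
#' Defaults reproduce the reference study's conditions: 17 subjects, both
#' cap types, per-phase ground-truth iAPFs from the study's summary table,
#' between-subject iAPF spread 0.26 Hz, and 4 subjects generated without
#' considerable alpha in one analyzed phase so that 13 complete cases reach
#' the ANOVA. Subject offsets are centred to exact zero mean so the realized
#' study grand mean equals the configured per-phase value.
#'
#' @param n_subjects number of subjects (default 17).
#' @param cap_types character subset of `c("gel", "dry")`.
#' @param subject_effect_sd between-subject iAPF SD in Hz (default 0.26).
#' @param n_excluded_no_alpha subjects generated with zero alpha in one
#'   analyzed phase (default 4).
#' @param seed root seed; every unit seed derives from it.
#' @param fs sampling rate (default 1024).
#' @param phase3_s cycling-phase duration in seconds (default 180).
#' @param bad_channel_rates optional named per-phase rates applied to both
#'   caps (e.g. all zero for failure-free data); default cap-specific rates.
#' @param alpha_power_ec eyes-closed whole-head alpha power, uV^2.
#' @return object of class `"synth_study_config"`.
#' @export
synth_study_config <- function(n_subjects = 17, cap_types = c("gel", "dry"),
                               subject_effect_sd = 0.26,
                               n_excluded_no_alpha = 4, seed = 1,
                               fs = 1024, phase3_s = 180,
                               bad_channel_rates = NULL,
                               alpha_power_ec = 17) {
  cap_types <- match.arg(cap_types, several.ok = TRUE)
  stopifnot(n_subjects >= 1, n_excluded_no_alpha >= 0,
            n_excluded_no_alpha <= n_subjects, subject_effect_sd >= 0)
  phase_specs <- lapply(stats::setNames(cap_types, cap_types), function(ct) {
    default_phase_specs(ct, phase3_s, bad_channel_rates)
  })
  structure(list(
    n_subjects = as.integer(n_subjects), cap_types = cap_types,
    subject_effect_sd = subject_effect_sd,
    n_excluded_no_alpha = as.integer(n_excluded_no_alpha),
    seed = as.integer(seed), fs = fs, phase3_s = phase3_s,
    phase_specs = phase_specs, alpha_power_ec = alpha_power_ec
  ), class = "synth_study_config")
}

# deterministic per-unit seed derivation (< 2^31)
unit_seed <- function(root, subject, cap_idx, extra = 0L) {
  ((root %% 65011) * 32401 + subject * 613 + cap_idx * 97 + extra * 7) %% 2147483647L
}

# subject iAPF offsets: N(0, sd^2), centred to exact zero mean
subject_offsets <- function(config) {
  if (config$n_subjects == 1L) return(0)
  off <- with_seed(unit_seed(config$seed, 0L, 0L, 1L),
                   stats::rnorm(config$n_subjects, 0, config$subject_effect_sd))
  off - mean(off)
}

# which subjects are alpha-deficient, and in which analyzed phase
deficient_assignment <- function(config) {
  if (config$n_excluded_no_alpha == 0L) return(list())
  subj <- seq(config$n_subjects - config$n_excluded_no_alpha + 1L, config$n_subjects)
  phases <- c("II", "IV", "V")[(seq_along(subj) - 1L) %% 3L + 1L]
  stats::setNames(as.list(phases), as.character(subj))
}

# phase specs for one subject/cap, with alpha zeroed in a deficient phase
subject_phase_specs <- function(config, cap_type, subject) {
  specs <- config$phase_specs[[cap_type]]
  defic <- deficient_assignment(config)[[as.character(subject)]]
  if (!is.null(defic)) {
    specs <- lapply(specs, function(sp) {
      if (sp$phase_id == defic) sp$alpha_power_scale <- 0
      sp
    })
  }
  specs
}

#' Montage used for a cap type
#' @param cap_type `"dry"` (equidistant layout) or `"gel"` (extended 10-20).
#' @return a [montage()].
#' @export
cap_montage <- function(cap_type = c("dry", "gel")) {
  cap_type <- match.arg(cap_type)
  if (cap_type == "dry") montage_equidistant64() else montage_tentwenty64()
}

# lognormal parameters matching a target mean and SD
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Synthetic dry-cap impedance tables
#'
#' Per-subject, per-electrode electrode-skin impedances (kOhm) before Phase
#' I and after Phase V, drawn lognormal with the study's reported moments
#' (455 +/- 251 kOhm at start, 132 +/- 126 kOhm at end). Impedances are
#' descriptive inputs to aggregate; nothing downstream gates on them.
#'
#' @param config a [synth_study_config()].
#' @param mont montage whose electrodes get impedance values.
#' @return data.frame with columns `subject`, `electrode`, `start_kohm`,
#'   `end_kohm`.
#' @export
synthesize_impedances <- function(config, mont = cap_montage("dry")) {
  p1 <- lognormal_params(455, 251)
  p2 <- lognormal_params(132, 126)
  with_seed(unit_seed(config$seed, 0L, 0L, 2L), {
    n <- config$n_subjects * length(mont$labels)
    data.frame(
      subject = rep(seq_len(config$n_subjects), each = length(mont$labels)),
      electrode = rep(mont$labels, config$n_subjects),
      start_kohm = stats::rlnorm(n, p1$mu, p1$sigma),
      end_kohm = stats::rlnorm(n, p2$mu, p2$sigma),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a full synthetic study
#'
#' Produces one recording per subject, cap and phase (Phase I holds both
#' eye conditions). With `dir = NULL` the recordings are returned in memory;
#' otherwise each is written as `sub<ss>_<cap>_phase<P>.edf` (+ JSON
#' sidecar) under `dir`, together with a `manifest.json` holding the full
#' ground truth (subject offsets, per-segment target iAPFs, injected
#' failures, impedance tables). The same seed reproduces the study, and the
#' manifest, byte for byte.
#'
#' @param config a [synth_study_config()].
#' @param dir output directory, or `NULL` for in-memory.
#' @return invisibly, the manifest list; with `dir = NULL` the manifest plus
#'   a `units` list of `synthesize_recording()` outputs.
#' @export
synthesize_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_study_config"))
  offs <- subject_offsets(config)
  defic <- deficient_assignment(config)
  units <- list(); manifest_units <- list()
  for (ci in seq_along(config$cap_types)) {
    ct <- config$cap_types[ci]
    mont <- cap_montage(ct)
    for (s in seq_len(config$n_subjects)) {
      specs <- subject_phase_specs(config, ct, s)
      by_phase <- split(specs, vapply(specs, `[[`, "", "phase_id"))
      for (ph in names(by_phase)) {
        res <- synthesize_recording(
          by_phase[[ph]], mont, subject_offset = offs[s],
          seed = unit_seed(config$seed, s, ci, match(ph, c("I", "II", "III", "IV", "V")) + 10L),
          fs = config$fs, alpha_power_ec = config$alpha_power_ec
        )
        key <- sprintf("sub%02d_%s_phase%s", s, ct, ph)
        entry <- c(list(subject = s, cap_type = ct, phase_id = ph, file = NA_character_),
                   res$ground_truth)
        if (!is.null(dir)) {
          if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
          path <- file.path(dir, paste0(key, ".edf"))
          write_edf(res$recording, path)
          entry$file <- paste0(key, ".edf")
        } else {
          units[[key]] <- res
        }
        manifest_units[[key]] <- entry
      }
    }
  }
  manifest <- list(
    config = list(
      n_subjects = config$n_subjects, cap_types = config$cap_types,
      subject_effect_sd = config$subject_effect_sd,
      n_excluded_no_alpha = config$n_excluded_no_alpha,
      seed = config$seed, fs = config$fs, phase3_s = config$phase3_s,
      alpha_power_ec = config$alpha_power_ec
    ),
    subject_offsets = offs,
    deficient_subjects = defic,
    units = manifest_units,
    impedances_dry = if ("dry" %in% config$cap_types) {
      synthesize_impedances(config)
    }
  )
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  } else {
    invisible(c(manifest, list(units = units)))
  }
}

#' Simulate an iAPF table directly (no EEG synthesis)
#'
#' Draws a complete subjects x (cap x phase) table from the additive model
#' `y = mu[cap, phase] + subject + noise` with iid Gaussian subject effects
#' and residuals. Used for calibrating the RM-ANOVA engine (type-I error,
#' power direction) where synthesizing full EEG for hundreds of studies
#' would add nothing.
#'
#' @param n_subjects number of rows.
#' @param means 2 x 3 matrix of cell means (rows gel, dry; columns II, IV,
#'   V) or a single number for a null table.
#' @param subject_sd between-subject SD (default 0.26 Hz).
#' @param noise_sd residual SD (default 0.08 Hz).
#' @param seed integer seed.
#' @return an `iapf_table` (see [rm_anova_2x3()]): numeric matrix with
#'   columns `gel_II, gel_IV, gel_V, dry_II, dry_IV, dry_V`.
#' @export
simulate_iapf_table <- function(n_subjects = 13, means = 10.3,
                                subject_sd = 0.26, noise_sd = 0.08, seed = 1) {
  if (length(means) == 1L) means <- matrix(means, 2, 3)
  stopifnot(all(dim(means) == c(2, 3)))
  with_seed(seed, {
    subj <- stats::rnorm(n_subjects, 0, subject_sd)
    cells <- as.vector(t(means))                  # gel II,IV,V then dry II,IV,V
    y <- outer(subj, rep(1, 6)) +
      matrix(cells, n_subjects, 6, byrow = TRUE) +
      matrix(stats::rnorm(n_subjects * 6, 0, noise_sd), n_subjects, 6)
    colnames(y) <- c("gel_II", "gel_IV", "gel_V", "dry_II", "dry_IV", "dry_V")
    structure(y, class = c("iapf_table", "matrix"))
  })
}
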