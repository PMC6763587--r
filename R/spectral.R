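#' Welch power spectral density over consecutive 30 s intervals
#'
#' The segment is divided into consecutive complete intervals of
#' `interval_seconds` (incomplete trailing data is dropped); within each
#' interval, Welch's method averages periodograms of Hann-tapered
#' sub-windows (`win_seconds` long, fractional `overlap`), and the
#' per-channel PSD is the average over all sub-windows of all intervals.
#' One-sided density normalization: the integral of the PSD over frequency
#' equals the signal variance. Each sub-window is mean-detrended before
#' tapering. The default 4 s window gives a 0.25 Hz frequency grid, which
#' places the 7.5 and 13 Hz alpha-band edges exactly on grid points.
#'
#' @param segment an [recording()] of at least `interval_seconds`.
#' @param win_seconds sub-window length in seconds (default 4).
#' @param overlap fractional overlap of sub-windows (default 0.5).
#' @param interval_seconds interval length in seconds (default 30).
#' @return an object of class `"spectral_result"`: list with `freqs` (Hz,
#'   0..fs/2), `psd` (frequencies x channels, uV^2/Hz), `n_intervals`,
#'   `n_windows`, `fs`, `channel_labels`.
#' @export
welch_psd <- function(segment, win_seconds = 4, overlap = 0.5,
                      interval_seconds = 30) {
  stopifnot(inherits(segment, "eeg_recording"))
  fs <- segment$fs
  int_len <- as.integer(round(interval_seconds * fs))
  if (n_samples(segment) < int_len) {
    stop(sprintf("segment too short for spectral analysis (%.1f s < %g s)",
                 duration_s(segment), interval_seconds), call. = FALSE)
  }
  n_int <- n_samples(segment) %/% int_len
  L <- as.integer(round(win_seconds * fs))
  hop <- as.integer(round(L * (1 - overlap)))
  stopifnot(L > 1, hop >= 1)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))   # periodic Hann
  U <- sum(w^2)
  nfreq <- L %/% 2 + 1L
  acc <- matrix(0, nfreq, n_channels(segment))
  nw <- 0L
  for (k in seq_len(n_int)) {
    base <- (k - 1L) * int_len
    starts <- seq(0L, int_len - L, by = hop)
    for (s0 in starts) {
      seg <- segment$data[(base + s0 + 1):(base + s0 + L), , drop = FALSE]
      seg <- sweep(seg, 2, colMeans(seg))
      X <- stats::mvfft(seg * w)[seq_len(nfreq), , drop = FALSE]
      acc <- acc + Mod(X)^2
      nw <- nw + 1L
    }
  }
  psd <- acc * (2 / (fs * U * nw))
  psd[1, ] <- psd[1, ] / 2                        # DC not doubled
  if (L %% 2L == 0L) psd[nfreq, ] <- psd[nfreq, ] / 2  # Nyquist not doubled
  colnames(psd) <- segment$channel_labels
  structure(
    list(freqs = (0:(nfreq - 1)) * fs / L, psd = psd,
         n_intervals = n_int, n_windows = nw, fs = fs,
         channel_labels = segment$channel_labels),
    class = "spectral_result"
  )
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result> %d channels, df=%.3g Hz, %d intervals (%d windows)\n",
              ncol(x$psd), x$freqs[2] - x$freqs[1], x$n_intervals, x$n_windows))
  invisible(x)
}

#' Whole-head mean PSD
#'
#' Unweighted mean of the per-channel PSDs. After bad-channel interpolation
#' all channels (interpolated ones included) enter the mean; if a QC report
#' is supplied, only its good channels are averaged (for data that was never
#' interpolated).
#'
#' @param sr a [welch_psd()] result.
#' @param qc optional `channel_qc`; restricts the mean to good channels.
#' @return numeric vector (one value per frequency).
#' @export
mean_psd <- function(sr, qc = NULL) {
  stopifnot(inherits(sr, "spectral_result"))
  keep <- if (is.null(qc)) rep(TRUE, ncol(sr$psd)) else qc_good(qc)
  if (!any(keep)) stop("no usable channels for the whole-head mean", call. = FALSE)
  rowMeans(sr$psd[, keep, drop = FALSE])
}

# trapezoid weights for grid points inside [lo, hi]
band_index <- function(freqs, band) {
  which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
}

trapezoid_weights <- function(f) {
  k <- length(f)
  if (k == 1L) return(1)
  w <- numeric(k)
  w[1] <- (f[2] - f[1]) / 2
  w[k] <- (f[k] - f[k - 1]) / 2
  if (k > 2L) w[2:(k - 1)] <- (f[3:k] - f[1:(k - 2)]) / 2
  w
}

# trapezoid band average: integral over the band divided by band width
band_average <- function(freqs, power, band) {
  idx <- band_index(freqs, band)
  if (length(idx) < 2L) stop("spectrum does not cover band ",
                             paste(band, collapse = "-"), " Hz", call. = FALSE)
  f <- freqs[idx]
  sum(trapezoid_weights(f) * power[idx]) / (f[length(f)] - f[1])
}

#' Alpha-presence gate
#'
#' Compares the alpha peak of a (whole-head mean) spectrum to the average
#' power of the neighbouring theta and beta bands: `presence_ratio` is the
#' maximum PSD in the alpha band divided by the mean of the theta-band and
#' beta-band average powers (equal weight per band), and alpha is declared
#' present when the ratio is at least `threshold` (inclusive). A zero
#' neighbour power yields an infinite ratio, counted as present, with a
#' warning.
#'
#' @param freqs frequency grid in Hz (must cover 4-30 Hz).
#' @param power spectrum on that grid (uV^2/Hz, nonnegative).
#' @param alpha_band alpha band edges (default `c(7.5, 13)`).
#' @param theta_band,beta_band neighbouring bands (defaults `c(4, 7.5)` and
#'   `c(13, 30)`).
#' @param threshold presence threshold on the ratio (default 1.3).
#' @return list with `peak_power`, `peak_freq`, `neighbor_power`,
#'   `presence_ratio`, `alpha_present`, and the band definitions.
#' @export
alpha_presence <- function(freqs, power, alpha_band = c(7.5, 13),
                           theta_band = c(4, 7.5), beta_band = c(13, 30),
                           threshold = 1.3) {
  stopifnot(length(freqs) == length(power))
  if (min(freqs) > theta_band[1] + 1e-9 || max(freqs) < beta_band[2] - 1e-9) {
    stop("spectrum must cover the theta-alpha-beta range (4-30 Hz)", call. = FALSE)
  }
  aidx <- band_index(freqs, alpha_band)
  peak_power <- max(power[aidx])
  peak_freq <- freqs[aidx][which.max(power[aidx])]
  neighbor <- mean(c(band_average(freqs, power, theta_band),
                     band_average(freqs, power, beta_band)))
  if (neighbor <= 0) {
    warning("zero neighbouring-band power; presence ratio is infinite")
    ratio <- Inf
  } else {
    ratio <- peak_power / neighbor
  }
  list(alpha_band = alpha_band, peak_power = peak_power, peak_freq = peak_freq,
       neighbor_power = neighbor, presence_ratio = ratio,
       alpha_present = ratio >= threshold, threshold = threshold)
}

#' Centre-of-gravity individual alpha peak frequency
#'
#' The iAPF is the power-weighted mean frequency of the (whole-head mean)
#' spectrum over the alpha band: `sum(f * P(f)) / sum(P(f))` on the discrete
#' grid restricted to the band, with trapezoid integration weights so that
#' the band edges count half. The result always lies within the band, is
#' invariant to positive rescaling of the spectrum, and should only be
#' computed when the alpha-presence gate passes.
#'
#' @param freqs frequency grid in Hz.
#' @param power spectrum on that grid (nonnegative).
#' @param band alpha band (default `c(7.5, 13)`).
#' @return the iAPF in Hz.
#' @export
compute_iapf <- function(freqs, power, band = c(7.5, 13)) {
  stopifnot(length(freqs) == length(power))
  if (any(power < 0)) stop("spectrum must be nonnegative", call. = FALSE)
  idx <- band_index(freqs, band)
  if (length(idx) < 2L) stop("spectrum does not cover the alpha band", call. = FALSE)
  f <- freqs[idx]
  w <- trapezoid_weights(f) * power[idx]
  tot <- sum(w)
  if (tot <= 0) stop("no alpha-band power; compute_iapf requires a present alpha peak",
                     call. = FALSE)
  sum(w * f) / tot
}

#' Alpha metrics of a whole-head mean spectrum
#'
#' Convenience wrapper: presence gate plus (when present) the COG iAPF.
#'
#' @inheritParams alpha_presence
#' @return the [alpha_presence()] list with an extra `iapf` entry
#'   (`NA_real_` when alpha is absent).
#' @export
alpha_metrics <- function(freqs, power, alpha_band = c(7.5, 13),
                          theta_band = c(4, 7.5), beta_band = c(13, 30),
                          threshold = 1.3) {
  m <- alpha_presence(freqs, power, alpha_band, theta_band, beta_band, threshold)
  m$iapf <- if (m$alpha_present) compute_iapf(freqs, power, alpha_band) else NA_real_
  m
}
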