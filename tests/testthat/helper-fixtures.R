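# shared fixture builders (all data generated in code)

# small montage: n points of the 64-electrode equidistant layout
small_montage <- function(n = 16) {
  m <- montage_equidistant64()
  montage(m$labels[seq_len(n)], m$positions[seq_len(n), ], "custom")
}

# pure-tone recording
tone_recording <- function(freq, fs = 256, seconds = 60, amplitude = 1,
                           nch = 1) {
  t <- (0:(seconds * fs - 1)) / fs
  x <- matrix(amplitude * sin(2 * pi * freq * t), ncol = 1)[, rep(1, nch),
                                                           drop = FALSE]
  recording(x, fs, sprintf("ch%02d", seq_len(nch)))
}

# analytic single-pass magnitude response of the Butterworth bandpass
# design (prewarped bilinear lowpass-prototype formula) -- independent of
# the package's pole/SOS path
butter_magnitude_oracle <- function(f, fs, band = c(1, 40), order = 30) {
  fs2 <- 2 * fs
  wp <- function(x) fs2 * tan(pi * x / fs)
  w1 <- wp(band[1]); w2 <- wp(band[2])
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  W <- wp(f)
  Om <- (W^2 - w0^2) / (W * bw)
  1 / sqrt(1 + Om^(2 * (order / 2)))
}

# independent brute-force COG: direct summation with trapezoid edge
# weights, written out longhand
cog_oracle <- function(freqs, power, lo = 7.5, hi = 13) {
  num <- 0; den <- 0
  idx <- which(freqs >= lo - 1e-9 & freqs <= hi + 1e-9)
  for (j in seq_along(idx)) {
    i <- idx[j]
    w <- if (j == 1) {
      (freqs[idx[2]] - freqs[idx[1]]) / 2
    } else if (j == length(idx)) {
      (freqs[idx[j]] - freqs[idx[j - 1]]) / 2
    } else {
      (freqs[idx[j + 1]] - freqs[idx[j - 1]]) / 2
    }
    num <- num + w * freqs[i] * power[i]
    den <- den + w * power[i]
  }
  num / den
}

# fit the log-log slope of a PSD between two frequencies
psd_slope <- function(freqs, power, lo = 2, hi = 40) {
  keep <- freqs >= lo & freqs <= hi
  unname(stats::coef(stats::lm(log(power[keep]) ~ log(freqs[keep])))[2])
}
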