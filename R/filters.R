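#' Bandpass filter specification
#'
#' The preprocessing bandpass is a 30th-order Butterworth with cut-offs at
#' 1 and 40 Hz, realized as a cascade of 15 second-order sections and applied
#' forward-backward (zero phase). `order` counts the poles of one pass; the
#' -3 dB points of one pass sit exactly at the band edges, and the
#' forward-backward application squares the magnitude response.
#'
#' @param order total pole count of one pass (even; default 30).
#' @param band length-2 numeric, passband edges in Hz (default `c(1, 40)`).
#' @param zero_phase logical; apply forward-backward (default TRUE).
#' @return object of class `"filter_spec"`.
#' @export
filter_spec <- function(order = 30L, band = c(1, 40), zero_phase = TRUE) {
  order <- as.integer(order)
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  if (order < 2L || order %% 2L != 0L) {
    stop("filter order must be an even integer >= 2", call. = FALSE)
  }
  structure(list(family = "butterworth", order = order, band = as.numeric(band),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Design a digital Butterworth bandpass as second-order sections
#'
#' Analog Butterworth prototype -> lowpass-to-bandpass transform ->
#' bilinear transform with frequency prewarping. The cascade realization
#' keeps the design numerically sound at high orders, where the expanded
#' transfer-function polynomial is singular. Each section pairs one
#' conjugate pole pair with one zero at z = 1 and one at z = -1; the overall
#' gain is distributed evenly across sections and normalized so that the
#' response is exactly 1 at the geometric band centre.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz; band must lie below `fs / 2`.
#' @return numeric matrix, one row per section, columns `b0 b1 b2 a0 a1 a2`.
#' @export
butter_bandpass_sos <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  f1 <- spec$band[1]; f2 <- spec$band[2]
  if (f2 >= fs / 2) stop("upper band edge must be below Nyquist", call. = FALSE)
  n <- spec$order %/% 2L          # analog prototype order
  # prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * f1 / fs)   # prewarped edges
  w2 <- fs2 * tan(pi * f2 / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  # lowpass -> bandpass: each prototype pole maps to a conjugate-quad pair
  half <- pa * bw / 2
  r <- sqrt(half^2 - w0^2)
  s_poles <- c(half + r, half - r)
  # bilinear transform
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  # n zeros at s=0 -> z=1, n zeros at infinity -> z=-1; overall gain via the
  # bilinear gain identity, then normalized exactly at the centre frequency
  nsec <- n
  # keep conjugate pairs together: poles come as (half+r, half-r); conj pair
  # of pole p is Conj(p) which equals the mapping of Conj(pa) -- pair by
  # matching each pole with its conjugate
  is_real <- abs(Im(z_poles)) < 1e-9
  zre <- sort(Re(z_poles[is_real]))
  zcx <- z_poles[!is_real & Im(z_poles) > 0]
  pairs <- lapply(zcx, function(p) c(p, Conj(p)))
  if (length(zre) %% 2L != 0L) {
    stop("failed to pair poles (odd number of real poles)", call. = FALSE)
  }
  if (length(zre)) {
    for (i in seq(1, length(zre), by = 2)) {
      pairs[[length(pairs) + 1L]] <- complex(real = zre[c(i, i + 1)], imaginary = 0)
    }
  }
  if (length(pairs) != nsec) {
    stop("failed to pair conjugate poles (unstable design)", call. = FALSE)
  }
  # least-resonant sections first
  pairs <- pairs[order(vapply(pairs, function(p) max(Mod(p)), 0))]
  sos <- t(vapply(pairs, function(p) {
    c(1, 0, -1, 1, -Re(p[1] + p[2]), Re(p[1] * p[2]))
  }, numeric(6)))
  if (any(abs(sos[, 6]) >= 1)) {
    stop("unstable filter realization (pole on or outside unit circle)", call. = FALSE)
  }
  # normalize gain to 1 at the geometric centre frequency
  fc <- sqrt(f1 * f2)
  g <- Mod(sos_response(sos, fc, fs))
  sos[, 1:3] <- sos[, 1:3] / g^(1 / nsec)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

#' Complex frequency response of an SOS cascade
#'
#' @param sos section matrix from [butter_bandpass_sos()].
#' @param f frequencies in Hz (vector).
#' @param fs sampling rate in Hz.
#' @return complex vector `H(f)` for a single pass.
#' @export
sos_response <- function(sos, f, fs) {
  z1 <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z1 + sos[s, 3] * z1^2
    den <- 1 + sos[s, 5] * z1 + sos[s, 6] * z1^2
    h <- h * num / den
  }
  h
}

# forward-backward SOS filtering with odd-reflection edge padding
sos_filtfilt <- function(x, sos, padlen = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 3072L)
  if (padlen > 0) {
    pre <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
      x[(padlen + 1):2, , drop = FALSE]
    post <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
      x[(n - 1):(n - padlen), , drop = FALSE]
    xp <- rbind(pre, x, post)
  } else xp <- x
  y <- sos_filtfilt_cpp(xp, sos)
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n), , drop = FALSE]
  y
}

#' Zero-phase bandpass filter a recording
#'
#' Applies the Butterworth band limitation of the preprocessing chain:
#' forward-backward filtering through the second-order-section cascade of
#' [butter_bandpass_sos()], which removes DC, has zero group delay by
#' construction, and squares the single-pass magnitude response.
#'
#' @param rec an [recording()] with `fs > 2 * band[2]`.
#' @param spec a [filter_spec()] (default the 30th-order 1-40 Hz design).
#' @return the filtered recording (labels, fs, annotations preserved).
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * spec$band[2]) {
    stop("sampling rate too low for the requested passband", call. = FALSE)
  }
  sos <- butter_bandpass_sos(spec, rec$fs)
  y <- if (spec$zero_phase) {
    sos_filtfilt(rec$data, sos, padlen = min(n_samples(rec) - 1L, as.integer(10 * rec$fs)))
  } else {
    sos_filt_cpp(rec$data, sos)
  }
  if (any(!is.finite(y))) stop("filter produced non-finite output", call. = FALSE)
  recording(y, rec$fs, rec$channel_labels, rec$reference, rec$annotations)
}
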