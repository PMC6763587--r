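#' Per-channel quality control report
#'
#' Deterministic stand-in for expert visual inspection: a channel is bad iff
#' the cumulative duration of any failure condition exceeds 30 s within the
#' segment. Conditions are evaluated on consecutive 1 s windows:
#' \describe{
#'   \item{isoelectric}{window standard deviation below `iso_sd` microvolts.}
#'   \item{saturated}{at least half the window's samples within `rail_tol`
#'     (relative) of the channel's observed rail (its absolute maximum).}
#'   \item{artifactual}{window RMS amplitude with a robust z-score (median /
#'     MAD baseline over the channel's own windows) above `artifact_z`.}
#' }
#'
#' @param segment an [recording()] of at least 30 s.
#' @param iso_sd isoelectric SD threshold, microvolts (default 0.1).
#' @param rail_tol relative tolerance defining "at the rail" (default 0.01).
#' @param rail_min minimum observed absolute maximum (microvolts) for the
#'   saturation test to apply; physiological scalp EEG stays well below this,
#'   so smaller channels cannot be "saturated" at their own maximum
#'   (default 100).
#' @param artifact_z robust z-score threshold (default 5).
#' @param min_bad_s cumulative seconds of a condition required to call the
#'   channel bad (exclusive bound; default 30).
#' @return a `channel_qc` data.frame with columns `channel`, `status`
#'   (`good`/`bad`), `reason` (`none`/`isoelectric`/`saturated`/
#'   `artifactual`) and `artifact_seconds` (seconds of windows failing any
#'   condition).
#' @export
detect_bad_channels <- function(segment, iso_sd = 0.1, rail_tol = 0.01,
                                artifact_z = 5, min_bad_s = 30,
                                rail_min = 100) {
  stopifnot(inherits(segment, "eeg_recording"))
  fs <- segment$fs
  if (duration_s(segment) < min_bad_s) {
    stop(sprintf("segment too short for channel QC (%.1f s < %g s)",
                 duration_s(segment), min_bad_s), call. = FALSE)
  }
  win <- as.integer(round(fs))
  nwin <- n_samples(segment) %/% win
  x <- segment$data[seq_len(nwin * win), , drop = FALSE]
  nch <- ncol(x)
  status <- rep("good", nch); reason <- rep("none", nch)
  artifact_seconds <- numeric(nch)
  for (c in seq_len(nch)) {
    xc <- matrix(x[, c], nrow = win)            # one column per window
    mu <- colMeans(xc)
    sds <- sqrt(colMeans(xc^2) - mu^2)
    iso <- sds < iso_sd
    rail <- max(abs(x[, c]))
    sat <- if (rail >= rail_min) {
      colMeans(abs(xc) >= (1 - rail_tol) * rail) >= 0.5
    } else rep(FALSE, nwin)
    rms <- sqrt(colMeans(xc^2))
    med <- stats::median(rms)
    madn <- stats::mad(rms)                     # 1.4826 * MAD
    art <- if (madn > 0) (rms - med) / madn > artifact_z else rms > med
    # tie-break order: a rail-stuck channel is saturated, not isoelectric
    secs <- c(saturated = sum(sat), isoelectric = sum(iso), artifactual = sum(art))
    artifact_seconds[c] <- sum(iso | sat | art)
    if (any(secs > min_bad_s)) {
      status[c] <- "bad"
      reason[c] <- names(secs)[which.max(secs)]
    }
  }
  structure(
    data.frame(channel = segment$channel_labels, status = status,
               reason = reason, artifact_seconds = artifact_seconds,
               stringsAsFactors = FALSE),
    class = c("channel_qc", "data.frame")
  )
}

#' Logical vector of good channels from a QC report
#' @param qc a `channel_qc` report.
#' @return logical vector in channel order.
#' @export
qc_good <- function(qc) qc$status == "good"

#' QC report marking every channel good (for failure-free data)
#' @param channel_labels channel labels.
#' @return a `channel_qc` report.
#' @export
qc_all_good <- function(channel_labels) {
  structure(
    data.frame(channel = as.character(channel_labels), status = "good",
               reason = "none", artifact_seconds = 0, stringsAsFactors = FALSE),
    class = c("channel_qc", "data.frame")
  )
}

#' Write / read a QC report as delimited text
#' @param qc a `channel_qc` report.
#' @param path file path (tab-separated, with header).
#' @return `path` / the report.
#' @export
write_qc <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qc
#' @export
read_qc <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(df, class = c("channel_qc", "data.frame"))
}

#' Re-reference to the average of the good channels
#'
#' Subtracts, at every sample, the mean over the good channels from every
#' channel (bad channels included, so they stay on a comparable scale but
#' remain flagged). After the operation the mean over good channels is zero
#' to numerical precision at every sample, which makes downstream results
#' independent of the original physical reference.
#'
#' @param rec an [recording()].
#' @param qc a `channel_qc` report (default: all channels good).
#' @return the re-referenced recording (`reference = "average"`).
#' @export
average_reference <- function(rec, qc = qc_all_good(rec$channel_labels)) {
  stopifnot(inherits(rec, "eeg_recording"))
  good <- qc_good(qc)
  if (sum(good) < 2) {
    stop("average reference needs at least 2 good channels", call. = FALSE)
  }
  m <- rowMeans(rec$data[, good, drop = FALSE])
  recording(rec$data - m, rec$fs, rec$channel_labels, "average", rec$annotations)
}

# Perrin-style spherical-spline kernel: g(cosang) truncated at `nterms`
# Legendre terms with spline order m.
spline_g <- function(cosang, m = 4, nterms = 50) {
  x <- as.matrix(cosang)
  x[] <- pmin(1, pmax(-1, x))
  pl_prev <- array(1, dim = dim(x))             # P_0
  pl <- x                                       # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * pl
  for (l in 2:nterms) {
    pl_new <- ((2 * l - 1) * x * pl - (l - 1) * pl_prev) / l
    acc <- acc + (2 * l + 1) / (l * (l + 1))^m * pl_new
    pl_prev <- pl; pl <- pl_new
  }
  acc / (4 * pi)
}

# interpolation operator: rows = bad electrodes, cols = good electrodes
spline_operator <- function(pos_good, pos_bad, m = 4, nterms = 50, lambda = 1e-5) {
  ng <- nrow(pos_good)
  G <- spline_g(pos_good %*% t(pos_good), m, nterms)
  A <- rbind(cbind(G + lambda * diag(ng), rep(1, ng)), c(rep(1, ng), 0))
  E <- rbind(diag(ng), rep(0, ng))
  coef <- solve(A, E)                            # (ng+1) x ng
  Gbg <- spline_g(pos_bad %*% t(pos_good), m, nterms)
  cbind(Gbg, rep(1, nrow(pos_bad))) %*% coef
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each bad channel by a spherical-spline estimate from the good
#' channels (spline order `m = 4`, Legendre series truncated at 50 terms,
#' ridge regularization `1e-5` on the spline system). Good channels are
#' untouched; the interpolation reproduces spatially constant fields
#' exactly. After interpolation all channels are usable downstream (the QC
#' report still records which ones were reconstructed).
#'
#' @param rec an [recording()].
#' @param qc a `channel_qc` report.
#' @param mont a [montage()] covering all channel labels.
#' @param m spline order (default 4).
#' @param nterms Legendre truncation (default 50).
#' @param lambda ridge regularization (default 1e-5).
#' @param min_good minimum number of good channels required (default 10).
#' @return the recording with bad channels replaced; attribute
#'   `"interpolated"` lists the reconstructed labels.
#' @export
interpolate_bad <- function(rec, qc, mont, m = 4, nterms = 50,
                            lambda = 1e-5, min_good = 10) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(mont, "montage"))
  montage_covers(mont, rec$channel_labels)
  good <- qc_good(qc)
  if (all(good)) return(rec)
  if (sum(good) < min_good) {
    stop(sprintf("interpolation refused: only %d good channels (need >= %d)",
                 sum(good), min_good), call. = FALSE)
  }
  pos <- mont$positions[rec$channel_labels, , drop = FALSE]
  tr <- spline_operator(pos[good, , drop = FALSE], pos[!good, , drop = FALSE],
                        m, nterms, lambda)
  out <- rec$data
  out[, !good] <- rec$data[, good, drop = FALSE] %*% t(tr)
  res <- recording(out, rec$fs, rec$channel_labels, rec$reference, rec$annotations)
  attr(res, "interpolated") <- rec$channel_labels[!good]
  res
}
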