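# Minimal EDF/EDF+ I/O.
#
# EDF stores 16-bit integers per sample with a per-signal linear mapping
# between digital and physical ranges; the header is fixed-width ASCII.
# Writing uses one data record per second (so fs must be an integer),
# a symmetric physical range covering the data extrema, and digital range
# -32767..32767. Phase annotations go into an "EDF Annotations" signal
# (EDF+ time-stamped annotation lists) and, redundantly, into a JSON
# sidecar `<path>.json`, which also records the exact sample count when
# the last second had to be zero-padded.

ascii_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = -1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = width - 2), 1, width)
  ascii_field(s, width)
}

tal_time <- function(t) {
  s <- sub("0+$", "", sprintf("%.6f", t))
  sub("\\.$", "", s)
}

#' Write a recording to an EDF(+) file
#'
#' One data record per second; symmetric physical range covering the data
#' extrema (16-bit quantization error is at most `physical_range / 2^16`).
#' Labels longer than EDF's 16-character field are truncated with a warning.
#' Annotations, if present, are written both as an EDF+ annotation signal
#' and to a JSON sidecar `<path>.json` (the sidecar also records the exact
#' sample count and the reference descriptor).
#'
#' @param rec an [recording()] with integer `fs`.
#' @param path output file path.
#' @param physical_max half-range of the physical scale in microvolts;
#'   default covers the data extrema.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_max = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (any(!is.finite(rec$data))) stop("cannot write non-finite data", call. = FALSE)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf needs an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  nch <- n_channels(rec)
  nsmp <- n_samples(rec)
  nrec <- as.integer(ceiling(nsmp / fs))
  if (is.null(physical_max)) {
    physical_max <- max(abs(rec$data), 1e-6) * (1 + 1e-9)
  }
  # quantize against the values as actually written in the 8-char header
  # fields, so reader and writer agree exactly on the affine scale
  repeat {
    pmax_h <- as.numeric(trimws(edf_num(physical_max, 8)))
    pmin_h <- as.numeric(trimws(edf_num(-physical_max, 8)))
    if (pmax_h >= max(rec$data) && pmin_h <= min(rec$data)) break
    physical_max <- physical_max * (1 + 1e-4)
  }
  labs <- rec$channel_labels
  too_long <- nchar(labs) > 16
  if (any(too_long)) {
    warning("truncating EDF labels to 16 characters: ",
            paste(labs[too_long], collapse = ", "))
    labs <- substr(labs, 1, 16)
  }

  has_annot <- length(rec$annotations) > 0L
  tals <- character(nrec)
  if (has_annot) {
    for (k in seq_len(nrec)) tals[k] <- sprintf("+%s\x14\x14", tal_time(k - 1))
    for (a in rec$annotations) {
      k <- min(nrec, floor(a$onset) + 1L)
      tals[k] <- paste0(tals[k], sprintf("+%s\x15%s\x14%s:%s\x14",
                                         tal_time(a$onset), tal_time(a$duration),
                                         a$phase_id, a$condition))
    }
    annot_bytes <- max(32L, as.integer(2 * ceiling((max(nchar(tals, "bytes")) + 2) / 2)))
    annot_ns <- annot_bytes %/% 2L
  }

  ns <- nch + if (has_annot) 1L else 0L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    ascii_field("0", 8),
    ascii_field("X X X X", 80),
    ascii_field(sprintf("Startdate 01-JAN-2000 X X ref:%s", rec$reference), 80),
    ascii_field("01.01.00", 8), ascii_field("00.00.00", 8),
    edf_num(256L * (ns + 1L), 8),
    ascii_field(if (has_annot) "EDF+C" else "", 44),
    edf_num(nrec, 8), edf_num(1, 8), edf_num(ns, 4)
  )
  sig_labels <- c(labs, if (has_annot) "EDF Annotations")
  dims <- c(rep("uV", nch), if (has_annot) "")
  pmins <- c(rep(pmin_h, nch), if (has_annot) -1)
  pmaxs <- c(rep(pmax_h, nch), if (has_annot) 1)
  dmins <- c(rep(-32767L, nch), if (has_annot) -32768L)
  dmaxs <- c(rep(32767L, nch), if (has_annot) 32767L)
  spr <- c(rep(fs, nch), if (has_annot) annot_ns)
  hdr <- paste0(
    hdr,
    paste(vapply(sig_labels, ascii_field, "", width = 16), collapse = ""),
    paste(rep(ascii_field("", 80), ns), collapse = ""),
    paste(vapply(dims, ascii_field, "", width = 8), collapse = ""),
    paste(vapply(pmins, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmaxs, edf_num, "", width = 8), collapse = ""),
    paste(vapply(dmins, edf_num, "", width = 8), collapse = ""),
    paste(vapply(dmaxs, edf_num, "", width = 8), collapse = ""),
    paste(rep(ascii_field("", 80), ns), collapse = ""),
    paste(vapply(spr, edf_num, "", width = 8), collapse = ""),
    paste(rep(ascii_field("", 32), ns), collapse = "")
  )
  writeBin(charToRaw(hdr), con)

  scale <- (pmax_h - pmin_h) / 65534
  for (k in seq_len(nrec)) {
    i0 <- (k - 1L) * fs
    take <- min(fs, nsmp - i0)
    block <- matrix(0, nrow = fs, ncol = nch)
    if (take > 0) block[seq_len(take), ] <- rec$data[(i0 + 1):(i0 + take), , drop = FALSE]
    dig <- round((block - pmin_h) / scale) - 32767
    dig[dig > 32767] <- 32767; dig[dig < -32767] <- -32767
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
    if (has_annot) {
      payload <- charToRaw(tals[k])
      writeBin(c(payload, raw(annot_bytes - length(payload))), con)
    }
  }

  sidecar <- list(
    n_samples = nsmp, fs = fs, reference = rec$reference,
    annotations = lapply(rec$annotations, function(a) {
      list(phase_id = a$phase_id, condition = a$condition,
           onset = a$onset, duration = a$duration)
    })
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

parse_tal_stream <- function(raw_bytes) {
  txt <- rawToChar(raw_bytes[raw_bytes != as.raw(0)])
  out <- list()
  for (tal in strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]) {
    # each remaining TAL: "+onset[\x15duration]\x14text[\x14text...]"
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    dur <- if (length(head) > 1) suppressWarnings(as.numeric(head[2])) else NA_real_
    for (text in parts[-1]) {
      m <- regmatches(text, regexec("^(I|II|III|IV|V):(eyes_open|eyes_closed)$", text))[[1]]
      if (length(m) == 3 && is.finite(onset) && is.finite(dur)) {
        out[[length(out) + 1L]] <- phase_annotation(m[2], m[3], onset, dur)
      }
    }
  }
  out
}

#' Read an EDF(+) file into a recording
#'
#' All ordinary signals must share one sampling rate (heterogeneous rates are
#' refused). Physical units are converted to microvolts when the dimension
#' field reads `mV` or `V`. Phase annotations are taken from the JSON sidecar
#' `<path>.json` when present, else parsed from an EDF+ `"EDF Annotations"`
#' signal; the sidecar also restores the exact sample count when the final
#' data record was zero-padded on write.
#'
#' @param path EDF file path.
#' @param sidecar read the JSON sidecar if it exists (default TRUE).
#' @return an [recording()].
#' @export
read_edf <- function(path, sidecar = TRUE) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  fsz <- file.info(path)$size
  if (fsz < 256) stop("not a valid EDF file (truncated header): ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rdnum <- function(n) suppressWarnings(as.numeric(trimws(rd(n))))
  rd(8); rd(80)
  recid <- rd(80)
  rd(8); rd(8)
  hdr_bytes <- rdnum(8)
  rd(44)
  nrec <- rdnum(8)
  recdur <- rdnum(8)
  ns <- rdnum(4)
  if (!is.finite(ns) || ns < 1 || !is.finite(nrec) || nrec < 1 ||
      !is.finite(recdur) || recdur <= 0 || hdr_bytes != 256 * (ns + 1)) {
    stop("not a valid EDF file (malformed header): ", path, call. = FALSE)
  }
  sig_lab <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin <- vapply(seq_len(ns), function(i) rdnum(8), 0)
  pmax <- vapply(seq_len(ns), function(i) rdnum(8), 0)
  dmin <- vapply(seq_len(ns), function(i) rdnum(8), 0)
  dmax <- vapply(seq_len(ns), function(i) rdnum(8), 0)
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- vapply(seq_len(ns), function(i) rdnum(8), 0)
  rd(32 * ns)

  is_annot <- sig_lab == "EDF Annotations"
  sig_idx <- which(!is_annot)
  if (!length(sig_idx)) stop("EDF file contains no data signals", call. = FALSE)
  rates <- spr[sig_idx] / recdur
  if (length(unique(rates)) != 1L) {
    stop("unsupported EDF: signals have heterogeneous sampling rates", call. = FALSE)
  }
  fs <- rates[1]
  rec_words <- sum(spr)
  expected <- hdr_bytes + nrec * rec_words * 2
  if (fsz < expected) {
    stop(sprintf("truncated EDF file: expected %d bytes, found %d", expected, fsz),
         call. = FALSE)
  }

  nch <- length(sig_idx)
  data <- matrix(0, nrow = nrec * spr[sig_idx[1]], ncol = nch)
  annot_raw <- list()
  offs <- c(0, cumsum(spr))
  for (k in seq_len(nrec)) {
    words <- readBin(con, "integer", rec_words, size = 2L,
                     endian = "little", signed = TRUE)
    for (j in seq_along(sig_idx)) {
      i <- sig_idx[j]
      seg <- words[(offs[i] + 1):(offs[i] + spr[i])]
      data[((k - 1) * spr[i] + 1):(k * spr[i]), j] <- seg
    }
    if (any(is_annot)) {
      i <- which(is_annot)[1]
      w <- words[(offs[i] + 1):(offs[i] + spr[i])]
      annot_raw[[k]] <- writeBin(as.integer(w), raw(), size = 2L, endian = "little")
    }
  }
  # digital -> physical, with unit conversion to microvolts
  unit_mult <- ifelse(dims[sig_idx] == "mV", 1e3,
                      ifelse(dims[sig_idx] == "V", 1e6, 1))
  for (j in seq_along(sig_idx)) {
    i <- sig_idx[j]
    sc <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    data[, j] <- (data[, j] - dmin[i]) * sc + pmin[i]
    if (unit_mult[j] != 1) data[, j] <- data[, j] * unit_mult[j]
  }

  annotations <- list()
  reference <- "average"
  m <- regmatches(recid, regexec("ref:([^ ]+)", recid))[[1]]
  if (length(m) == 2) reference <- m[2]

  side_path <- paste0(path, ".json")
  if (sidecar && file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = FALSE)
    if (!is.null(side$n_samples) && side$n_samples <= nrow(data)) {
      data <- data[seq_len(side$n_samples), , drop = FALSE]
    }
    if (!is.null(side$reference)) reference <- side$reference
    annotations <- lapply(side$annotations, function(a) {
      phase_annotation(a$phase_id, a$condition, a$onset, a$duration)
    })
  } else if (length(annot_raw)) {
    annotations <- parse_tal_stream(do.call(c, annot_raw))
  }

  recording(data, fs, sig_lab[sig_idx], reference, annotations)
}
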