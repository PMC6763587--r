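#' Multichannel EEG recording
#'
#' The core container: a samples-by-channels matrix in microvolts with a
#' sampling rate, ordered channel labels, a reference descriptor and optional
#' phase annotations. Saturation is represented by rail values (finite), never
#' by `NA`/`NaN`.
#'
#' @param data numeric matrix, `n_samples` x `n_channels`, microvolts.
#' @param fs sampling rate in samples/s (> 0; the cycling paradigm records at
#'   1024 samples/s).
#' @param channel_labels character vector of unique labels, one per column.
#' @param reference `"average"` or the label of a physical reference
#'   electrode (e.g. `"M1"` for the dry cap, `"CPz"` for the gel cap).
#' @param annotations list of [phase_annotation()] objects (may be empty).
#' @return An object of class `"eeg_recording"`.
#' @export
recording <- function(data, fs, channel_labels,
                      reference = "average", annotations = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channel_labels <- as.character(channel_labels)
  if (ncol(data) != length(channel_labels)) {
    stop("n_channels must equal length(channel_labels)", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("recording data must be finite (represent saturation by rail values, not NaN)",
         call. = FALSE)
  }
  colnames(data) <- channel_labels
  annotations <- validate_annotations(annotations)
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         reference = reference, annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz, ref=%s, %d annotations\n",
              ncol(x$data), nrow(x$data) / x$fs, x$fs, x$reference,
              length(x$annotations)))
  invisible(x)
}

#' Number of samples / channels / duration helpers
#' @param rec an [recording()].
#' @return integer or numeric scalar.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' @rdname n_samples
#' @export
n_channels <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) nrow(rec$data) / rec$fs

#' Phase annotation
#'
#' Marks one paradigm interval. Time is in seconds from recording start;
#' intervals are half-open `[onset, onset + duration)` and sample indices
#' derived from them are 0-based.
#'
#' @param phase_id one of `"I".."V"`.
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param onset onset in seconds (>= 0).
#' @param duration duration in seconds (> 0).
#' @return An object of class `"phase_annotation"`.
#' @export
phase_annotation <- function(phase_id, condition, onset, duration) {
  phase_id <- match.arg(phase_id, c("I", "II", "III", "IV", "V"))
  condition <- match.arg(condition, c("eyes_open", "eyes_closed"))
  stopifnot(is.finite(onset), onset >= 0, is.finite(duration), duration > 0)
  structure(list(phase_id = phase_id, condition = condition,
                 onset = as.numeric(onset), duration = as.numeric(duration)),
            class = "phase_annotation")
}

validate_annotations <- function(annotations) {
  if (!length(annotations)) return(list())
  ok <- vapply(annotations, inherits, TRUE, what = "phase_annotation")
  if (!all(ok)) stop("annotations must be phase_annotation objects", call. = FALSE)
  ons <- vapply(annotations, `[[`, 0, "onset")
  annotations <- annotations[order(ons)]
  ons <- vapply(annotations, `[[`, 0, "onset")
  ends <- ons + vapply(annotations, `[[`, 0, "duration")
  if (length(annotations) > 1L && any(ons[-1] < ends[-length(ends)] - 1e-9)) {
    stop("phase annotations must not overlap", call. = FALSE)
  }
  annotations
}

#' Standard five-phase cycling paradigm schedule
#'
#' Builds the annotation list for the endurance-cycling paradigm: Phase I
#' baseline (2 min eyes open then 2 min eyes closed), Phase II pre-cycling
#' (120 s), Phase III cycling until exhaustion (duration free, eyes open),
#' Phase IV active recovery (120 s) and Phase V passive recovery (120 s),
#' all eyes closed from Phase II onward.
#'
#' @param phase3_s duration of the cycling phase in seconds.
#' @return list of [phase_annotation()]s, back to back from t = 0.
#' @export
paradigm_schedule <- function(phase3_s = 180) {
  specs <- list(
    list("I", "eyes_open", 120), list("I", "eyes_closed", 120),
    list("II", "eyes_closed", 120), list("III", "eyes_open", phase3_s),
    list("IV", "eyes_closed", 120), list("V", "eyes_closed", 120)
  )
  t0 <- 0
  out <- lapply(specs, function(s) {
    a <- phase_annotation(s[[1]], s[[2]], t0, s[[3]])
    t0 <<- t0 + s[[3]]
    a
  })
  out
}

segment_key <- function(phase_id, condition) {
  if (phase_id == "I") paste0("I_", sub("eyes_", "", condition)) else phase_id
}

#' Split a recording into per-phase segments
#'
#' Cuts the recording at its phase annotations. Each annotation yields one
#' sub-recording with exactly `duration * fs` samples (half-open interval,
#' 0-based sample indexing). Phase I yields separate eyes-open and
#' eyes-closed segments, keyed `"I_open"` and `"I_closed"`; other phases are
#' keyed by their roman numeral.
#'
#' @param rec an [recording()] with annotations.
#' @return named list of `eeg_recording` segments (annotation carried over).
#' @export
segment_by_phase <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(rec$annotations)) {
    stop("recording has no phase annotations to segment by", call. = FALSE)
  }
  out <- list()
  for (a in rec$annotations) {
    i0 <- round(a$onset * rec$fs)        # 0-based first sample
    nsmp <- round(a$duration * rec$fs)
    if (i0 + nsmp > n_samples(rec)) {
      stop(sprintf("annotation %s/%s extends past end of recording",
                   a$phase_id, a$condition), call. = FALSE)
    }
    seg <- recording(rec$data[(i0 + 1):(i0 + nsmp), , drop = FALSE],
                     rec$fs, rec$channel_labels, rec$reference,
                     list(phase_annotation(a$phase_id, a$condition, 0, a$duration)))
    out[[segment_key(a$phase_id, a$condition)]] <- seg
  }
  out
}

#' Extract one phase segment
#'
#' @param rec annotated [recording()].
#' @param phase_id `"I".."V"`.
#' @param condition required for Phase I (which has both conditions);
#'   ignored otherwise unless given.
#' @return an `eeg_recording` segment.
#' @export
get_phase <- function(rec, phase_id, condition = NULL) {
  segs <- segment_by_phase(rec)
  key <- if (phase_id == "I") {
    if (is.null(condition)) stop("Phase I needs condition", call. = FALSE)
    segment_key(phase_id, condition)
  } else phase_id
  if (is.null(segs[[key]])) {
    stop("no annotation for phase ", key, " in this recording", call. = FALSE)
  }
  segs[[key]]
}
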