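#' Channel reliability of one phase segment
#'
#' The percentage of channels retained after bad-channel exclusion,
#' `100 * retained / total`, kept in exact rational form until display.
#'
#' @param qc a `channel_qc` report for the segment.
#' @param subject,cap_type,phase_id optional identifiers carried into the
#'   record.
#' @return data.frame row with `subject`, `cap_type`, `phase_id`,
#'   `n_channels_total`, `n_channels_retained`, `reliability` (percent).
#' @export
channel_reliability <- function(qc, subject = NA, cap_type = NA_character_,
                                phase_id = NA_character_) {
  total <- nrow(qc)
  retained <- sum(qc_good(qc))
  data.frame(subject = subject, cap_type = cap_type, phase_id = phase_id,
             n_channels_total = total, n_channels_retained = retained,
             reliability = 100 * retained / total,
             stringsAsFactors = FALSE)
}

#' Per-electrode topographic grand average
#'
#' Aggregates a per-subject, per-electrode scalar (reliability fraction,
#' impedance in kOhm, ...) into a plotting-ready per-electrode mean and
#' population standard deviation across subjects (and phases, if the input
#' pools them). Missing entries - e.g. excluded sessions - are omitted
#' pairwise, with the contributing count reported per electrode.
#'
#' @param records data.frame with columns `electrode`, `value`, and any
#'   identifier columns; or a numeric matrix (rows = subjects, columns =
#'   electrodes).
#' @param mont optional [montage()]; if given, every electrode must belong
#'   to it and the output is ordered by the montage.
#' @return data.frame with `electrode`, `mean`, `std` (population, divisor
#'   n), `n`.
#' @export
topographic_grand_average <- function(records, mont = NULL) {
  if (is.matrix(records)) {
    if (is.null(colnames(records))) {
      stop("matrix input needs electrode labels as column names", call. = FALSE)
    }
    records <- data.frame(
      electrode = rep(colnames(records), each = nrow(records)),
      value = as.vector(records), stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("electrode", "value") %in% names(records)))
  if (!is.null(mont)) {
    extra <- setdiff(unique(records$electrode), mont$labels)
    if (length(extra)) {
      stop("electrodes not in montage: ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  sp <- split(records$value[!is.na(records$value)],
              records$electrode[!is.na(records$value)])
  out <- data.frame(
    electrode = names(sp),
    mean = vapply(sp, mean, 0),
    std = vapply(sp, function(v) sqrt(mean((v - mean(v))^2)), 0),
    n = vapply(sp, length, 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(mont)) out <- out[match(intersect(mont$labels, out$electrode),
                                       out$electrode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a topographic summary as delimited text
#' @param summary output of [topographic_grand_average()].
#' @param path file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_topographic <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
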