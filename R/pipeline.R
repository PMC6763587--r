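#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the analysis chain with the defaults used
#' throughout: 30th-order 1-40 Hz zero-phase Butterworth, 1 s QC windows
#' with the isoelectric / saturated / artifactual thresholds, Welch PSD
#' (4 s Hann, 50% overlap, 30 s intervals), alpha band 7.5-13 Hz flanked by
#' theta 4-7.5 and beta 13-30 Hz, presence threshold 1.3, analyzed phases
#' II / IV / V. Any override travels with the report's provenance.
#'
#' @param study a [synth_study_config()] (recordings generated in memory,
#'   unit by unit) or a directory produced by [synthesize_study()].
#' @param filter a [filter_spec()].
#' @param qc list of [detect_bad_channels()] thresholds.
#' @param welch list of [welch_psd()] parameters.
#' @param alpha_band,theta_band,beta_band band edges in Hz.
#' @param presence_threshold alpha-presence ratio threshold (default 1.3).
#' @param analyzed_phases segment keys entering the iAPF statistics.
#' @param gate_phases segment keys on which the alpha-presence subject
#'   exclusion rule is evaluated (analyzed phases plus Phase I eyes
#'   closed).
#' @param process_phases segment keys processed at all (QC, reliability,
#'   PSD); Phases I and III are processed but never analyzed for iAPF.
#' @param qc_only_phases subset of `process_phases` that get channel QC and
#'   reliability only, skipping the spectral chain (useful for segments
#'   that feed neither the gate nor the statistics).
#' @param iapf_mode `"mean_psd"` (default): one COG on the
#'   interval-averaged whole-head mean PSD; `"per_interval"`: one COG per
#'   30 s interval, averaged. The presence gate always uses the
#'   interval-averaged spectrum.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(study,
                            filter = filter_spec(),
                            qc = list(iso_sd = 0.1, rail_tol = 0.01,
                                      artifact_z = 5, min_bad_s = 30),
                            welch = list(win_seconds = 4, overlap = 0.5,
                                         interval_seconds = 30),
                            alpha_band = c(7.5, 13),
                            theta_band = c(4, 7.5), beta_band = c(13, 30),
                            presence_threshold = 1.3,
                            analyzed_phases = c("II", "IV", "V"),
                            gate_phases = c("I_closed", "II", "IV", "V"),
                            process_phases = c("I_open", "I_closed", "II",
                                               "III", "IV", "V"),
                            qc_only_phases = character(0),
                            iapf_mode = c("mean_psd", "per_interval")) {
  iapf_mode <- match.arg(iapf_mode)
  structure(list(study = study, filter = filter, qc = qc, welch = welch,
                 alpha_band = alpha_band, theta_band = theta_band,
                 beta_band = beta_band,
                 presence_threshold = presence_threshold,
                 analyzed_phases = analyzed_phases,
                 gate_phases = gate_phases,
                 process_phases = process_phases,
                 qc_only_phases = qc_only_phases,
                 iapf_mode = iapf_mode),
            class = "pipeline_config")
}

#' Process one phase segment: QC, filter, re-reference, interpolate, Welch
#'
#' The per-segment chain in the order of the preprocessing pipeline:
#' bad-channel detection on the raw segment, zero-phase bandpass, average
#' re-reference excluding bad channels, spherical-spline interpolation of
#' the bad channels (skipped, with the mean then restricted to good
#' channels, if fewer than 10 good channels remain), Welch PSD over 30 s
#' intervals, whole-head mean PSD, presence gate and (when present) the COG
#' iAPF.
#'
#' @param seg an [recording()] segment.
#' @param mont a [montage()].
#' @param config a [pipeline_config()].
#' @return list with `qc`, `reliability`, `metrics` (from
#'   [alpha_metrics()]), `mean_psd`, `freqs`.
#' @export
process_segment <- function(seg, mont, config = pipeline_config(NULL)) {
  qc <- do.call(detect_bad_channels, c(list(seg), config$qc))
  rel <- channel_reliability(qc)
  if (sum(qc_good(qc)) < 2) {
    stop("fewer than 2 good channels; segment unusable", call. = FALSE)
  }
  filt <- bandpass(seg, config$filter)
  reref <- average_reference(filt, qc)
  interp_ok <- sum(qc_good(qc)) >= 10
  prepped <- if (interp_ok) interpolate_bad(reref, qc, mont) else reref
  sr <- do.call(welch_psd, c(list(prepped), config$welch))
  mps <- mean_psd(sr, qc = if (interp_ok) NULL else qc)
  metrics <- alpha_metrics(sr$freqs, mps,
                           alpha_band = config$alpha_band,
                           theta_band = config$theta_band,
                           beta_band = config$beta_band,
                           threshold = config$presence_threshold)
  if (identical(config$iapf_mode, "per_interval") && isTRUE(metrics$alpha_present)) {
    int_len <- as.integer(round(config$welch$interval_seconds * prepped$fs))
    n_int <- n_samples(prepped) %/% int_len
    per <- vapply(seq_len(n_int), function(k) {
      chunk <- recording(prepped$data[((k - 1) * int_len + 1):(k * int_len), ,
                                      drop = FALSE],
                         prepped$fs, prepped$channel_labels)
      srk <- do.call(welch_psd, c(list(chunk), config$welch))
      mk <- mean_psd(srk, qc = if (interp_ok) NULL else qc)
      compute_iapf(srk$freqs, mk, band = config$alpha_band)
    }, 0)
    metrics$iapf <- mean(per)
    metrics$iapf_per_interval <- per
  }
  list(qc = qc, reliability = rel, metrics = metrics,
       mean_psd = mps, freqs = sr$freqs)
}

# enumerate study units; each element knows how to produce its recording
study_units <- function(config) {
  study <- config$study
  if (inherits(study, "synth_study_config")) {
    offs <- subject_offsets(study)
    units <- list()
    for (ci in seq_along(study$cap_types)) {
      ct <- study$cap_types[ci]
      for (s in seq_len(study$n_subjects)) {
        specs <- subject_phase_specs(study, ct, s)
        by_phase <- split(specs, vapply(specs, `[[`, "", "phase_id"))
        for (ph in names(by_phase)) {
          sp <- by_phase[[ph]]
          seed <- unit_seed(study$seed, s, ci,
                            match(ph, c("I", "II", "III", "IV", "V")) + 10L)
          units[[sprintf("sub%02d_%s_phase%s", s, ct, ph)]] <- list(
            subject = s, cap_type = ct, phase_id = ph,
            load = local({
              sp_ <- sp; ct_ <- ct; off_ <- offs[s]; seed_ <- seed
              function() synthesize_recording(
                sp_, cap_montage(ct_), subject_offset = off_, seed = seed_,
                fs = study$fs, alpha_power_ec = study$alpha_power_ec
              )$recording
            })
          )
        }
      }
    }
    list(units = units, montages = lapply(
      stats::setNames(study$cap_types, study$cap_types), cap_montage),
      seed = study$seed)
  } else if (is.character(study) && dir.exists(study)) {
    mf <- file.path(study, "manifest.json")
    files <- if (file.exists(mf)) {
      man <- jsonlite::read_json(mf, simplifyVector = FALSE)
      lapply(man$units, function(u) {
        list(subject = u$subject, cap_type = u$cap_type, phase_id = u$phase_id,
             file = file.path(study, u$file))
      })
    } else {
      edfs <- list.files(study, pattern = "\\.edf$", full.names = TRUE)
      lapply(edfs, function(f) {
        m <- regmatches(basename(f),
                        regexec("sub([0-9]+)_([a-z]+)_phase([IV]+)", basename(f)))[[1]]
        if (length(m) != 4) stop("cannot parse study filename: ", f, call. = FALSE)
        list(subject = as.integer(m[2]), cap_type = m[3], phase_id = m[4], file = f)
      })
    }
    units <- list()
    caps <- unique(vapply(files, `[[`, "", "cap_type"))
    for (u in files) {
      units[[sprintf("sub%02d_%s_phase%s", u$subject, u$cap_type, u$phase_id)]] <-
        list(subject = u$subject, cap_type = u$cap_type, phase_id = u$phase_id,
             load = local({ f <- u$file; function() read_edf(f) }))
    }
    list(units = units,
         montages = lapply(stats::setNames(caps, caps), cap_montage),
         seed = NA_integer_)
  } else {
    stop("study must be a synth_study_config or an existing study directory",
         call. = FALSE)
  }
}

#' Run the full study analysis
#'
#' Executes, for every subject, cap and processed phase segment:
#' segmentation, channel QC, zero-phase bandpass, average re-reference,
#' spherical-spline interpolation, Welch PSD, whole-head mean PSD, the
#' alpha-presence gate and the COG iAPF. Subjects without considerable
#' alpha (presence ratio below threshold) in one or more gated phases are
#' excluded entirely; the remaining complete cases enter the 2 x 3
#' RM-ANOVA when both cap types are present. Stage failures are recorded
#' per segment and the pipeline continues; it fails globally only when
#' fewer than 3 complete subjects remain for the statistics.
#'
#' @param config a [pipeline_config()].
#' @param run_anova run the RM-ANOVA on the retained complete cases
#'   (requires both cap types; default TRUE when possible).
#' @return object of class `"study_report"`: list with `segments` (one row
#'   per processed segment: reliability, presence ratio, iAPF),
#'   `exclusions`, `retained_subjects`, `iapf_table`, `anova`,
#'   `reliability`, `errors`, `provenance`.
#' @export
run_pipeline <- function(config, run_anova = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  su <- study_units(config)
  seg_rows <- list(); err_rows <- list()
  for (key in names(su$units)) {
    u <- su$units[[key]]
    rec <- tryCatch(u$load(), error = function(e) e)
    if (inherits(rec, "error")) {
      err_rows[[key]] <- data.frame(unit = key, segment = NA_character_,
                                    message = conditionMessage(rec),
                                    stringsAsFactors = FALSE)
      next
    }
    segs <- segment_by_phase(rec)
    for (sk in names(segs)) {
      if (!sk %in% config$process_phases) next
      qc_only <- sk %in% config$qc_only_phases
      res <- tryCatch(
        if (qc_only) {
          qc <- do.call(detect_bad_channels, c(list(segs[[sk]]), config$qc))
          list(qc = qc, reliability = channel_reliability(qc),
               metrics = list(presence_ratio = NA_real_,
                              alpha_present = NA, iapf = NA_real_))
        } else {
          process_segment(segs[[sk]], su$montages[[u$cap_type]], config)
        },
        error = function(e) e
      )
      if (inherits(res, "error")) {
        err_rows[[paste(key, sk)]] <- data.frame(
          unit = key, segment = sk, message = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      seg_rows[[paste(key, sk)]] <- data.frame(
        subject = u$subject, cap_type = u$cap_type, segment = sk,
        n_channels = res$reliability$n_channels_total,
        n_retained = res$reliability$n_channels_retained,
        reliability = res$reliability$reliability,
        presence_ratio = res$metrics$presence_ratio,
        alpha_present = res$metrics$alpha_present,
        iapf = if (isTRUE(res$metrics$alpha_present)) res$metrics$iapf else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    rm(rec, segs)
  }
  segments <- do.call(rbind, c(seg_rows, list(NULL)))
  rownames(segments) <- NULL
  errors <- do.call(rbind, c(err_rows, list(NULL)))

  # subject-level exclusion: no considerable alpha in >= 1 gated phase
  subjects <- sort(unique(segments$subject))
  excl <- list()
  for (s in subjects) {
    rows <- segments[segments$subject == s & segments$segment %in% config$gate_phases, ]
    missing_segs <- length(unique(paste(rows$cap_type, rows$segment))) <
      length(su$montages) * length(config$gate_phases)
    if (nrow(rows) == 0 || any(!rows$alpha_present)) {
      bad <- rows$segment[!rows$alpha_present]
      excl[[as.character(s)]] <- data.frame(
        subject = s,
        reason = sprintf("no considerable alpha activity in phase(s): %s",
                         paste(unique(bad), collapse = ", ")),
        stringsAsFactors = FALSE)
    } else if (missing_segs) {
      excl[[as.character(s)]] <- data.frame(
        subject = s, reason = "gated phase segment missing or failed",
        stringsAsFactors = FALSE)
    }
  }
  exclusions <- do.call(rbind, c(excl, list(NULL)))
  retained <- setdiff(subjects, exclusions$subject)
  if (length(retained) < 3) {
    stop(sprintf("only %d subjects remain after the alpha criterion; need >= 3",
                 length(retained)), call. = FALSE)
  }

  caps <- names(su$montages)
  tab <- NULL; anova <- NULL
  long <- segments[segments$subject %in% retained &
                     segments$segment %in% config$analyzed_phases, ]
  long <- data.frame(subject = long$subject, cap = long$cap_type,
                     phase = long$segment, iapf = long$iapf,
                     stringsAsFactors = FALSE)
  if (run_anova && all(c("gel", "dry") %in% caps)) {
    tab <- as_iapf_table(long)
    anova <- rm_anova_2x3(tab)
  }

  reliability <- stats::aggregate(reliability ~ cap_type + segment,
                                  data = segments, FUN = mean)
  structure(
    list(segments = segments, exclusions = exclusions,
         retained_subjects = retained, iapf_long = long, iapf_table = tab,
         anova = anova, reliability = reliability, errors = errors,
         provenance = list(
           seed = su$seed,
           config_hash = digest::digest(config),
           package_version = as.character(utils::packageVersion("alphacog"))
         )),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d segments, %d subjects retained (%d excluded)\n",
              nrow(x$segments), length(x$retained_subjects),
              if (is.null(x$exclusions)) 0L else nrow(x$exclusions)))
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}

#' Per-phase grand-mean iAPF of a study report
#'
#' @param report a [run_pipeline()] result.
#' @return data.frame with `cap_type`, `segment`, `mean_iapf`, `sd_iapf`,
#'   `n` over the retained subjects and analyzed phases.
#' @export
phase_grand_means <- function(report) {
  long <- report$iapf_long
  sp <- split(long$iapf, list(long$cap, long$phase), drop = TRUE)
  out <- data.frame(
    key = names(sp),
    mean_iapf = vapply(sp, mean, 0, na.rm = TRUE),
    sd_iapf = vapply(sp, stats::sd, 0, na.rm = TRUE),
    n = vapply(sp, function(v) sum(!is.na(v)), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  parts <- strsplit(out$key, ".", fixed = TRUE)
  out$cap_type <- vapply(parts, `[[`, "", 1)
  out$segment <- vapply(parts, `[[`, "", 2)
  out[, c("cap_type", "segment", "mean_iapf", "sd_iapf", "n")]
}

#' Export a study report
#'
#' Writes the segment table and iAPF long table as tab-separated text and
#' the full report (including the ANOVA) as JSON.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$segments, file.path(dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$iapf_long, file.path(dir, "iapf_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- report
  out$iapf_table <- if (!is.null(report$iapf_table)) {
    as.data.frame(unclass(report$iapf_table))
  }
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
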