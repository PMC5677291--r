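#' Build the epoch-by-feature table for a cohort
#'
#' Runs the full feature-extraction pipeline on one or more subject
#' recordings: the PPG channel is band-pass filtered (0.5--4 Hz) per
#' session and, after discarding the leading 35 s, cut into 6-s epochs;
#' pulse peaks are detected per epoch and the 15 HRV features computed
#' from the NN intervals. The EDA channel is decomposed once per session
#' (the deconvolution needs more context than a single epoch) and the 6
#' skin-conductance features are read per epoch from the decomposition;
#' the 3 SKT features are computed per epoch from the raw temperature.
#' A 240-s session yields 34 epochs, hence 170 rows per subject.
#'
#' Epochs on which a feature is undefined (too few NN intervals for the
#' spectral or nonlinear measures) carry `NA` markers that are imputed
#' with the subject-session median of that feature (falling back to the
#' subject median), keeping the classifier input rectangular; the number
#' of imputed cells is recorded in `attr(, "n_imputed")`.
#'
#' @param recordings A `subject_recording` or list of them (see
#'   [generate_subject()], [read_recording()]).
#' @param discard_lead,epoch_duration Epoching parameters in seconds.
#' @param pnn_denominator See [hrv_time_domain()].
#' @param peak_detection `"per_epoch"` (default) detects pulse peaks
#'   independently in each epoch; `"per_session"` detects once on the
#'   whole filtered session and assigns NN intervals to epochs by the
#'   time of the closing peak.
#' @param verbose Print per-subject progress.
#'
#' @return A data.frame with columns `subject`, `session` (factor in
#'   protocol order), `epoch`, and the 24 feature columns of
#'   [feature_names()].
#' @export
build_feature_table <- function(recordings, discard_lead = 35,
                                epoch_duration = 6,
                                pnn_denominator = "intervals",
                                peak_detection = c("per_epoch",
                                                   "per_session"),
                                verbose = FALSE) {
  peak_detection <- match.arg(peak_detection)
  if (inherits(recordings, "subject_recording"))
    recordings <- list(recordings)
  rows <- list()
  n_imputed <- 0L
  for (rec in recordings) {
    if (verbose) message("extracting features: ", rec$subject_id)
    for (lab in names(rec$sessions)) {
      chans <- rec$sessions[[lab]]
      ppg_f <- bandpass_ppg(chans$ppg)
      eps <- segment_epochs(ppg_f, discard_lead, epoch_duration)
      dec <- decompose_sc(chans$eda)
      session_peaks <- if (peak_detection == "per_session")
        tryCatch(detect_peaks(ppg_f), stresskelm_insufficient_peaks =
                   function(e) numeric(0)) else NULL
      for (i in seq_along(eps$epochs)) {
        t0 <- eps$t_start[i]
        t1 <- eps$t_end[i]
        hrv <- epoch_hrv(eps$epochs[[i]], session_peaks, t0, t1,
                         pnn_denominator)
        eda <- eda_features(ts_window(chans$eda, t0, t1), dec)
        skt <- skt_features(ts_window(chans$skt, t0, t1))
        rows[[length(rows) + 1L]] <- c(
          list(subject = rec$subject_id, session = lab, epoch = i),
          hrv, eda, skt)
      }
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tab$session <- factor(tab$session, levels = session_levels())
  # impute missing-feature markers with subject-session medians
  for (col in feature_names("IT")) {
    miss <- is.na(tab[[col]])
    if (!any(miss)) next
    n_imputed <- n_imputed + sum(miss)
    med_ss <- stats::ave(tab[[col]], tab$subject, tab$session,
                         FUN = function(v) stats::median(v, na.rm = TRUE))
    med_s <- stats::ave(tab[[col]], tab$subject,
                        FUN = function(v) stats::median(v, na.rm = TRUE))
    fill <- ifelse(is.na(med_ss), med_s, med_ss)
    fill[is.na(fill)] <- 0
    tab[[col]][miss] <- fill[miss]
  }
  attr(tab, "n_imputed") <- n_imputed
  tab
}

# HRV features for one epoch, from per-epoch or per-session peaks.
epoch_hrv <- function(epoch_ts, session_peaks, t0, t1, pnn_denominator) {
  nn <- tryCatch({
    peaks <- if (is.null(session_peaks)) detect_peaks(epoch_ts)
    else session_peaks[session_peaks >= t0 & session_peaks < t1]
    compute_nn(peaks)
  }, error = function(e) NULL)
  if (is.null(nn)) {
    out <- as.list(rep(NA_real_, 15))
    names(out) <- feature_names("HRV")
    return(out)
  }
  hrv_features(nn, pnn_denominator = pnn_denominator)
}

#' Select a feature-set slice of the feature table
#'
#' The classifier is evaluated under four conditions: the 15 HRV
#' features, the 6 skin-conductance (SC) features, the 3 SKT features,
#' or the integrated 24-feature panel (IT).
#'
#' @param table A feature table from [build_feature_table()].
#' @param set One of `"HRV"`, `"SC"`, `"SKT"`, `"IT"`.
#' @return The table restricted to the id columns plus the selected
#'   feature columns.
#' @export
feature_set_slice <- function(table, set = c("IT", "HRV", "SC", "SKT")) {
  set <- match.arg(set)
  cols <- feature_names(set)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("feature table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  table[, c("subject", "session", "epoch", cols)]
}

#' Write / read a feature table as CSV
#'
#' @param table Feature table.
#' @param path CSV path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the table with `session` releveled in
#'   protocol order.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$session <- factor(tab$session, levels = session_levels())
  tab
}
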