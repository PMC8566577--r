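#' Multichannel EEG recording
#'
#' Container for one subject's continuous EEG: a channels-by-samples numeric
#' matrix in microvolts, the sampling rate in Hz, and ordered 10/20 channel
#' labels.
#'
#' @param data Numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique channel names, one per row
#'   of `data`.
#' @param subject_id Subject identifier.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(8 * 512), 8), fs = 512,
#'                  channel_labels = montage_8ch())
#' @export
recording <- function(data, fs, channel_labels, subject_id = "s01") {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_value("`data` must be a numeric matrix [n_channels x n_samples]")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort_value("`fs` must be a positive scalar (Hz)")
  }
  if (nrow(data) != length(channel_labels)) {
    abort_format(sprintf(
      "channel count mismatch: %d data rows but %d labels",
      nrow(data), length(channel_labels)
    ))
  }
  if (anyDuplicated(channel_labels)) {
    abort_format(sprintf(
      "duplicate channel labels: %s",
      paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", ")
    ))
  }
  if (!all(is.finite(data))) abort_format("non-finite samples in recording")
  rownames(data) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id), data = data, fs = fs,
         channel_labels = as.character(channel_labels)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' The 8-channel dry-electrode montage
#'
#' Channel labels of the frontal/central/occipital montage the pipeline was
#' designed around: three symmetric pairs plus two midline sites.
#' @return Character vector of 8 labels.
#' @export
montage_8ch <- function() c("Fp1", "Fp2", "Fz", "Cz", "C3", "C4", "O1", "O2")

#' Read an EEG recording from disk
#'
#' Reads EDF (16-bit European Data Format) or CSV (one column per channel,
#' header row of labels, YAML sidecar `<stem>.yaml` carrying `fs` and
#' `subject_id`).
#'
#' @param path File path (`.edf` or `.csv`).
#' @param format `"auto"` (from extension), `"edf"` or `"csv"`.
#' @param expected_channels Optional character vector; if given, a format
#'   error naming the missing labels is raised when any are absent.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           expected_channels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      edf = "edf", csv = "csv",
      abort_format(sprintf("cannot infer format from extension of %s", path))
    )
  }
  rec <- if (format == "edf") read_edf(path) else read_csv_recording(path)
  if (!is.null(expected_channels)) {
    missing <- setdiff(expected_channels, rec$channel_labels)
    if (length(missing)) {
      abort_format(sprintf(
        "missing expected channel(s): %s", paste(missing, collapse = ", ")
      ))
    }
  }
  rec
}

#' Write an EEG recording to disk
#'
#' @param rec An [recording()] object.
#' @param path Output path; extension selects the format unless `format` is
#'   given. CSV output writes a YAML sidecar next to the file.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      edf = "edf", csv = "csv",
      abort_format(sprintf("cannot infer format from extension of %s", path))
    )
  }
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channel_labels
    utils::write.csv(df, path, row.names = FALSE)
    sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
    yaml::write_yaml(list(fs = rec$fs, subject_id = rec$subject_id), sidecar)
  }
  invisible(path)
}

read_csv_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df))) {
    abort_format("duplicate channel labels in CSV header")
  }
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  if (!file.exists(sidecar)) sidecar <- paste0(tools::file_path_sans_ext(path), ".yml")
  if (!file.exists(sidecar)) {
    abort_io(sprintf("missing metadata sidecar for %s (expected .yaml)", path))
  }
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$fs)) abort_format("sidecar metadata lacks `fs`")
  recording(t(as.matrix(df)), fs = meta$fs, channel_labels = names(df),
            subject_id = meta$subject_id %||% "unknown")
}
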