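#' Build and validate a trial table
#'
#' A trial table describes stimulus presentations within a recording: one row
#' per trial with its 0-based onset sample, duration in samples, valence
#' label and stimulus id. Intervals are half-open `[onset, onset + duration)`.
#'
#' @param trial_id Integer trial identifiers, unique within a subject.
#' @param onset_sample 0-based onset sample of the labeled (image-projection)
#'   segment.
#' @param duration_samples Segment length in samples.
#' @param label Class labels, exactly two levels (`"negative"`, `"positive"`).
#' @param stimulus_id Stimulus identifiers.
#' @return A tibble with class-checked columns.
#' @export
trial_table <- function(trial_id, onset_sample, duration_samples, label,
                        stimulus_id = as.character(trial_id)) {
  tbl <- tibble::tibble(
    trial_id = as.integer(trial_id),
    onset_sample = as.integer(onset_sample),
    duration_samples = as.integer(duration_samples),
    label = as.character(label),
    stimulus_id = as.character(stimulus_id)
  )
  validate_trial_table(tbl)
  tbl
}

validate_trial_table <- function(tbl, n_samples = NULL) {
  if (anyDuplicated(tbl$trial_id)) abort_value("duplicate trial_id")
  if (any(tbl$onset_sample < 0L) || any(tbl$duration_samples <= 0L)) {
    abort_value("trial intervals must have onset >= 0 and duration > 0")
  }
  if (!is.null(n_samples) &&
      any(tbl$onset_sample + tbl$duration_samples > n_samples)) {
    abort_value("trial interval extends beyond recording bounds")
  }
  classes <- sort(unique(tbl$label))
  if (length(classes) != 2L) {
    abort_value(sprintf("expected exactly two classes, got: %s",
                        paste(classes, collapse = ", ")))
  }
  invisible(tbl)
}

#' Set of fixed-length epochs
#'
#' The unit of all downstream bookkeeping: a tensor of epochs with aligned
#' labels, trial ids and subject ids. Every epoch of a trial carries that
#' trial's label; epochs never straddle trials.
#'
#' @param epochs Numeric array `[n_epochs x n_channels x n_samples]`.
#' @param labels Per-epoch class labels.
#' @param trial_ids Per-epoch integer trial ids.
#' @param subject_ids Per-epoch subject ids.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Channel names.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, trial_ids, subject_ids, fs,
                      channel_labels) {
  if (length(dim(epochs)) != 3L) {
    abort_value("`epochs` must be a 3-d array [epochs x channels x samples]")
  }
  n <- dim(epochs)[1]
  if (length(labels) != n || length(trial_ids) != n || length(subject_ids) != n) {
    abort_value("labels/trial_ids/subject_ids must match epoch count")
  }
  if (dim(epochs)[2] != length(channel_labels)) {
    abort_value("channel_labels must match the channel dimension")
  }
  structure(
    list(epochs = epochs, labels = as.character(labels),
         trial_ids = as.integer(trial_ids),
         subject_ids = as.character(subject_ids),
         fs = fs, channel_labels = as.character(channel_labels)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs
  ))
  cat(sprintf("subjects: %d | trials: %d | classes: %s\n",
              length(unique(x$subject_ids)),
              length(unique(paste(x$subject_ids, x$trial_ids))),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

n_epochs <- function(x) dim(x$epochs)[1]

#' Subset an epoch set by epoch index
#' @param x An `epoch_set`.
#' @param idx Integer or logical index over epochs.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(x, idx) {
  epoch_set(x$epochs[idx, , , drop = FALSE], x$labels[idx], x$trial_ids[idx],
            x$subject_ids[idx], x$fs, x$channel_labels)
}

#' Concatenate epoch sets (e.g. across subjects)
#' @param sets A list of `epoch_set` objects sharing fs and montage.
#' @return One combined `epoch_set`.
#' @export
bind_epochs <- function(sets) {
  stopifnot(length(sets) >= 1L)
  fs <- sets[[1]]$fs
  ch <- sets[[1]]$channel_labels
  for (s in sets) {
    if (!identical(s$fs, fs) || !identical(s$channel_labels, ch)) {
      abort_value("epoch sets differ in fs or montage")
    }
  }
  d <- dim(sets[[1]]$epochs)
  n <- sum(vapply(sets, n_epochs, 0L))
  arr <- array(0, dim = c(n, d[2], d[3]))
  at <- 1L
  for (s in sets) {
    k <- n_epochs(s)
    arr[at:(at + k - 1L), , ] <- s$epochs
    at <- at + k
  }
  epoch_set(arr,
            unlist(lapply(sets, `[[`, "labels")),
            unlist(lapply(sets, `[[`, "trial_ids")),
            unlist(lapply(sets, `[[`, "subject_ids")),
            fs, ch)
}

#' Cut a recording into overlapping fixed-length epochs
#'
#' Each trial's labeled segment is divided into windows of `window_s` seconds
#' starting at multiples of `window_s - overlap_s` from the trial onset; only
#' complete windows are kept and every epoch inherits the trial's label and
#' id. With the protocol defaults (5-s trials, 2-s windows, 1-s overlap) each
#' trial yields 4 epochs of 1024 samples at 512 Hz.
#'
#' @param rec An [recording()].
#' @param trials A [trial_table()] for that recording.
#' @param window_s Window length, seconds.
#' @param overlap_s Overlap between consecutive windows, seconds
#'   (`0 <= overlap_s < window_s`).
#' @return An [epoch_set()].
#' @export
segment_epochs <- function(rec, trials, window_s = 2, overlap_s = 1) {
  if (overlap_s < 0 || overlap_s >= window_s) {
    abort_value("`overlap_s` must satisfy 0 <= overlap_s < window_s")
  }
  validate_trial_table(trials, n_samples = ncol(rec$data))
  win <- as.integer(round(window_s * rec$fs))
  step <- as.integer(round((window_s - overlap_s) * rec$fs))
  if (any(trials$duration_samples < win)) {
    abort_value(sprintf(
      "window (%g s) longer than trial(s): %s", window_s,
      paste(trials$trial_id[trials$duration_samples < win], collapse = ", ")
    ))
  }
  n_per_trial <- (trials$duration_samples - win) %/% step + 1L
  n_total <- sum(n_per_trial)
  n_ch <- nrow(rec$data)
  arr <- array(0, dim = c(n_total, n_ch, win))
  labels <- character(n_total)
  trial_ids <- integer(n_total)
  at <- 1L
  for (i in seq_len(nrow(trials))) {
    for (j in seq_len(n_per_trial[i])) {
      s0 <- trials$onset_sample[i] + (j - 1L) * step # 0-based
      arr[at, , ] <- rec$data[, (s0 + 1L):(s0 + win)]
      labels[at] <- trials$label[i]
      trial_ids[at] <- trials$trial_id[i]
      at <- at + 1L
    }
  }
  epoch_set(arr, labels, trial_ids, rep(rec$subject_id, n_total), rec$fs,
            rec$channel_labels)
}

#' Balance a trial table after artifact rejection
#'
#' Removes all corrupted trials and, for each removal, one seeded-random
#' trial of the opposite class so the class counts stay equal. When no trial
#' is corrupted, one seeded-random trial per class is removed instead, so
#' that every subject contributes the same amount of data (13 + 13 trials
#' become 12 + 12 under the acquisition protocol).
#'
#' @param trials A [trial_table()].
#' @param corrupted_ids Trial ids marked as artifact-corrupted.
#' @param seed Integer seed for the random removals.
#' @param target_per_class Optional explicit per-class trial count; defaults
#'   to the rule above.
#' @return The balanced trial table (a tibble).
#' @export
balance_trials <- function(trials, corrupted_ids = integer(), seed = 1L,
                           target_per_class = NULL) {
  validate_trial_table(trials)
  corrupted_ids <- intersect(corrupted_ids, trials$trial_id)
  kept <- trials[!trials$trial_id %in% corrupted_ids, , drop = FALSE]
  counts <- table(factor(kept$label, levels = sort(unique(trials$label))))
  if (is.null(target_per_class)) {
    target_per_class <- min(counts) - (length(corrupted_ids) == 0L)
  }
  if (target_per_class < 1L) abort_value("no trials left after balancing")
  if (any(counts < target_per_class)) {
    abort_value(sprintf(
      "cannot balance: class counts after corruption removal are (%s), target %d",
      paste(counts, collapse = ", "), target_per_class
    ))
  }
  with_seed(seed, {
    keep_ids <- unlist(lapply(names(counts), function(cl) {
      ids <- kept$trial_id[kept$label == cl]
      if (length(ids) > target_per_class) {
        drop <- sample(ids, length(ids) - target_per_class)
        ids <- setdiff(ids, drop)
      }
      ids
    }))
  })
  out <- kept[kept$trial_id %in% keep_ids, , drop = FALSE]
  tibble::as_tibble(out)
}
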