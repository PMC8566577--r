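#' Band-pass filter specification
#'
#' Describes an IIR band-pass design. `order` is the per-pass design order;
#' zero-phase application runs the filter forward and backward, squaring the
#' magnitude response (effective order doubled) and cancelling phase.
#'
#' @param family `"butterworth"` or `"chebyshev2"`.
#' @param order Design order per pass.
#' @param band Numeric `(low, high)` passband edges in Hz.
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @param stopband_atten_db Stopband attenuation in dB (Chebyshev II only).
#' @param stopband_margin_hz Distance of the Chebyshev II stopband edges from
#'   the passband edges, Hz.
#' @param design `"bandpass"` (default) or `"lowpass"`; the lowpass form
#'   realizes only the upper edge (used for the lowest filter-bank band,
#'   whose lower edge is set by the broadband preprocessing).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(family = c("butterworth", "chebyshev2"), order = 4L,
                        band, zero_phase = TRUE, stopband_atten_db = 30,
                        stopband_margin_hz = 1,
                        design = c("bandpass", "lowpass")) {
  family <- match.arg(family)
  design <- match.arg(design)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    abort_value("`band` must be (low, high) with 0 < low < high")
  }
  if (order < 1L) abort_value("`order` must be >= 1")
  structure(list(family = family, order = as.integer(order),
                 band = as.numeric(band), zero_phase = isTRUE(zero_phase),
                 stopband_atten_db = stopband_atten_db,
                 stopband_margin_hz = stopband_margin_hz, design = design),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
broadband_spec <- function() filter_spec("butterworth", 4L, c(0.5, 48.5))

#' @rdname filter_spec
#' @export
alpha_spec <- function() filter_spec("butterworth", 4L, c(8, 13))

design_coefs <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$band[2] >= nyq) {
    abort_value(sprintf("band edge %g Hz >= Nyquist (%g Hz)", spec$band[2], nyq))
  }
  if (spec$family == "butterworth") {
    flt <- signal::butter(spec$order, spec$band / nyq, type = "pass")
  } else if ((spec$design %||% "bandpass") == "lowpass") {
    edge <- min(spec$band[2] + 2 * spec$stopband_margin_hz, nyq - 0.1)
    flt <- signal::cheby2(spec$order, spec$stopband_atten_db, edge / nyq,
                          type = "low")
  } else {
    lo <- max(spec$band[1] - spec$stopband_margin_hz, 0.1)
    hi <- min(spec$band[2] + spec$stopband_margin_hz, nyq - 0.1)
    flt <- signal::cheby2(spec$order, spec$stopband_atten_db, c(lo, hi) / nyq,
                          type = "pass")
  }
  coefs <- list(b = as.numeric(flt$b), a = as.numeric(flt$a))
  if (max(Mod(polyroot(rev(coefs$a)))) >= 1) {
    abort_value(sprintf(
      "unstable IIR design for band %g-%g Hz at fs %g", spec$band[1],
      spec$band[2], fs
    ))
  }
  coefs
}

# Zero-phase IIR filtering of each column of X: odd-symmetric edge extension
# of length 3*(max polynomial length), forward pass, backward pass, trim.
zero_phase_cols <- function(coefs, X) {
  n <- nrow(X)
  pad <- 3L * max(length(coefs$a), length(coefs$b))
  if (n <= pad) {
    abort_value(sprintf(
      "signal too short for stable zero-phase filtering (%d samples <= %d pad)",
      n, pad
    ))
  }
  head_ext <- 2 * matrix(X[1, ], pad, ncol(X), byrow = TRUE) -
    X[(pad + 1L):2L, , drop = FALSE]
  tail_ext <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[(n - 1L):(n - pad), , drop = FALSE]
  Xe <- rbind(head_ext, X, tail_ext)
  Y <- iir_filter_cols(coefs$b, coefs$a, Xe)
  Y <- iir_filter_cols(coefs$b, coefs$a, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(pad + 1L):(pad + n), , drop = FALSE]
}

single_pass_cols <- function(coefs, X) {
  iir_filter_cols(coefs$b, coefs$a, X)
}

#' Apply a band-pass filter
#'
#' Zero-phase (forward-backward) application of `spec` to a recording or to
#' every epoch of an epoch set. Output has the same shape as the input; an
#' in-band sinusoid passes with gain ~1 and no lag.
#'
#' @param x An [recording()] or [epoch_set()].
#' @param spec A [filter_spec()].
#' @return Same class as `x`.
#' @export
bandpass <- function(x, spec) UseMethod("bandpass")

#' @export
bandpass.eeg_recording <- function(x, spec) {
  coefs <- design_coefs(spec, x$fs)
  fn <- if (spec$zero_phase) zero_phase_cols else single_pass_cols
  x$data <- t(fn(coefs, t(x$data)))
  rownames(x$data) <- x$channel_labels
  x
}

#' @export
bandpass.epoch_set <- function(x, spec) {
  coefs <- design_coefs(spec, x$fs)
  fn <- if (spec$zero_phase) zero_phase_cols else single_pass_cols
  d <- dim(x$epochs)
  # samples x (epochs*channels): each epoch-channel trace filtered separately
  M <- matrix(aperm(x$epochs, c(3, 1, 2)), nrow = d[3])
  M <- fn(coefs, M)
  x$epochs <- aperm(array(M, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  x
}

#' Pluggable trial-level artifact-rejection stage
#'
#' Artifact screening (performed with ICA in an external toolbox in the
#' original protocol) is exposed as a hook: `reject_fn` receives the epoch
#' set and returns the trial ids of whole trials to discard. Rejected trials
#' are removed together with one seeded-random trial of the opposite class
#' each, keeping the classes balanced. The default hook is the identity.
#'
#' @param epochs An [epoch_set()] for a single subject.
#' @param reject_fn `NULL` (identity) or `function(epoch_set) -> trial ids`.
#' @param seed Seed for the balancing removals.
#' @return The (possibly re-balanced) `epoch_set`.
#' @export
artifact_hook <- function(epochs, reject_fn = NULL, seed = 1L) {
  if (is.null(reject_fn)) return(epochs)
  bad <- as.integer(reject_fn(epochs))
  if (length(bad) == 0L) return(epochs)
  meta <- tibble::tibble(trial_id = epochs$trial_ids, label = epochs$labels)
  meta <- meta[!duplicated(meta$trial_id), ]
  tbl <- trial_table(meta$trial_id, 0L, 1L, meta$label)
  balanced <- balance_trials(tbl, corrupted_ids = bad, seed = seed)
  subset_epochs(epochs, epochs$trial_ids %in% balanced$trial_id)
}
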