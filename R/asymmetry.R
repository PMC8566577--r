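#' Hemispheric pair-difference features
#'
#' Prior-knowledge features from the valence/right-hemisphere asymmetry
#' theories: per-sample differences of symmetric channel pairs, right minus
#' left. `frontal_pair` uses Fp2 - Fp1 only; `three_pairs` adds C4 - C3 and
#' O2 - O1 (the only symmetric pairs of the 8-channel montage; Fz and Cz are
#' midline).
#'
#' @param epochs An [epoch_set()].
#' @param mode `"frontal_pair"` or `"three_pairs"`.
#' @return An `asymmetry_features` object: tensor
#'   `[n_epochs x n_pairs x n_samples]` plus the epoch bookkeeping.
#' @export
pair_differences <- function(epochs, mode = c("frontal_pair", "three_pairs")) {
  mode <- match.arg(mode)
  pairs <- list(c("Fp1", "Fp2"))
  if (mode == "three_pairs") {
    pairs <- c(pairs, list(c("C3", "C4"), c("O1", "O2")))
  }
  needed <- unlist(pairs)
  missing <- setdiff(needed, epochs$channel_labels)
  if (length(missing)) {
    abort_value(sprintf("missing channel(s): %s", paste(missing, collapse = ", ")))
  }
  d <- dim(epochs$epochs)
  vals <- array(0, dim = c(d[1], length(pairs), d[3]))
  for (p in seq_along(pairs)) {
    li <- match(pairs[[p]][1], epochs$channel_labels)
    ri <- match(pairs[[p]][2], epochs$channel_labels)
    vals[, p, ] <- epochs$epochs[, ri, ] - epochs$epochs[, li, ]
  }
  structure(
    list(mode = mode, values = vals,
         pair_names = vapply(pairs, function(p) paste0(p[2], "-", p[1]), ""),
         labels = epochs$labels, trial_ids = epochs$trial_ids,
         subject_ids = epochs$subject_ids, fs = epochs$fs),
    class = "asymmetry_features"
  )
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: Hann-windowed segments of
#' `segment_s` seconds with fractional overlap `overlap`, one-sided density
#' scaling (power integrates to the signal variance).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param segment_s Segment length in seconds.
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return A list with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, segment_s = 1, overlap = 0.5) {
  L <- as.integer(round(segment_s * fs))
  if (L > length(x)) abort_value("signal shorter than one Welch segment")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1)) # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- L %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nfreq])^2 * scale
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[nfreq] <- 1
  list(freq = seq(0, nfreq - 1) * fs / L, psd = psd * dbl)
}

band_power <- function(psd, band) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$psd[sel]) * df
}

#' Frontal alpha-asymmetry index
#'
#' Per epoch, the natural log of the left-hemisphere alpha power minus the
#' log of the right-hemisphere alpha power,
#' `index = ln(alpha_psd_left) - ln(alpha_psd_right)`, with alpha power
#' integrated over `band` from a Welch PSD. Swapping the channels negates the
#' index; a common amplitude rescaling of both channels leaves it unchanged.
#'
#' @param epochs An [epoch_set()].
#' @param left_ch,right_ch Channel labels of the homologous pair.
#' @param band Integration band, Hz (default alpha, 8-13 Hz).
#' @param segment_s,overlap Welch settings (see [welch_psd()]).
#' @return A tibble with one row per epoch: `alpha_psd_left`,
#'   `alpha_psd_right` (uV^2), `index`, plus epoch bookkeeping columns.
#' @export
alpha_asymmetry <- function(epochs, left_ch = "Fp1", right_ch = "Fp2",
                            band = c(8, 13), segment_s = 1, overlap = 0.5) {
  for (ch in c(left_ch, right_ch)) {
    if (!ch %in% epochs$channel_labels) {
      abort_value(sprintf("missing channel(s): %s", ch))
    }
  }
  li <- match(left_ch, epochs$channel_labels)
  ri <- match(right_ch, epochs$channel_labels)
  n <- n_epochs(epochs)
  pl <- pr <- numeric(n)
  for (i in seq_len(n)) {
    pl[i] <- band_power(welch_psd(epochs$epochs[i, li, ], epochs$fs,
                                  segment_s, overlap), band)
    pr[i] <- band_power(welch_psd(epochs$epochs[i, ri, ], epochs$fs,
                                  segment_s, overlap), band)
  }
  if (any(pl <= 0) || any(pr <= 0) || any(!is.finite(c(pl, pr)))) {
    abort_value("non-positive alpha power: log-ratio index undefined")
  }
  tibble::tibble(
    subject_id = epochs$subject_ids, trial_id = epochs$trial_ids,
    label = epochs$labels,
    alpha_psd_left = pl, alpha_psd_right = pr,
    index = log(pl) - log(pr)
  )
}
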