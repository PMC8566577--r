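# Shared fixtures, all built in code.

fs_test <- 512

# sinusoidal recording: one row per channel, amplitudes in microvolts
sine_recording <- function(freqs, amps, secs = 4, fs = fs_test,
                           labels = NULL, subject_id = "s01") {
  t <- seq(0, secs - 1 / fs, by = 1 / fs)
  data <- t(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  if (is.null(labels)) labels <- paste0("ch", seq_along(freqs))
  recording(data, fs, labels, subject_id)
}

# iid-noise epoch set with grouped trials (4 epochs per trial)
noise_epochs <- function(n_trials = 24, n_ch = 8, n_samp = 1024, fs = fs_test,
                         seed = 1, labels = NULL, epochs_per_trial = 4) {
  set.seed(seed)
  n <- n_trials * epochs_per_trial
  if (is.null(labels)) {
    labels <- rep(rep(c("negative", "positive"), length.out = n_trials),
                  each = epochs_per_trial)
  }
  epoch_set(array(stats::rnorm(n * n_ch * n_samp), c(n, n_ch, n_samp)),
            labels, rep(seq_len(n_trials), each = epochs_per_trial),
            rep("s01", n), fs, montage_8ch()[seq_len(n_ch)])
}

# a balanced 26-trial table laid out sequentially (5-s trials, 1-s gaps)
protocol_trials <- function(n_per_class = 13, fs = fs_test, trial_s = 5,
                            gap_s = 1) {
  n <- 2 * n_per_class
  trial_table(
    trial_id = seq_len(n),
    onset_sample = as.integer(gap_s * fs + (seq_len(n) - 1) *
                                (trial_s + gap_s) * fs),
    duration_samples = as.integer(trial_s * fs),
    label = rep(c("negative", "positive"), n_per_class)
  )
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
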