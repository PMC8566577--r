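test_that("generation is seed-deterministic and structurally faithful", {
  cfg <- synth_config(n_subjects = 2, n_corrupted_subjects = 1, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)

  # subject subsetting regenerates identical per-subject streams
  d_sub <- generate_dataset(cfg, subjects = 2)
  expect_identical(d_sub$recordings[[1]], d1$recordings[[2]])

  # 26 trials per subject, balanced 13/13, stimulus scores in the intervals
  tr1 <- d1$trials[d1$trials$subject_id == "s01", ]
  expect_equal(nrow(tr1), 26L)
  expect_equal(as.vector(table(tr1$label)), c(13L, 13L))
  sel <- d1$stimuli[d1$stimuli$class != "excluded", ]
  expect_equal(nrow(sel), 26L)

  # exactly one corrupted trial for the configured subject
  expect_equal(nrow(d1$ground_truth$corrupted), 1L)
  expect_equal(d1$ground_truth$corrupted$subject_id, "s01")

  # SAM ratings stay on the 1-5 scale and track polarity
  expect_true(all(d1$sam$rating %in% 1:5))
  by_class <- merge(d1$sam, sel[, c("stimulus_id", "class")])
  expect_gt(mean(by_class$rating[by_class$class == "positive"]),
            mean(by_class$rating[by_class$class == "negative"]))
})

test_that("epoched synthetic data has the protocol tensor shape", {
  cfg <- synth_config(n_subjects = 1, n_corrupted_subjects = 1, seed = 3)
  ep <- dataset_epochs(cfg)
  expect_equal(dim(ep$epochs), c(96, 8, 1024))
  expect_equal(as.vector(table(ep$labels)), c(48L, 48L))
  expect_equal(length(unique(ep$trial_ids)), 24L)

  # config route and materialized-dataset route agree
  ds <- generate_dataset(cfg)
  ep2 <- dataset_epochs(ds)
  expect_equal(ep$epochs, ep2$epochs, tolerance = 1e-12)
})

test_that("a planted covariance shift is recovered in band and pattern", {
  cfg <- synth_config(n_subjects = 1, n_corrupted_subjects = 0,
                      effects = list(effect_covariance_shift()), seed = 5)
  ep <- dataset_epochs(cfg)
  bank <- design_filter_bank(ep$fs)
  mod <- fit_csp(fbcsp:::epoch_covariances(ep, bank))
  gt <- generate_dataset(cfg, subjects = 1)$ground_truth
  rec <- ground_truth_recovery_report(gt, mod)
  expect_true(rec$band_correct)
  expect_equal(rec$true_band, 3L) # 8.5-12.5 Hz
  expect_gt(rec$pattern_cosine, 0.95)
  expect_gt(rec$top_eigenvalue, 0.7)
  expect_lt(rec$top_eigenvalue, 0.9)
})

test_that("two effects in different bands are recovered independently", {
  cfg <- synth_config(
    n_subjects = 1, n_corrupted_subjects = 0, seed = 8,
    effects = list(
      effect_covariance_shift(band = c(8.5, 12.5), variance_ratio = 4),
      effect_covariance_shift(band = c(20.5, 24.5), variance_ratio = 0.25,
                              source_sd = 12)
    )
  )
  ep <- dataset_epochs(cfg)
  mod <- fit_csp(fbcsp:::epoch_covariances(ep, design_filter_bank(ep$fs)))
  rec <- ground_truth_recovery_report(generate_dataset(cfg, 1)$ground_truth,
                                      mod)
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$band_correct))
  expect_equal(sort(rec$true_band), c(3L, 6L))
  expect_true(all(rec$pattern_cosine > 0.9))
})

test_that("the frontal asymmetry effect shifts the index by about -2 log(gain)", {
  g <- 1.5
  cfg <- synth_config(n_subjects = 1, n_corrupted_subjects = 0, seed = 13,
                      effects = list(effect_frontal_asymmetry(right_gain = g)))
  ep <- dataset_epochs(cfg)
  aa <- alpha_asymmetry(ep)
  d <- mean(aa$index[aa$label == "negative"]) -
    mean(aa$index[aa$label == "positive"])
  expect_lt(d, 0) # right-hemisphere dominance under negative valence
  expect_lt(abs(d + 2 * log(g)), 0.25) # one-subject check; tighter in bulk
})

test_that("null configurations carry no class information in the covariances", {
  cfg <- synth_config(n_subjects = 1, n_corrupted_subjects = 0,
                      effects = list(), seed = 17)
  ep <- dataset_epochs(cfg)
  mod <- fit_csp(ep) # broadband CSP on null data
  # eigenvalues hover around 1/2 (no planted structure)
  expect_lt(max(abs(mod$bands[[1]]$eigenvalues - 0.5)), 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_subjects = 0), class = "fbcsp_value_error")
  expect_error(synth_config(effects = list(effect_covariance_shift(band = c(8, 300)))),
               class = "fbcsp_value_error")
  expect_error(effect_covariance_shift(variance_ratio = 1),
               class = "fbcsp_value_error")
  expect_error(synth_config(n_subjects = 2, n_corrupted_subjects = 3),
               class = "fbcsp_value_error")
})
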