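test_that("epoch segmentation follows the 2-s/1-s protocol arithmetic", {
  # one 5-s trial at 512 Hz, 2-s windows, 1-s overlap -> 4 epochs of 1024
  rec <- recording(matrix(rnorm(8 * 2560), 8), fs_test, montage_8ch())
  tt <- trial_table(1:2, c(0L, 0L), c(2560L, 2560L),
                    c("negative", "positive"))
  ep <- segment_epochs(rec, tt, window_s = 2, overlap_s = 1)
  expect_equal(sum(ep$trial_ids == 1L), 4L)
  expect_equal(dim(ep$epochs)[3], 1024L)

  # exact-fit window: a 2-s trial yields exactly one epoch
  rec2 <- recording(matrix(rnorm(8 * 1024), 8), fs_test, montage_8ch())
  tt2 <- trial_table(1:2, c(0L, 0L), c(1024L, 1024L),
                     c("negative", "positive"))
  expect_equal(sum(segment_epochs(rec2, tt2)$trial_ids == 1L), 1L)

  # epochs inherit trial labels and never straddle trials
  expect_true(all(tapply(ep$labels, ep$trial_ids,
                         function(l) length(unique(l))) == 1L))

  # window longer than a trial is an error
  expect_error(segment_epochs(rec2, tt2, window_s = 3),
               class = "fbcsp_value_error")
})

test_that("24 protocol trials of 5 s give 96 epochs and the count formula holds", {
  fs <- fs_test
  tt <- protocol_trials()[1:24, ]
  n_samples <- max(tt$onset_sample + tt$duration_samples) + fs
  rec <- recording(matrix(rnorm(8 * n_samples), 8), fs, montage_8ch())
  ep <- segment_epochs(rec, tt, 2, 1)
  expect_equal(dim(ep$epochs)[1], 96L)

  # floor((dur - win)/(win - ov)) + 1, over assorted geometries
  for (case in list(c(5, 2, 1), c(5, 2, 0), c(6, 3, 1.5), c(4, 1, 0.5))) {
    dur <- case[1]; win <- case[2]; ov <- case[3]
    tt1 <- trial_table(1:2, c(0L, 0L), as.integer(dur * fs),
                       c("negative", "positive"))
    rec1 <- recording(matrix(rnorm(2 * dur * fs), 2), fs, c("A", "B"))
    got <- sum(segment_epochs(rec1, tt1, win, ov)$trial_ids == 1L)
    expect_equal(got, floor((dur - win) / (win - ov)) + 1)
  }
})

test_that("EDF round-trip preserves samples to quantization, labels and fs exactly", {
  set.seed(4)
  rec <- recording(matrix(rnorm(8 * 1024, sd = 40), 8), 512, montage_8ch(),
                   subject_id = "s07")
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$fs, 512)
  expect_identical(back$subject_id, "s07")
  step <- (max(rec$data) - min(rec$data)) / 65534
  expect_lt(max(abs(back$data - rec$data)), step)
})

test_that("CSV + sidecar loads an equivalent recording and errors are typed", {
  rec <- recording(matrix(rnorm(8 * 512), 8), 512, montage_8ch(), "s01")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, csv)
  back <- read_recording(csv)
  expect_equal(back$data, rec$data, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$fs, 512)

  expect_error(read_recording(tempfile(fileext = ".edf")),
               class = "fbcsp_io_error")
  expect_error(
    read_recording(csv, expected_channels = c(montage_8ch(), "Pz")),
    regexp = "Pz", class = "fbcsp_format_error"
  )
  expect_error(recording(matrix(0, 2, 4), 512, c("A", "A")),
               class = "fbcsp_format_error")
  expect_error(recording(matrix(c(0, NA, 0, 0), 2), 512, c("A", "B")),
               class = "fbcsp_format_error")
})

test_that("trial balancing mirrors the artifact-handling protocol", {
  tt <- protocol_trials() # 13 + 13

  # one corrupted negative trial: it and one random positive are dropped
  corrupted <- tt$trial_id[tt$label == "negative"][1]
  bal <- balance_trials(tt, corrupted_ids = corrupted, seed = 9)
  expect_equal(nrow(bal), 24L)
  expect_equal(as.vector(table(bal$label)), c(12L, 12L))
  expect_false(corrupted %in% bal$trial_id)

  # no corruption: one random trial per class is dropped
  bal2 <- balance_trials(tt, seed = 9)
  expect_equal(nrow(bal2), 24L)
  expect_equal(as.vector(table(bal2$label)), c(12L, 12L))

  # determinism
  expect_identical(balance_trials(tt, corrupted, seed = 5),
                   balance_trials(tt, corrupted, seed = 5))

  # balancing property over random corruption patterns
  set.seed(31)
  for (i in 1:20) {
    corr <- sample(tt$trial_id, sample(0:4, 1))
    bal_i <- balance_trials(tt, corr, seed = i)
    counts <- table(bal_i$label)
    expect_equal(length(unique(counts)), 1L)
    expect_true(all(!corr %in% bal_i$trial_id))
    # drops exactly down to the per-class minimum left after corruption
    # (minus one per class when nothing was corrupted)
    kept_counts <- table(tt$label[!tt$trial_id %in% corr])
    target <- min(kept_counts) - (length(corr) == 0L)
    expect_equal(nrow(bal_i), 2L * target)
  }

  # impossible target is an error
  expect_error(balance_trials(tt, corrupted_ids = tt$trial_id,
                              seed = 1),
               class = "fbcsp_value_error")
  expect_error(balance_trials(tt, seed = 1, target_per_class = 20),
               class = "fbcsp_value_error")
})
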