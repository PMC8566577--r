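test_that("fold plans group trials, stratify classes and hit the protocol sizes", {
  ep <- noise_epochs(n_trials = 24)
  plan <- make_folds(ep, k = 12, mode = "within_subject", seed = 4)
  expect_equal(nrow(plan), 24L)
  # each fold: one trial per class -> 8 test epochs, 88 train epochs
  per_fold <- table(plan$fold, plan$label)
  expect_true(all(per_fold == 1L))
  f1 <- plan$trial_id[plan$fold == 1]
  expect_equal(sum(ep$trial_ids %in% f1), 8L)
  expect_equal(sum(!ep$trial_ids %in% f1), 88L)
  # no trial in two folds
  expect_equal(anyDuplicated(plan$trial_id), 0L)

  # cross-subject plan over the pooled 25 x 24 trials: 200/2200 epoch split
  pooled <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:25), each = 24),
    trial_id = rep(1:24, 25),
    label = rep(rep(c("negative", "positive"), 12), 25)
  )
  cplan <- make_folds(pooled, k = 12, mode = "cross_subject", seed = 4)
  sizes <- table(cplan$fold)
  expect_equal(as.vector(sizes), rep(50L, 12)) # x4 epochs/trial = 200 test
  expect_true(all(table(cplan$fold, cplan$label) == 25L))

  expect_error(make_folds(ep, k = 30), class = "fbcsp_value_error")
  expect_error(make_folds(ep, k = 13), class = "fbcsp_value_error")
})

test_that("cross-validation is perfect on oracle features and chance on noise", {
  # oracle: raw amplitude encodes the label
  n_trials <- 12
  labs <- rep(rep(c("negative", "positive"), 6), each = 4)
  arr <- array(rnorm(48 * 2 * 64, sd = 0.01), c(48, 2, 64))
  arr[labs == "negative", , ] <- arr[labs == "negative", , ] + 1
  ep <- epoch_set(arr, labs, rep(1:12, each = 4), rep("s01", 48), 64,
                  c("A", "B"))
  plan <- make_folds(ep, k = 6, mode = "within_subject", seed = 1)
  r <- cross_validate(ep, feature_pipeline("raw"), model_spec("knn"), plan,
                      seed = 1)
  expect_equal(r$aggregate$mean_accuracy, 1.0)
  expect_true(all(r$per_fold$accuracy == 1.0))

  # label-independent noise: accuracy within the trial-level binomial band
  set.seed(99)
  accs <- vapply(1:4, function(i) {
    epn <- noise_epochs(n_trials = 24, n_ch = 4, n_samp = 128, seed = 100 + i)
    pl <- make_folds(epn, k = 12, mode = "within_subject", seed = i)
    cross_validate(epn, feature_pipeline("raw"), model_spec("knn"), pl,
                   seed = i)$aggregate$mean_accuracy
  }, 0)
  half_width <- 1.96 * sqrt(0.25 / (4 * 24))
  expect_lt(abs(mean(accs) - 0.5), half_width + 0.02)
})

test_that("reported metrics satisfy the confusion-matrix identities", {
  truth <- c(rep("negative", 6), rep("positive", 6))
  pred <- c(rep("negative", 4), rep("positive", 2),
            rep("negative", 1), rep("positive", 5))
  m <- fbcsp:::classification_metrics(truth, pred)
  expect_equal(m$accuracy, (m$tp + m$tn) / 12)
  expect_equal(m$precision, m$tp / (m$tp + m$fp))
  expect_equal(m$recall, m$tp / (m$tp + m$fn))
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  # the class of interest is negative valence
  expect_equal(m$tp, 4L)
  expect_equal(m$fn, 2L)
})

test_that("feature stages fitted in a fold never see test labels (no leakage)", {
  ep <- noise_epochs(n_trials = 12, n_ch = 4, n_samp = 256, seed = 7)
  pipe <- feature_pipeline("fb_csp", bank = design_filter_bank(fs_test),
                           mi_k = 10)
  ctx <- fbcsp:::pipeline_prepare(pipe, ep)
  train_idx <- which(ep$trial_ids <= 10)
  fit1 <- fbcsp:::pipeline_fit(ctx, train_idx)
  # shuffle the labels of the held-out trials only
  ctx2 <- ctx
  test_pos <- which(ep$trial_ids > 10)
  ctx2$labels[test_pos] <- sample(ctx2$labels[test_pos])
  fit2 <- fbcsp:::pipeline_fit(ctx2, train_idx)
  expect_identical(rlang::hash(fit1), rlang::hash(fit2))
})

test_that("kNN distances agree with reference implementations", {
  set.seed(42)
  tr <- matrix(rnorm(40), 8)
  te <- matrix(rnorm(15), 3)
  # euclidean against dist()
  D <- fbcsp:::knn_dist_matrix(te, tr, "euclidean")
  ref <- as.matrix(dist(rbind(te, tr)))[1:3, 4:11]
  expect_equal(unname(D), unname(ref), tolerance = 1e-10)
  # cityblock / minkowski p=1 coincide
  D1 <- fbcsp:::knn_dist_matrix(te, tr, "cityblock")
  D2 <- fbcsp:::knn_dist_matrix(te, tr, "minkowski", exponent = 1)
  expect_equal(D1, D2, tolerance = 1e-10)
  # correlation distance via cor()
  Dc <- fbcsp:::knn_dist_matrix(te, tr, "correlation")
  expect_equal(Dc[2, 3], 1 - cor(te[2, ], tr[3, ]), tolerance = 1e-10)
  # spearman via cor(method = "spearman")
  Ds <- fbcsp:::knn_dist_matrix(te, tr, "spearman")
  expect_equal(Ds[1, 4], 1 - cor(te[1, ], tr[4, ], method = "spearman"),
               tolerance = 1e-10)

  # kNN euclidean k=1 prediction agrees with class::knn
  y <- rep(c("negative", "positive"), length.out = 8)
  mdl <- fbcsp:::fit_knn(tr, y, list(distance = "euclidean", weights = "equal",
                                     exponent = 2, neighbors = 1))
  ref_pred <- as.character(class::knn(tr, te, factor(y), k = 1))
  expect_equal(as.character(predict(mdl, te)), ref_pred)
})

test_that("regularized LDA matches MASS::lda at gamma = 0, delta = 0", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, 1), 20), matrix(rnorm(60, -1), 20))
  y <- rep(c("negative", "positive"), each = 20)
  fit <- fbcsp:::fit_rlda(X, y, list(gamma = 0, delta = 0,
                                     discrim_type = "linear"))
  Xte <- matrix(rnorm(30), 10)
  ref <- MASS::lda(X, grouping = factor(y))
  expect_equal(as.character(predict(fit, Xte)),
               as.character(predict(ref, Xte)$class))
})

test_that("the ANN trainer honors capacity, early stopping and determinism", {
  set.seed(5)
  # linearly separable toy data -> perfect training accuracy
  X <- rbind(matrix(rnorm(100, 2), 50), matrix(rnorm(100, -2), 50))
  y <- rep(c("negative", "positive"), each = 50)
  val <- c(1:5, 96:100)
  ann <- train_ann(X, y, hidden = 25, activation = "relu",
                   validation_idx = val, seed = 1)
  tr_rows <- setdiff(1:100, val)
  expect_equal(mean(predict(ann, X[tr_rows, ]) == y[tr_rows]), 1.0)

  # anti-learnable validation: labels inverted -> val loss worsens as the
  # net fits training, so patience triggers within ~patience epochs
  y_bad <- y; y_bad[val] <- rev(y[val])
  ann2 <- train_ann(X, y_bad, hidden = 25, activation = "relu",
                    validation_idx = val, seed = 1, patience = 10)
  expect_lt(ann2$stopped_epoch, 200)

  # bit-identical refit under the same seed
  a1 <- train_ann(X, y, hidden = 30, validation_idx = val, seed = 9)
  a2 <- train_ann(X, y, hidden = 30, validation_idx = val, seed = 9)
  expect_identical(a1$params, a2$params)

  expect_error(train_ann(X, y, validation_idx = integer()),
               class = "fbcsp_value_error")
})

test_that("grid search selects by CV accuracy with simplicity tie-breaks", {
  ep <- noise_epochs(n_trials = 8, n_ch = 2, n_samp = 64, seed = 3)
  # plant a separable amplitude difference so accuracy orders the grid
  ep$epochs[ep$labels == "negative", , ] <-
    ep$epochs[ep$labels == "negative", , ] * 3
  plan <- make_folds(ep, k = 4, mode = "within_subject", seed = 2)
  pipe <- feature_pipeline("csp")

  # one-point grid returns that point
  g1 <- tibble::tibble(neighbors = 3L)
  gs1 <- grid_search(ep, "knn", pipe, plan, grid = g1, seed = 1)
  expect_equal(gs1$best_spec$params$neighbors, 3L)

  # selection is reproducible and reports the chosen k
  g <- tibble::tibble(neighbors = c(1L, 2L, 3L))
  gs_a <- grid_search(ep, "knn", pipe, plan, grid = g, seed = 6)
  gs_b <- grid_search(ep, "knn", pipe, plan, grid = g, seed = 6)
  expect_identical(gs_a$best_spec$params, gs_b$best_spec$params)
  expect_true("mean_accuracy" %in% names(gs_a$results))
  expect_equal(nrow(gs_a$results), 3L)

  expect_error(grid_search(ep, "knn", pipe, plan,
                           grid = tibble::tibble()[0, ], seed = 1),
               class = "fbcsp_value_error")

  # Table 2 grids cover the documented ranges
  expect_setequal(unique(table2_grid("knn")$distance), fbcsp:::knn_distances())
  expect_true(all(table2_grid("ann")$hidden >= 25 &
                    table2_grid("ann")$hidden <= 200))
  expect_true(all(table2_grid("lr")$C >= 0.25 & table2_grid("lr")$C <= 1))
})
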