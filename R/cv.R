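#' Trial-grouped stratified fold assignment
#'
#' Builds a k-fold plan at the trial level so that all epochs of a trial land
#' in the same fold (train and test never share parts of a trial) and each
#' fold receives an equal share of each class (stratification). Trials are
#' shuffled with `seed` and dealt round-robin per class; when the per-class
#' trial count is not a multiple of `k` the remainder continues round-robin,
#' so fold sizes differ by at most one trial per class. In `within_subject`
#' mode the assignment is computed independently per subject; in
#' `cross_subject` mode all subjects' trials are pooled first.
#'
#' @param x An [epoch_set()], or a trial-level tibble with columns
#'   `subject_id`, `trial_id`, `label`.
#' @param k Number of folds (default 12).
#' @param mode `"within_subject"` or `"cross_subject"`.
#' @param seed Shuffle seed.
#' @return A `fold_plan`: tibble `(subject_id, trial_id, label, fold)` with
#'   attributes `k` and `mode`.
#' @export
make_folds <- function(x, k = 12L, mode = c("within_subject", "cross_subject"),
                       seed = 1L) {
  mode <- match.arg(mode)
  meta <- if (inherits(x, "epoch_set")) {
    tibble::tibble(subject_id = x$subject_ids, trial_id = x$trial_ids,
                   label = x$labels)
  } else {
    tibble::as_tibble(x)[, c("subject_id", "trial_id", "label")]
  }
  meta <- meta[!duplicated(meta[, c("subject_id", "trial_id")]), ]

  assign_one <- function(df, seed) {
    if (k > nrow(df)) {
      abort_value(sprintf("k = %d exceeds trial count %d", k, nrow(df)))
    }
    classes <- sort(unique(df$label))
    if (k > min(table(df$label))) {
      abort_value(sprintf(
        "k = %d folds cannot all contain both classes (min class count %d)",
        k, min(table(df$label))
      ))
    }
    df$fold <- NA_integer_
    with_seed(seed, {
      for (cl in classes) {
        idx <- which(df$label == cl)
        idx <- idx[sample.int(length(idx))]
        df$fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    df
  }

  out <- if (mode == "within_subject") {
    subs <- unique(meta$subject_id)
    dplyr::bind_rows(lapply(seq_along(subs), function(i) {
      assign_one(meta[meta$subject_id == subs[i], , drop = FALSE],
                 derive_seed(seed, i))
    }))
  } else {
    assign_one(meta, seed)
  }
  structure(out, k = k, mode = mode, class = c("fold_plan", class(out)))
}

# ---- Feature pipelines ---------------------------------------------------
#
# A pipeline separates a per-epoch deterministic "prepare" step (filtering,
# banking, per-epoch covariances, flattening: no fitting, hence computable
# once for all folds without leakage) from per-fold "fit" (CSP projections,
# PCA, MI ranking, standardization: training rows only) and "transform".

#' Feature-extraction pipeline definition
#'
#' @param mode One of `"raw"` (flattened broadband epochs, 8 x 1024 = 8192
#'   features), `"pca"` (raw + 95%-variance PCA), `"csp"` (broadband CSP
#'   log-variances, 8 features), `"fb_raw"` (flattened filter-bank tensor,
#'   12 x 8 x 1024 = 98304 features), `"fb_pca"`, `"fb_csp"` (12 x 8 = 96
#'   features), `"apriori_frontal"` (Fp2-Fp1 trace, 1024 features),
#'   `"apriori_three_pairs"` (three pair differences, 3072 features).
#' @param bank Filter bank for the `fb_*` modes (defaults to
#'   [design_filter_bank()] at the data's fs).
#' @param variance_kept PCA explained-variance fraction.
#' @param mi_k Optional mutual-information selection: keep the top `mi_k`
#'   features (fitted on training rows).
#' @param log_var Use log-variance CSP features (default) or raw normalized
#'   variances.
#' @param standardize z-score features with training means/sds.
#' @return An `fbcsp_pipeline` definition.
#' @export
feature_pipeline <- function(mode = c("fb_csp", "csp", "raw", "pca", "fb_raw",
                                      "fb_pca", "apriori_frontal",
                                      "apriori_three_pairs"),
                             bank = NULL, variance_kept = 0.95, mi_k = NULL,
                             log_var = TRUE, standardize = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, bank = bank, variance_kept = variance_kept,
                 mi_k = mi_k, log_var = log_var, standardize = standardize),
            class = "fbcsp_pipeline")
}

flatten_epochs <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1])
}

pipeline_prepare <- function(pipe, epochs) {
  needs_bank <- pipe$mode %in% c("fb_csp", "fb_raw", "fb_pca")
  bank <- pipe$bank
  if (needs_bank && is.null(bank)) bank <- design_filter_bank(epochs$fs)
  ctx <- list(pipe = pipe, labels = epochs$labels,
              trial_ids = epochs$trial_ids, subject_ids = epochs$subject_ids)
  if (pipe$mode %in% c("csp", "fb_csp")) {
    ctx$cov <- epoch_covariances(epochs, bank = if (needs_bank) bank else NULL)
  } else if (pipe$mode %in% c("raw", "pca")) {
    ctx$X <- flatten_epochs(epochs$epochs)
  } else if (pipe$mode %in% c("fb_raw", "fb_pca")) {
    ctx$X <- flatten_epochs(apply_filter_bank(epochs, bank)$epochs)
  } else if (pipe$mode == "apriori_frontal") {
    ctx$X <- flatten_epochs(pair_differences(epochs, "frontal_pair")$values)
  } else if (pipe$mode == "apriori_three_pairs") {
    ctx$X <- flatten_epochs(pair_differences(epochs, "three_pairs")$values)
  }
  ctx
}

pipeline_fit <- function(ctx, train_idx) {
  pipe <- ctx$pipe
  fit <- list(train_idx = train_idx)
  if (pipe$mode %in% c("csp", "fb_csp")) {
    fit$csp <- fit_csp_cov(ctx$cov, idx = train_idx)
    Xtr <- csp_features_cov(ctx$cov, fit$csp, idx = train_idx,
                            log = pipe$log_var)
  } else {
    Xtr <- ctx$X[train_idx, , drop = FALSE]
    if (pipe$mode %in% c("pca", "fb_pca")) {
      fit$pca <- fit_pca(Xtr, pipe$variance_kept)
      Xtr <- stats::predict(fit$pca, Xtr)
    }
  }
  if (!is.null(pipe$mi_k)) {
    fit$mi <- mi_rank(Xtr, ctx$labels[train_idx],
                      k = min(pipe$mi_k, ncol(Xtr)))
    Xtr <- Xtr[, as.integer(fit$mi), drop = FALSE]
  }
  if (pipe$standardize) {
    fit$center <- colMeans(Xtr)
    fit$scale <- apply(Xtr, 2, stats::sd)
    fit$scale[fit$scale < 1e-12] <- 1
  }
  fit
}

pipeline_transform <- function(ctx, fit, idx) {
  pipe <- ctx$pipe
  if (pipe$mode %in% c("csp", "fb_csp")) {
    X <- csp_features_cov(ctx$cov, fit$csp, idx = idx, log = pipe$log_var)
  } else {
    X <- ctx$X[idx, , drop = FALSE]
    if (!is.null(fit$pca)) X <- stats::predict(fit$pca, X)
  }
  if (!is.null(fit$mi)) X <- X[, as.integer(fit$mi), drop = FALSE]
  if (pipe$standardize) {
    X <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  }
  X
}

# ---- Metrics -------------------------------------------------------------

# Confusion-based metrics with the negative-valence class as the class of
# interest (precision/recall/F1 quantify the cost of missing negative states).
classification_metrics <- function(truth, pred, positive = "negative") {
  truth <- as.character(truth)
  pred <- as.character(pred)
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  tibble::tibble(accuracy = (tp + tn) / length(truth), precision = precision,
                 recall = recall, f1 = f1, n = length(truth),
                 tp = tp, tn = tn, fp = fp, fn = fn)
}

# ---- Cross-validation ----------------------------------------------------

# Pick grouped, stratified validation trials from the training trials of one
# fold (used by the ANN early stopping). Fraction defaults mirror the
# protocol: 16/88 epochs within-subject, 200/2200 cross-subject.
pick_validation <- function(meta_train, frac, seed) {
  n_val_trials <- max(2L, round(nrow(meta_train) * frac / 2) * 2L)
  classes <- sort(unique(meta_train$label))
  with_seed(seed, {
    ids <- unlist(lapply(classes, function(cl) {
      cand <- which(meta_train$label == cl)
      cand[sample.int(length(cand), max(1L, n_val_trials %/% 2L))]
    }))
  })
  ids
}

#' Trial-grouped stratified cross-validation
#'
#' Runs the full leakage-safe evaluation loop: for every fold, all
#' data-dependent feature stages (CSP projections, PCA, MI ranking,
#' standardization) are fitted on the training trials only, the classifier is
#' trained, and accuracy, precision, recall and F1 (negative valence as class
#' of interest) are measured on the held-out fold. In `within_subject` mode
#' each subject is evaluated separately and the aggregate is the mean (and
#' sd) of the per-subject mean accuracies; in `cross_subject` mode folds span
#' the pooled trials and aggregation is over folds.
#'
#' @param epochs An [epoch_set()] (already broadband-preprocessed).
#' @param pipeline A [feature_pipeline()].
#' @param spec A [model_spec()].
#' @param plan A [make_folds()] plan for `epochs`.
#' @param seed Seed for classifier fitting and validation-set carving.
#' @param validation_frac Fraction of training trials carved out as the ANN
#'   validation set; defaults to 2/11 within-subject and 1/11 cross-subject.
#' @return An `eval_report` with per-fold, per-subject and aggregate tibbles.
#' @export
cross_validate <- function(epochs, pipeline, spec, plan, seed = 1L,
                           validation_frac = NULL) {
  mode <- attr(plan, "mode")
  k <- attr(plan, "k")
  if (is.null(validation_frac)) {
    validation_frac <- if (mode == "within_subject") 2 / 11 else 1 / 11
  }
  run_subject <- function(epochs_s, plan_s, seed) {
    ctx <- pipeline_prepare(pipeline, epochs_s)
    key <- paste(epochs_s$subject_ids, epochs_s$trial_ids)
    fold_of <- stats::setNames(plan_s$fold, paste(plan_s$subject_id,
                                                  plan_s$trial_id))
    epoch_fold <- as.integer(fold_of[key])
    per_fold <- lapply(sort(unique(plan_s$fold)), function(f) {
      test_idx <- which(epoch_fold == f)
      train_idx <- which(epoch_fold != f)
      fit <- pipeline_fit(ctx, train_idx)
      Xtr <- pipeline_transform(ctx, fit, train_idx)
      Xte <- pipeline_transform(ctx, fit, test_idx)
      ytr <- ctx$labels[train_idx]
      validation_idx <- NULL
      if (spec$family == "ann") {
        meta_tr <- tibble::tibble(
          subject_id = ctx$subject_ids[train_idx],
          trial_id = ctx$trial_ids[train_idx],
          label = ytr
        )
        trials_tr <- meta_tr[!duplicated(meta_tr[, 1:2]), ]
        vt <- pick_validation(trials_tr, validation_frac,
                              derive_seed(seed, f))
        vkey <- paste(trials_tr$subject_id[vt], trials_tr$trial_id[vt])
        validation_idx <- which(paste(meta_tr$subject_id,
                                      meta_tr$trial_id) %in% vkey)
      }
      model <- fit_model(spec, Xtr, ytr, validation_idx = validation_idx,
                         seed = derive_seed(seed, f))
      pred <- predict_model(model, Xte)
      m <- classification_metrics(ctx$labels[test_idx], pred)
      m$fold <- f
      m$n_train <- length(train_idx)
      m
    })
    dplyr::bind_rows(per_fold)
  }

  if (mode == "within_subject") {
    subs <- unique(plan$subject_id)
    per_fold <- dplyr::bind_rows(lapply(seq_along(subs), function(i) {
      s <- subs[i]
      sel <- epochs$subject_ids == s
      df <- run_subject(subset_epochs(epochs, sel),
                        plan[plan$subject_id == s, , drop = FALSE],
                        derive_seed(seed, i))
      df$subject_id <- s
      df
    }))
    per_subject <- per_fold |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(dplyr::across(c("accuracy", "precision", "recall", "f1"),
                                     ~ mean(.x, na.rm = TRUE)),
                       sd_accuracy = stats::sd(.data$accuracy), .groups = "drop")
    agg_src <- per_subject$accuracy
  } else {
    per_fold <- run_subject(epochs, plan, seed)
    per_fold$subject_id <- "(pooled)"
    per_subject <- NULL
    agg_src <- per_fold$accuracy
  }
  aggregate <- tibble::tibble(
    mode = mode, k = k,
    mean_accuracy = mean(agg_src), sd_accuracy = stats::sd(agg_src),
    mean_precision = mean(per_fold$precision, na.rm = TRUE),
    mean_recall = mean(per_fold$recall, na.rm = TRUE),
    mean_f1 = mean(per_fold$f1, na.rm = TRUE),
    n_epochs_evaluated = sum(per_fold$n)
  )
  structure(list(per_fold = tibble::as_tibble(per_fold),
                 per_subject = per_subject, aggregate = aggregate,
                 spec = spec, pipeline_mode = pipeline$mode, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<eval_report> %s | %s features | %s: accuracy %.1f%% +/- %.1f\n",
    x$spec$family, x$pipeline_mode, a$mode, 100 * a$mean_accuracy,
    100 * ifelse(is.na(a$sd_accuracy), 0, a$sd_accuracy)
  ))
  cat(sprintf("precision %.3f | recall %.3f | F1 %.3f | %d epochs evaluated\n",
              a$mean_precision, a$mean_recall, a$mean_f1, a$n_epochs_evaluated))
  invisible(x)
}

#' Hyperparameter grid search under the CV protocol
#'
#' Evaluates each candidate hyperparameter setting with [cross_validate()]
#' and selects by mean CV accuracy. Ties go to the simpler model (fewer
#' neighbors, smaller box constraint, fewer neurons, fewer trees, smaller C,
#' more regularization), then to the lexicographically first setting.
#'
#' @param epochs,pipeline,plan,seed As in [cross_validate()].
#' @param family Classifier family.
#' @param grid Tibble of settings (default [table2_grid()]).
#' @param n_max Optional cap: a seeded-random subsample of the grid.
#' @return List with `best_spec`, `best_report`, and a `results` tibble of
#'   mean/sd accuracy per setting.
#' @export
grid_search <- function(epochs, family, pipeline, plan, grid = NULL,
                        seed = 1L, n_max = NULL) {
  grid <- grid %||% table2_grid(family)
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) abort_value("empty hyperparameter grid")
  if (!is.null(n_max) && n_max < nrow(grid)) {
    with_seed(seed, grid <- grid[sample.int(nrow(grid), n_max), ])
  }
  complexity <- function(row) {
    switch(family,
      knn = c(row$neighbors %||% 0),
      svm = c(row$box_constraint %||% 0),
      ann = c(row$hidden %||% 0),
      rf = c(row$n_trees %||% 0, row$depth %||% 0),
      lr = c(row$C %||% 0),
      lda = c(-(row$gamma %||% 0))
    )
  }
  results <- vector("list", nrow(grid))
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- as.list(grid[i, ])
    spec <- do.call(model_spec, c(list(family = family), row))
    rep_i <- cross_validate(epochs, pipeline, spec, plan, seed = seed)
    reports[[i]] <- rep_i
    results[[i]] <- tibble::tibble(
      setting = i,
      mean_accuracy = rep_i$aggregate$mean_accuracy,
      sd_accuracy = rep_i$aggregate$sd_accuracy
    )
  }
  results <- dplyr::bind_cols(grid, dplyr::bind_rows(results))
  ord <- order(-results$mean_accuracy,
               vapply(seq_len(nrow(grid)),
                      function(i) complexity(as.list(grid[i, ]))[1], 0),
               apply(grid, 1, paste, collapse = "|"))
  best_i <- ord[1]
  list(
    best_spec = do.call(model_spec, c(list(family = family),
                                      as.list(grid[best_i, ]))),
    best_report = reports[[best_i]],
    results = results
  )
}
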