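valid_cells <- function() {
  list(
    apriori_frontal = c("entire", "alpha"),
    apriori_three_pairs = c("entire", "alpha"),
    raw = "entire", pca = "entire", csp = "entire",
    fb_raw = "entire", fb_pca = "entire", fb_csp = "entire"
  )
}

#' Assemble and validate a pipeline configuration
#'
#' A configuration ties the stages together: data source (synthetic
#' simulation or files on disk), feature mode and band, classifier family
#' with hyperparameters, and the cross-validation plan. Feature/band
#' combinations are restricted to the evaluated cells: the a-priori modes
#' run on the entire band or alpha-filtered data; the data-driven modes on
#' the entire band (the filter bank supplies the frequency resolution).
#'
#' @param feature_mode See [feature_pipeline()].
#' @param band `"entire"` or `"alpha"`.
#' @param classifier Family name or a [model_spec()].
#' @param cv_mode `"within_subject"` or `"cross_subject"`.
#' @param k Folds.
#' @param seed Master seed.
#' @param mi_k Optional mutual-information feature count.
#' @param simulate `NULL`, `TRUE` (defaults) or a named list of
#'   [synth_config()] overrides.
#' @param data Named list of file inputs (`recordings` = vector of EDF/CSV
#'   paths, `trials` = trial CSV with a `subject_id` column) when not
#'   simulating.
#' @param out_dir Optional output directory for reports.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(feature_mode = "fb_csp", band = "entire",
                            classifier = "knn",
                            cv_mode = "within_subject", k = 12L, seed = 1L,
                            mi_k = NULL, simulate = TRUE, data = NULL,
                            out_dir = NULL) {
  cells <- valid_cells()
  if (!feature_mode %in% names(cells) || !band %in% cells[[feature_mode]]) {
    abort_config(sprintf(
      "invalid feature/band combination (%s, %s); valid cells: %s",
      feature_mode, band,
      paste(vapply(names(cells), function(m) {
        sprintf("%s x {%s}", m, paste(cells[[m]], collapse = ","))
      }, ""), collapse = "; ")
    ))
  }
  if (!cv_mode %in% c("within_subject", "cross_subject")) {
    abort_config("cv_mode must be within_subject or cross_subject")
  }
  spec <- if (inherits(classifier, "model_spec")) classifier else
    model_spec(classifier)
  structure(list(feature_mode = feature_mode, band = band, classifier = spec,
                 cv_mode = cv_mode, k = as.integer(k), seed = as.integer(seed),
                 mi_k = mi_k, simulate = simulate, data = data,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys matching [pipeline_config()] arguments;
#'   `classifier` may be a string or a mapping `{family: ..., params: {...}}`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.list(y$classifier)) {
    y$classifier <- do.call(model_spec, c(list(family = y$classifier$family),
                                          y$classifier$params))
  }
  do.call(pipeline_config, y)
}

load_pipeline_epochs <- function(config) {
  if (!is.null(config$simulate) && !isFALSE(config$simulate)) {
    overrides <- if (isTRUE(config$simulate)) list() else config$simulate
    cfg <- do.call(synth_config, utils::modifyList(
      list(seed = config$seed), overrides
    ))
    epochs <- dataset_epochs(cfg)
  } else {
    d <- config$data
    if (is.null(d$recordings) || is.null(d$trials)) {
      abort_config("file-based runs need data$recordings and data$trials")
    }
    trials <- tibble::as_tibble(utils::read.csv(d$trials))
    sets <- lapply(d$recordings, function(p) {
      rec <- read_recording(p)
      tt <- trials[trials$subject_id == rec$subject_id, , drop = FALSE]
      if (nrow(tt) == 0L) {
        abort_config(sprintf("no trials for subject %s", rec$subject_id))
      }
      rec <- bandpass(rec, broadband_spec())
      segment_epochs(rec, tibble::as_tibble(tt))
    })
    epochs <- bind_epochs(sets)
  }
  if (config$band == "alpha") epochs <- bandpass(epochs, alpha_spec())
  epochs
}

#' Run the full valence-detection pipeline
#'
#' Executes load/simulate, preprocessing, epoching, feature extraction,
#' trial-grouped stratified cross-validation and metric reporting for one
#' configuration cell. The returned report embeds the resolved configuration
#' and a content hash of the epoch tensor; if `out_dir` is set, the per-fold
#' table (CSV) and the full report (JSON) are written there.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return The [cross_validate()] `eval_report`, with `config` and
#'   `input_hash` attached.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  epochs <- load_pipeline_epochs(config)
  pipe <- feature_pipeline(config$feature_mode, mi_k = config$mi_k)
  plan <- make_folds(epochs, k = config$k, mode = config$cv_mode,
                     seed = config$seed)
  report <- cross_validate(epochs, pipe, config$classifier, plan,
                           seed = config$seed)
  report$config <- config
  report$input_hash <- rlang::hash(epochs$epochs)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$per_fold,
                     file.path(config$out_dir, "per_fold.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(aggregate = report$aggregate,
           per_subject = report$per_subject,
           classifier = list(family = config$classifier$family,
                             params = config$classifier$params),
           feature_mode = config$feature_mode, band = config$band,
           cv_mode = config$cv_mode, k = config$k, seed = config$seed,
           input_hash = report$input_hash),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}
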