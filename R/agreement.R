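#' Select polarized stimuli from a normative score table
#'
#' Reproduces the stimulus-selection rule of the acquisition protocol: the
#' negative interval is `[min_score, min_score + span]` and the positive
#' interval `[max_score - span, max_score]` (with the reference table these
#' are 1.32-2.32 and 5.28-6.28 for span 1.00), and `n_per_class` images
#' are drawn at random from each interval.
#'
#' @param table Tibble with columns `stimulus_id`, `normative_valence`
#'   (1.00-7.00 scale), `normative_sd`.
#' @param span Interval width in scale units.
#' @param n_per_class Images per class.
#' @param seed Sampling seed.
#' @return The table with a `class` column (`negative`/`positive`/
#'   `excluded`), selected rows first.
#' @export
select_polarized <- function(table, span = 1.0, n_per_class = 13L, seed = 1L) {
  v <- table$normative_valence
  neg_int <- c(min(v), min(v) + span)
  pos_int <- c(max(v) - span, max(v))
  neg_pool <- which(v >= neg_int[1] & v <= neg_int[2])
  pos_pool <- which(v >= pos_int[1] & v <= pos_int[2])
  if (length(neg_pool) < n_per_class || length(pos_pool) < n_per_class) {
    abort_value(sprintf(
      "interval holds too few stimuli (negative %d, positive %d, need %d)",
      length(neg_pool), length(pos_pool), n_per_class
    ))
  }
  with_seed(seed, {
    neg_sel <- neg_pool[sample.int(length(neg_pool), n_per_class)]
    pos_sel <- pos_pool[sample.int(length(pos_pool), n_per_class)]
  })
  table$class <- "excluded"
  table$class[neg_sel] <- "negative"
  table$class[pos_sel] <- "positive"
  attr(table, "intervals") <- list(negative = neg_int, positive = pos_int)
  dplyr::arrange(tibble::as_tibble(table), .data$class != "negative",
                 .data$class != "positive", .data$normative_valence)
}

#' Cross-cultural neutral-rating exclusion
#'
#' Drops stimuli rated neutral by at least `threshold` of the pre-test
#' raters.
#'
#' @param table Stimulus tibble.
#' @param neutral_frac Per-stimulus fraction of neutral votes.
#' @param threshold Exclusion threshold (default 0.5).
#' @return The filtered tibble.
#' @export
exclude_neutral <- function(table, neutral_frac, threshold = 0.5) {
  if (length(neutral_frac) != nrow(table)) {
    abort_value("`neutral_frac` must have one value per stimulus")
  }
  tibble::as_tibble(table[neutral_frac < threshold, , drop = FALSE])
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = a - b` between two paired measurement series: mean
#' difference (bias), its standard deviation, and the conventional 95%
#' limits of agreement `mean(d) +/- 1.96 sd(d)`.
#'
#' @param a,b Paired numeric vectors (length >= 3).
#' @param loa_multiplier Width of the limits (1.96 for 95%).
#' @return A one-row tibble: `mean_difference`, `sd_difference`, `loa_low`,
#'   `loa_high`, `max_abs_difference`, `n`.
#' @export
bland_altman <- function(a, b, loa_multiplier = 1.96) {
  if (length(a) != length(b)) abort_value("paired series differ in length")
  if (length(a) < 3L) abort_value("need at least 3 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(
    mean_difference = m, sd_difference = s,
    loa_low = m - loa_multiplier * s, loa_high = m + loa_multiplier * s,
    max_abs_difference = max(abs(d)), n = length(d)
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; invariant under strictly
#' monotone transforms of either series.
#'
#' @param a,b Paired numeric vectors (length >= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) abort_value("paired series differ in length")
  if (length(a) < 3L) abort_value("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_value("constant input: rank correlation undefined")
  }
  stats::cor(a, b, method = "spearman")
}

#' Compatibility check against the normative reference
#'
#' The self-assessment sample is declared compatible with the normative
#' sample when the maximum absolute difference between the (rescaled) SAM
#' means and the normative scores stays below the threshold, by default the
#' average normative standard deviation.
#'
#' @param sam_means Per-stimulus mean self-assessment scores, on the
#'   normative scale.
#' @param normative Per-stimulus normative scores.
#' @param threshold Scale-unit threshold (default: caller supplies the mean
#'   normative SD).
#' @return A list: `compatible` (logical), `max_abs_difference`, `threshold`.
#' @export
compatibility_check <- function(sam_means, normative, threshold) {
  if (length(sam_means) != length(normative)) {
    abort_value("paired series differ in length")
  }
  mx <- max(abs(sam_means - normative))
  list(compatible = mx < threshold, max_abs_difference = mx,
       threshold = threshold)
}

#' SAM 1-5 ratings to the normative 1-7 scale
#' @param rating Numeric ratings on 1-5.
#' @return Linearly rescaled values on 1-7.
#' @export
sam_to_normative_scale <- function(rating) 1 + (rating - 1) * 6 / 4

#' Full agreement analysis between SAM ratings and normative scores
#'
#' Aggregates per-stimulus SAM means, rescales them to the normative 1-7
#' scale (linear map by default), and reports Bland-Altman statistics,
#' Spearman rho and the compatibility verdict against the mean normative SD.
#'
#' @param stimuli Stimulus tibble with `stimulus_id`, `normative_valence`,
#'   `normative_sd` (selected stimuli only).
#' @param sam Tibble of ratings with `subject_id`, `stimulus_id`, `rating`
#'   (1-5 scale).
#' @param rescale `"linear"` (default) or `"none"`.
#' @param threshold Compatibility threshold; default mean of `normative_sd`.
#' @return An `agreement_report` list: `per_stimulus` tibble,
#'   `bland_altman`, `spearman_rho`, `compatibility`, `rescale`.
#' @export
agreement_report <- function(stimuli, sam, rescale = c("linear", "none"),
                             threshold = NULL) {
  rescale <- match.arg(rescale)
  sam_means <- sam |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(sam_mean = mean(.data$rating), .groups = "drop")
  df <- dplyr::inner_join(
    tibble::as_tibble(stimuli)[, c("stimulus_id", "normative_valence",
                                   "normative_sd")],
    sam_means, by = "stimulus_id"
  )
  if (nrow(df) < 3L) abort_value("need at least 3 paired stimuli")
  df$sam_scaled <- if (rescale == "linear") {
    sam_to_normative_scale(df$sam_mean)
  } else df$sam_mean
  threshold <- threshold %||% mean(df$normative_sd)
  ba <- bland_altman(df$sam_scaled, df$normative_valence)
  rho <- spearman_rho(df$sam_scaled, df$normative_valence)
  comp <- compatibility_check(df$sam_scaled, df$normative_valence, threshold)
  structure(list(per_stimulus = df, bland_altman = ba, spearman_rho = rho,
                 compatibility = comp, rescale = rescale),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf(
    "<agreement_report> n = %d stimuli | bias %.3f [LoA %.3f, %.3f] | rho %.3f\n",
    ba$n, ba$mean_difference, ba$loa_low, ba$loa_high, x$spearman_rho
  ))
  cat(sprintf("compatible: %s (max |diff| %.3f vs threshold %.3f)\n",
              x$compatibility$compatible, x$compatibility$max_abs_difference,
              x$compatibility$threshold))
  invisible(x)
}
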