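#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted CSP model
#'
#' One row per (band, component) with the class-1 variance-ratio eigenvalue.
#' @param x A `csp_model`.
#' @param ... Unused.
#' @return A tibble: `band`, `band_low`, `band_high`, `component`,
#'   `eigenvalue`.
#' @export
tidy.csp_model <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$bands), function(b) {
    tibble::tibble(
      band = b,
      band_low = x$band_edges[b, 1], band_high = x$band_edges[b, 2],
      component = seq_len(x$n_components),
      eigenvalue = x$bands[[b]]$eigenvalues
    )
  }))
}

#' @rdname tidy.csp_model
#' @export
glance.csp_model <- function(x, ...) {
  td <- tidy.csp_model(x)
  tibble::tibble(
    n_bands = length(x$bands), n_components = x$n_components,
    max_eigenvalue = max(td$eigenvalue),
    max_contrast = max(abs(td$eigenvalue - 0.5)),
    class1 = x$class1
  )
}

#' Tidy a cross-validation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Per-fold metrics tibble ([tidy()]) or the one-row aggregate
#'   ([glance()]).
#' @export
tidy.eval_report <- function(x, ...) x$per_fold

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) x$aggregate

#' Tidy an agreement report
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return Per-stimulus tibble ([tidy()]) or the one-row summary
#'   ([glance()]).
#' @export
tidy.agreement_report <- function(x, ...) x$per_stimulus

#' @rdname tidy.agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  ba <- x$bland_altman
  tibble::tibble(
    n = ba$n, mean_difference = ba$mean_difference,
    sd_difference = ba$sd_difference, loa_low = ba$loa_low,
    loa_high = ba$loa_high, spearman_rho = x$spearman_rho,
    max_abs_difference = x$compatibility$max_abs_difference,
    threshold = x$compatibility$threshold,
    compatible = x$compatibility$compatible
  )
}

#' Plot CSP eigenvalue spectra per band
#' @param object A `csp_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csp_model <- function(object, ...) {
  td <- tidy.csp_model(object)
  td$band_label <- sprintf("%g-%g Hz", td$band_low, td$band_high)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~band_label) +
    ggplot2::labs(y = "class-1 variance ratio", x = "CSP component") +
    ggplot2::theme_minimal()
}

#' Plot per-fold accuracies of a CV report
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  pf <- object$per_fold
  ggplot2::ggplot(pf, ggplot2::aes(x = .data$subject_id, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = NULL, y = "fold accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bland-Altman plot of an agreement report
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- object$per_stimulus
  df$avg <- (df$sam_scaled + df$normative_valence) / 2
  df$diff <- df$sam_scaled - df$normative_valence
  ba <- object$bland_altman
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_difference, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = 2, colour = "indianred") +
    ggplot2::labs(x = "mean of SAM (rescaled) and normative score",
                  y = "difference (SAM - normative)") +
    ggplot2::theme_minimal()
}
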