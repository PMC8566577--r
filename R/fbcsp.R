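#' Design the 12-band filter bank
#'
#' Contiguous 4-Hz Chebyshev type II band-pass filters spanning 0.5-48.5 Hz:
#' 0.5-4.5, 4.5-8.5, ..., 44.5-48.5 Hz. The narrowing of the five classical
#' EEG bands into 12 sub-bands raises the frequency resolution of the
#' features presented to the spatial filter.
#'
#' @param fs Sampling rate, Hz; must exceed twice the top band edge.
#' @param band_start,band_end Outer edges, Hz.
#' @param bandwidth Width of each band, Hz.
#' @param order Chebyshev II design order per pass.
#' @param stopband_atten_db Stopband attenuation, dB.
#' @return A `filter_bank` object: list of [filter_spec()]s plus the band
#'   edge table.
#' @export
design_filter_bank <- function(fs, band_start = 0.5, band_end = 48.5,
                               bandwidth = 4, order = 4L,
                               stopband_atten_db = 30) {
  if (fs <= 2 * band_end) {
    abort_value(sprintf("fs = %g Hz too low for a %g Hz top band edge", fs,
                        band_end))
  }
  lows <- seq(band_start, band_end - bandwidth, by = bandwidth)
  bands <- cbind(low = lows, high = lows + bandwidth)
  specs <- lapply(seq_len(nrow(bands)), function(i) {
    if (i == 1L) {
      # a transfer-function bandpass with a sub-hertz stopband edge is
      # numerically unstable at this fs; the lowest band is realized as a
      # lowpass, its low edge being enforced by the broadband preprocessing
      filter_spec("chebyshev2", max(order + 2L, 6L), bands[i, ],
                  stopband_atten_db = stopband_atten_db, design = "lowpass")
    } else {
      filter_spec("chebyshev2", order, bands[i, ],
                  stopband_atten_db = stopband_atten_db)
    }
  })
  structure(list(bands = bands, specs = specs, fs = fs), class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d bands of %g Hz, %g-%g Hz (Chebyshev II)\n",
              nrow(x$bands), x$bands[1, 2] - x$bands[1, 1],
              min(x$bands), max(x$bands)))
  invisible(x)
}

#' Apply a filter bank to an epoch set
#'
#' Zero-phase application of every band filter, returning the banked tensor
#' `[n_epochs x n_bands x n_channels x n_samples]` that the CSP stage
#' consumes (flattened size `n_bands * n_channels * n_samples` per epoch;
#' 12 x 8 x 1024 = 98304 for the protocol shape).
#'
#' @param epochs An [epoch_set()].
#' @param bank A [design_filter_bank()] result.
#' @return A `banked_epochs` object.
#' @export
apply_filter_bank <- function(epochs, bank) {
  d <- dim(epochs$epochs)
  nb <- nrow(bank$bands)
  arr <- array(0, dim = c(d[1], nb, d[2], d[3]))
  for (b in seq_len(nb)) {
    arr[, b, , ] <- bandpass(epochs, bank$specs[[b]])$epochs
  }
  structure(
    list(epochs = arr, bands = bank$bands, labels = epochs$labels,
         trial_ids = epochs$trial_ids, subject_ids = epochs$subject_ids,
         fs = epochs$fs, channel_labels = epochs$channel_labels),
    class = "banked_epochs"
  )
}

# Per-epoch, per-band spatial covariance tensor [n_epochs x n_bands x ch x ch]
# (unnormalized X X^T; trace-normalization happens where needed). For an
# epoch_set, a single "band" holding the input as-is is used. Computing these
# once makes CSP fitting inside every CV fold an averaging step.
epoch_covariances <- function(x, bank = NULL) {
  if (inherits(x, "banked_epochs")) {
    d <- dim(x$epochs)
    out <- array(0, dim = c(d[1], d[2], d[3], d[3]))
    for (i in seq_len(d[1])) {
      for (b in seq_len(d[2])) {
        out[i, b, , ] <- tcrossprod(x$epochs[i, b, , ])
      }
    }
    structure(list(cov = out, bands = x$bands, labels = x$labels,
                   trial_ids = x$trial_ids, subject_ids = x$subject_ids,
                   channel_labels = x$channel_labels),
              class = "epoch_cov")
  } else if (inherits(x, "epoch_set")) {
    if (!is.null(bank)) {
      # band-at-a-time to avoid materializing the banked tensor
      d <- dim(x$epochs)
      nb <- nrow(bank$bands)
      out <- array(0, dim = c(d[1], nb, d[2], d[2]))
      for (b in seq_len(nb)) {
        filt <- bandpass(x, bank$specs[[b]])
        for (i in seq_len(d[1])) out[i, b, , ] <- tcrossprod(filt$epochs[i, , ])
      }
      structure(list(cov = out, bands = bank$bands, labels = x$labels,
                     trial_ids = x$trial_ids, subject_ids = x$subject_ids,
                     channel_labels = x$channel_labels),
                class = "epoch_cov")
    } else {
      d <- dim(x$epochs)
      out <- array(0, dim = c(d[1], 1L, d[2], d[2]))
      for (i in seq_len(d[1])) out[i, 1, , ] <- tcrossprod(x$epochs[i, , ])
      structure(list(cov = out, bands = matrix(c(NA, NA), 1), labels = x$labels,
                     trial_ids = x$trial_ids, subject_ids = x$subject_ids,
                     channel_labels = x$channel_labels),
                class = "epoch_cov")
    }
  } else {
    abort_value("expected an epoch_set or banked_epochs")
  }
}

# CSP for one band from trace-normalized class-average covariances.
csp_one_band <- function(C1, C2, reg_eps = 1e-10) {
  p <- nrow(C1)
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  tol <- p * .Machine$double.eps * max(ec$values)
  if (min(ec$values) <= tol) {
    warning("rank-deficient composite covariance; regularizing", call. = FALSE)
    Cc <- Cc + reg_eps * sum(diag(Cc)) * diag(p)
    ec <- eigen(Cc, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors) # whitening: P Cc P' = I
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  eu <- eigen(S1, symmetric = TRUE) # descending for class 1
  W <- t(P) %*% eu$vectors # columns are spatial filters; W' Cc W = I
  # sign convention: largest-|entry| of each filter positive
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  A <- Cc %*% W # spatial patterns (forward model), columns
  list(W = W, patterns = A, eigenvalues = pmin(pmax(eu$values, 0), 1),
       C1 = C1, C2 = C2)
}

#' Fit Common Spatial Patterns per band
#'
#' For each band, class covariances are estimated as the per-class average of
#' trace-normalized per-epoch sample covariances. The composite covariance is
#' whitened and the whitened class-1 covariance eigendecomposed; the
#' projection `W` (columns = spatial filters) simultaneously diagonalizes the
#' two class covariances, with eigenvalues sorted decreasing for class 1 (so
#' they are ascending for class 2; the per-component pair sums to 1). All
#' `n_channels` components are retained.
#'
#' @param x An [epoch_set()], [apply_filter_bank()] output, or an internal
#'   covariance tensor.
#' @param labels Optional label override (defaults to `x$labels`).
#' @param class1 Label treated as class 1 (default `"negative"`, the class of
#'   interest).
#' @return A `csp_model`: one entry per band with `W`, `patterns`,
#'   `eigenvalues`, `C1`, `C2`.
#' @export
fit_csp <- function(x, labels = NULL, class1 = "negative") {
  cv <- if (inherits(x, "epoch_cov")) x else epoch_covariances(x)
  labels <- labels %||% cv$labels
  fit_csp_cov(cv, labels, class1)
}

fit_csp_cov <- function(cv, labels = NULL, class1 = "negative",
                        idx = NULL) {
  labels <- labels %||% cv$labels
  if (!is.null(idx)) {
    labels <- labels[idx]
  } else {
    idx <- seq_along(labels)
  }
  classes <- unique(labels)
  if (length(classes) != 2L) {
    abort_value(sprintf("CSP requires exactly two classes, got %d",
                        length(classes)))
  }
  if (!class1 %in% classes) class1 <- sort(classes)[1]
  class2 <- setdiff(classes, class1)
  nb <- dim(cv$cov)[2]
  p <- dim(cv$cov)[3]
  i1 <- idx[labels == class1]
  i2 <- idx[labels == class2]
  bands <- vector("list", nb)
  for (b in seq_len(nb)) {
    avg_cov <- function(ii) {
      acc <- matrix(0, p, p)
      for (i in ii) {
        Ci <- cv$cov[i, b, , ]
        acc <- acc + Ci / sum(diag(Ci))
      }
      acc / length(ii)
    }
    bands[[b]] <- csp_one_band(avg_cov(i1), avg_cov(i2))
  }
  structure(
    list(bands = bands, band_edges = cv$bands, class1 = class1,
         class2 = class2, channel_labels = cv$channel_labels,
         n_components = p),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d band(s) x %d components (class 1 = %s)\n",
              length(x$bands), x$n_components, x$class1))
  top <- vapply(x$bands, function(b) b$eigenvalues[1], 0)
  cat("top eigenvalue per band:", paste(sprintf("%.2f", top), collapse = " "),
      "\n")
  invisible(x)
}

#' Log-variance CSP features
#'
#' Per epoch and band, the data are projected through the fitted spatial
#' filters and each component's variance, normalized by the sum over
#' components, is (by default) log-transformed. With 12 bands and 8 retained
#' components this yields the 96-dimensional feature vector; the
#' normalization makes the features invariant to a per-epoch amplitude
#' rescaling.
#'
#' @param x Same input kinds as [fit_csp()].
#' @param model A fitted `csp_model` on the same montage/bands.
#' @param log Log-transform the normalized variances (default `TRUE`).
#' @return Numeric matrix `[n_epochs x (n_bands * n_components)]` with
#'   `band.component` column names.
#' @export
csp_features <- function(x, model, log = TRUE) {
  cv <- if (inherits(x, "epoch_cov")) x else epoch_covariances(x)
  csp_features_cov(cv, model, log = log)
}

csp_features_cov <- function(cv, model, idx = NULL, log = TRUE) {
  d <- dim(cv$cov)
  if (is.null(idx)) idx <- seq_len(d[1])
  nb <- d[2]
  if (nb != length(model$bands) || d[3] != length(model$channel_labels)) {
    abort_value("shape mismatch between data and fitted CSP model")
  }
  p <- model$n_components
  out <- matrix(0, length(idx), nb * p)
  for (b in seq_len(nb)) {
    W <- model$bands[[b]]$W
    for (k in seq_along(idx)) {
      v <- diag(t(W) %*% cv$cov[idx[k], b, , ] %*% W)
      v <- v / sum(v)
      out[k, ((b - 1) * p + 1):(b * p)] <- if (log) base::log(v) else v
    }
  }
  colnames(out) <- as.vector(outer(seq_len(p), seq_len(nb),
                                   function(c, b) sprintf("b%02d.c%d", b, c)))
  out
}

#' Principal-component feature reduction
#'
#' Centers the training features and retains the smallest number of
#' components whose cumulative explained variance reaches `variance_kept`
#' (0.95 in the reference pipeline). Fit on training rows only; apply to
#' held-out rows with [predict()].
#'
#' @param X Numeric feature matrix (training rows).
#' @param variance_kept Fraction of variance to retain, in `(0, 1]`.
#' @return A `pca_reducer` with `center`, `rotation`, `n_components`.
#' @export
fit_pca <- function(X, variance_kept = 0.95) {
  if (variance_kept <= 0 || variance_kept > 1) {
    abort_value("`variance_kept` must be in (0, 1]")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > .Machine$double.eps * ev[1]]
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance_kept - 1e-12)[1]
  structure(list(center = pc$center, rotation = pc$rotation[, 1:k, drop = FALSE],
                 n_components = k, explained = cum[k]),
            class = "pca_reducer")
}

#' @export
predict.pca_reducer <- function(object, newdata, ...) {
  sweep(newdata, 2, object$center) %*% object$rotation
}

#' Mutual-information feature ranking
#'
#' Ranks features by the estimated mutual information between each feature
#' and the class label (plug-in estimate over equal-frequency bins) and
#' returns the indices of the top `k`. Intended to be fitted on training rows
#' only.
#'
#' @param X Numeric feature matrix.
#' @param labels Class labels.
#' @param k Number of features to keep.
#' @param n_bins Number of discretization bins.
#' @return Integer vector of the `k` selected column indices (highest MI
#'   first), with the full score vector as attribute `"scores"`.
#' @export
mi_rank <- function(X, labels, k, n_bins = 8L) {
  if (k <= 0) abort_value("`k` must be positive")
  if (k > ncol(X)) abort_value("`k` exceeds the number of features")
  y <- as.integer(factor(labels))
  scores <- vapply(seq_len(ncol(X)), function(j) {
    mutual_information(X[, j], y, n_bins)
  }, 0)
  ord <- order(scores, decreasing = TRUE)
  out <- ord[seq_len(k)]
  attr(out, "scores") <- scores
  out
}

mutual_information <- function(x, y, n_bins = 8L) {
  brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                names = FALSE, type = 7))
  if (length(brk) < 2L) return(0)
  xb <- cut(x, breaks = brk, include.lowest = TRUE, labels = FALSE)
  joint <- table(xb, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      pij <- joint[i, j]
      if (pij > 0) mi <- mi + pij * base::log(pij / (px[i] * py[j]))
    }
  }
  as.numeric(mi)
}

#' Serialize / restore a fitted CSP model
#'
#' Writes band edges, spatial filters, patterns, eigenvalues and class
#' covariances to a YAML archive readable across sessions.
#'
#' @param model A `csp_model`.
#' @param path Output path.
#' @return `path` (write) or the restored `csp_model` (read).
#' @export
write_csp_model <- function(model, path) {
  ser <- list(
    class1 = model$class1, class2 = model$class2,
    channel_labels = model$channel_labels,
    n_components = model$n_components,
    band_edges = apply(model$band_edges, 1, as.numeric, simplify = FALSE),
    bands = lapply(model$bands, function(b) {
      list(W = as.numeric(b$W), patterns = as.numeric(b$patterns),
           eigenvalues = as.numeric(b$eigenvalues),
           C1 = as.numeric(b$C1), C2 = as.numeric(b$C2))
    })
  )
  yaml::write_yaml(ser, path, precision = 17L)
  invisible(path)
}

#' @rdname write_csp_model
#' @export
read_csp_model <- function(path) {
  ser <- yaml::read_yaml(path)
  p <- length(ser$channel_labels)
  bands <- lapply(ser$bands, function(b) {
    list(W = matrix(b$W, p), patterns = matrix(b$patterns, p),
         eigenvalues = as.numeric(b$eigenvalues),
         C1 = matrix(b$C1, p), C2 = matrix(b$C2, p))
  })
  be <- do.call(rbind, lapply(ser$band_edges, as.numeric))
  colnames(be) <- c("low", "high")
  structure(
    list(bands = bands, band_edges = be, class1 = ser$class1,
         class2 = ser$class2, channel_labels = unlist(ser$channel_labels),
         n_components = ser$n_components),
    class = "csp_model"
  )
}
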