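test_that("the filter bank is 12 contiguous 4-Hz Chebyshev II bands over 0.5-48.5", {
  bank <- design_filter_bank(fs_test)
  expect_equal(nrow(bank$bands), 12L)
  expect_equal(unname(bank$bands[1, ]), c(0.5, 4.5))
  expect_equal(unname(bank$bands[12, ]), c(44.5, 48.5))
  expect_true(all(bank$bands[-1, 1] == bank$bands[-12, 2])) # no gaps
  expect_true(all(bank$bands[, 2] - bank$bands[, 1] == 4))
  expect_error(design_filter_bank(90), class = "fbcsp_value_error")
})

test_that("banked tensor has the protocol shape and bands select their tones", {
  bank <- design_filter_bank(fs_test)
  ep <- noise_epochs(n_trials = 2, n_samp = 1024)
  banked <- apply_filter_bank(ep, bank)
  expect_equal(dim(banked$epochs), c(8, 12, 8, 1024))
  expect_equal(prod(dim(banked$epochs)[-1]), 98304L)

  # 10 Hz tone concentrates in band 3 (8.5-12.5); others attenuated > 20 dB
  t <- seq(0, 2 - 1 / fs_test, by = 1 / fs_test)
  tone <- sin(2 * pi * 10 * t)
  arr <- array(rep(tone, each = 2), c(1, 2, 1024))
  ep1 <- epoch_set(arr, "negative", 1L, "s01", fs_test, c("A", "B"))
  b1 <- apply_filter_bank(ep1, bank)
  mid <- 300:700
  rms <- vapply(1:12, function(b) sqrt(mean(b1$epochs[1, b, 1, mid]^2)), 0)
  expect_equal(which.max(rms), 3L)
  expect_true(all(20 * log10(rms[-3] / rms[3]) < -20))

  # white noise: per-band variance roughly proportional to bandwidth share
  set.seed(5)
  epw <- noise_epochs(n_trials = 4, n_ch = 2, n_samp = 2048)
  bw <- apply_filter_bank(epw, bank)
  v <- vapply(1:12, function(b) mean(bw$epochs[, b, , ]^2), 0)
  mid_bands <- 2:11 # edge bands lose part of their 4 Hz to the transition
  expect_lt(max(abs(v[mid_bands] / mean(v[mid_bands]) - 1)), 0.25)
})

test_that("CSP solves the planted two-channel problem in closed form", {
  # identical class covariances: no structure, all eigenvalues 1/2
  C <- crossprod(matrix(rnorm(16), 4))
  m0 <- fbcsp:::csp_one_band(C / sum(diag(C)), C / sum(diag(C)))
  expect_equal(m0$eigenvalues, rep(0.5, 4), tolerance = 1e-10)

  # diag(4,1) vs diag(1,4): trace-normalized eigenvalues 0.8 / 0.2,
  # axis-aligned filters
  m <- fbcsp:::csp_one_band(diag(c(4, 1)) / 5, diag(c(1, 4)) / 5)
  expect_equal(m$eigenvalues, c(0.8, 0.2), tolerance = 1e-12)
  W <- apply(abs(m$W), 2, which.max)
  expect_equal(W, c(1L, 2L))
})

test_that("whitening-route CSP equals the generalized eigenproblem oracle", {
  set.seed(77)
  for (rep in 1:10) {
    p <- sample(4:8, 1)
    C1 <- crossprod(matrix(rnorm(12 * p), 12))
    C2 <- crossprod(matrix(rnorm(12 * p), 12))
    C1 <- C1 / sum(diag(C1)); C2 <- C2 / sum(diag(C2))
    m <- fbcsp:::csp_one_band(C1, C2)
    # oracle: brute-force non-symmetric eigensolve of (C1+C2)^-1 C1
    ge <- eigen(solve(C1 + C2) %*% C1)
    ord <- order(Re(ge$values), decreasing = TRUE)
    expect_equal(m$eigenvalues, Re(ge$values)[ord], tolerance = 1e-9)
    for (j in seq_len(p)) {
      v <- Re(ge$vectors[, ord[j]])
      cosang <- abs(sum(v * m$W[, j])) / sqrt(sum(v^2) * sum(m$W[, j]^2))
      expect_lt(acos(pmin(cosang, 1)), 1e-6)
    }
    # simultaneous diagonalization and the paired-eigenvalue identity
    D1 <- t(m$W) %*% C1 %*% m$W
    D2 <- t(m$W) %*% C2 %*% m$W
    expect_lt(max(abs(D1[lower.tri(D1)])), 1e-8)
    expect_lt(max(abs(D2[lower.tri(D2)])), 1e-8)
    expect_equal(diag(D1) + diag(D2), rep(1, p), tolerance = 1e-10)
  }
})

test_that("CSP features have the protocol dimensionality and invariances", {
  set.seed(12)
  ep <- noise_epochs(n_trials = 6)
  bank <- design_filter_bank(fs_test)
  cvb <- fbcsp:::epoch_covariances(ep, bank)
  mod <- fit_csp(cvb)
  X <- csp_features(cvb, mod)
  expect_equal(ncol(X), 96L)
  expect_equal(nrow(X), 24L)

  # broadband (single-band) route gives 8 features per epoch
  mod1 <- fit_csp(ep)
  X1 <- csp_features(ep, mod1)
  expect_equal(ncol(X1), 8L)

  # per-epoch amplitude rescaling cancels in the normalized variances
  ep2 <- ep; ep2$epochs <- ep2$epochs * 5.5
  expect_equal(csp_features(ep2, mod1), X1, tolerance = 1e-10)

  # invariance under an invertible channel mixing applied to the data
  A <- diag(8) + matrix(rnorm(64, sd = 0.2), 8)
  epm <- ep
  for (i in seq_len(dim(ep$epochs)[1])) epm$epochs[i, , ] <- A %*% ep$epochs[i, , ]
  modm <- fit_csp(epm)
  # per-epoch trace normalization makes the invariance exact only in the
  # limit; at 24 epochs small deviations remain
  expect_equal(csp_features(epm, modm), csp_features(ep, mod1),
               tolerance = 0.02, ignore_attr = TRUE)

  # single-class input is rejected
  expect_error(fit_csp(ep, labels = rep("negative", 24)),
               class = "fbcsp_value_error")
})

test_that("CSP model YAML serialization round-trips", {
  set.seed(3)
  ep <- noise_epochs(n_trials = 4, n_ch = 4, n_samp = 512)
  mod <- fit_csp(ep)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_csp_model(mod, path)
  back <- read_csp_model(path)
  expect_equal(back$bands[[1]]$W, mod$bands[[1]]$W, tolerance = 1e-12)
  expect_equal(back$bands[[1]]$eigenvalues, mod$bands[[1]]$eigenvalues,
               tolerance = 1e-12)
  expect_identical(back$channel_labels, mod$channel_labels)
})

test_that("PCA reduction retains the requested variance on training rows only", {
  set.seed(9)
  # one dominant direction holding ~99% of the variance -> 1 component at 95%
  n <- 60
  u <- rnorm(20); u <- u / sqrt(sum(u^2))
  X <- outer(rnorm(n, sd = 10), u) + matrix(rnorm(n * 20, sd = 0.3), n)
  red <- fit_pca(X, 0.95)
  expect_equal(red$n_components, 1L)

  # full variance keeps min(n-1, p) informative components
  Xf <- matrix(rnorm(30 * 5), 30)
  expect_equal(fit_pca(Xf, 1.0)$n_components, 5L)

  # the training mean maps to the zero vector
  expect_equal(as.numeric(predict(red, matrix(colMeans(X), 1))),
               rep(0, red$n_components), tolerance = 1e-10)

  expect_error(fit_pca(X, 0), class = "fbcsp_value_error")
  expect_error(fit_pca(X, 1.2), class = "fbcsp_value_error")
})

test_that("mutual-information ranking orders label-informative features first", {
  set.seed(21)
  n <- 200
  y <- rep(c("negative", "positive"), each = n / 2)
  X <- cbind(
    label_copy = as.numeric(y == "negative"),
    informative = as.numeric(y == "negative") + rnorm(n, sd = 0.5),
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  sel <- mi_rank(X, y, k = 2)
  expect_equal(sel[1], 1L) # the label itself has maximal MI
  expect_equal(sort(sel), c(1L, 2L))
  scores <- attr(sel, "scores")
  expect_lt(max(scores[3:4]), 0.05)
  expect_gt(scores[1], log(2) - 0.01)

  # k = n_features returns all features, reordered
  expect_setequal(as.integer(mi_rank(X, y, k = 4)), 1:4)
  expect_error(mi_rank(X, y, k = 0), class = "fbcsp_value_error")
  expect_error(mi_rank(X, y, k = 9), class = "fbcsp_value_error")
})
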