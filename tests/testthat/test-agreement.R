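make_pool <- function(n = 120, seed = 3) {
  set.seed(seed)
  tibble::tibble(
    stimulus_id = sprintf("img%03d", 1:n),
    normative_valence = round(c(1.32, 6.28, runif(n - 2, 1.32, 6.28)), 2),
    normative_sd = round(runif(n, 0.6, 1.4), 2)
  )
}

test_that("polarized selection reproduces the scoring intervals", {
  pool <- make_pool()
  sel <- select_polarized(pool, span = 1.0, n_per_class = 13, seed = 2)
  ints <- attr(sel, "intervals")
  expect_equal(ints$negative, c(1.32, 2.32))
  expect_equal(ints$positive, c(5.28, 6.28))
  expect_equal(sum(sel$class == "negative"), 13L)
  expect_equal(sum(sel$class == "positive"), 13L)
  expect_equal(sum(sel$class != "excluded"), 26L)
  neg <- sel$normative_valence[sel$class == "negative"]
  pos <- sel$normative_valence[sel$class == "positive"]
  expect_true(all(neg >= 1.32 & neg <= 2.32))
  expect_true(all(pos >= 5.28 & pos <= 6.28))

  # span 0 keeps only exact extremes
  sel0 <- select_polarized(pool, span = 0, n_per_class = 1, seed = 1)
  expect_equal(sel0$normative_valence[sel0$class == "negative"], 1.32)
  expect_equal(sel0$normative_valence[sel0$class == "positive"], 6.28)

  expect_error(select_polarized(pool, span = 0, n_per_class = 3),
               class = "fbcsp_value_error")
})

test_that("neutral-vote exclusion filters at the 50% threshold", {
  pool <- make_pool(10)
  frac <- c(0.6, 0.5, 0.49, rep(0.1, 7))
  kept <- exclude_neutral(pool, frac)
  expect_equal(nrow(kept), 8L)
  expect_false(any(kept$stimulus_id %in% pool$stimulus_id[1:2]))
})

test_that("Bland-Altman agrees with the direct formula oracle", {
  # identical series: zero bias and degenerate limits
  a <- c(1, 2, 3, 4)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  # constant offset: bias -0.5, sd 0
  ba1 <- bland_altman(a, a + 0.5)
  expect_equal(ba1$mean_difference, -0.5)
  expect_equal(ba1$sd_difference, 0)

  # seeded random pairs vs. writing the formulas out longhand
  set.seed(14)
  x <- rnorm(40); y <- rnorm(40)
  ba <- bland_altman(x, y)
  d <- x - y
  md <- sum(d) / length(d)
  sd_d <- sqrt(sum((d - md)^2) / (length(d) - 1))
  expect_equal(ba$mean_difference, md, tolerance = 1e-12)
  expect_equal(ba$sd_difference, sd_d, tolerance = 1e-12)
  expect_equal(ba$loa_low, md - 1.96 * sd_d, tolerance = 1e-12)
  expect_equal(ba$loa_high, md + 1.96 * sd_d, tolerance = 1e-12)

  # antisymmetry: swapping the series negates bias and mirrors limits
  ba_sw <- bland_altman(y, x)
  expect_equal(ba_sw$mean_difference, -ba$mean_difference, tolerance = 1e-12)
  expect_equal(ba_sw$loa_low, -ba$loa_high, tolerance = 1e-12)

  expect_error(bland_altman(1:4, 1:5), class = "fbcsp_value_error")
  expect_error(bland_altman(1:2, 1:2), class = "fbcsp_value_error")
})

test_that("Spearman rho matches a rank-then-Pearson oracle and its invariances", {
  expect_equal(spearman_rho(1:10, exp(1:10)), 1.0)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1.0)

  # ties handled by average ranks: compare against longhand ranked Pearson
  a <- c(1, 2, 2, 3, 5, 5, 7)
  b <- c(2.2, 1.1, 3.3, 3.3, 4.4, 6.6, 5.5)
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearman_rho(a, b), oracle, tolerance = 1e-12)

  # invariant under strictly monotone transforms
  set.seed(2)
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y), tolerance = 1e-12)

  expect_error(spearman_rho(rep(1, 5), 1:5), class = "fbcsp_value_error")
})

test_that("compatibility verdict uses the average normative SD threshold", {
  expect_true(compatibility_check(1:5, 1:5, threshold = 0.1)$compatible)
  out <- compatibility_check(c(1, 2.5), c(1, 1), threshold = 1.0)
  expect_false(out$compatible)
  expect_equal(out$max_abs_difference, 1.5)
})

test_that("the full agreement report ties selection, rescaling and statistics", {
  pool <- make_pool()
  sel <- select_polarized(pool, seed = 5)
  chosen <- sel[sel$class != "excluded", ]
  # two raters whose rescaled ratings sit near the normative scores
  set.seed(6)
  sam <- dplyr::bind_rows(lapply(c("s01", "s02"), function(s) {
    v7 <- pmin(pmax(chosen$normative_valence + rnorm(26, 0, 0.3), 1), 7)
    tibble::tibble(subject_id = s, stimulus_id = chosen$stimulus_id,
                   rating = round(1 + (v7 - 1) * 4 / 6))
  }))
  rep <- agreement_report(chosen, sam)
  expect_s3_class(rep, "agreement_report")
  expect_equal(nrow(rep$per_stimulus), 26L)
  expect_equal(rep$compatibility$threshold, mean(chosen$normative_sd))
  expect_gt(rep$spearman_rho, 0.85)
  expect_true(rep$compatibility$compatible)
  g <- glance(rep)
  expect_tibble(g)
  expect_equal(g$spearman_rho, rep$spearman_rho)
})
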