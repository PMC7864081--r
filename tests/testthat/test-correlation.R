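test_that("pearson_correlation recovers exact linear relationships", {
  x <- c(0.3, 1.2, 2.2, 5.0, 7.7)
  res <- pearson_correlation(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
})

test_that("pearson r matches the covariance/std formula computed by hand", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y)$r, brute, tolerance = 1e-12)
})

test_that("confidence band is symmetric about the fitted line and t-based", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.2, 1.8, 4.1, 3.3, 6.2, 5.9)
  res <- pearson_correlation(x, y)
  band <- res$ci95_band
  expect_equal(band$fit - band$lwr, band$upr - band$fit)
  expect_equal(band$fit, res$intercept + res$slope * band$x)
  # half-width follows the t-based mean-confidence formula at every point
  fit <- lm(y ~ x)
  s <- summary(fit)$sigma
  sxx <- sum((x - mean(x))^2)
  hw <- qt(0.975, 4) * s * sqrt(1 / 6 + (band$x - mean(x))^2 / sxx)
  expect_equal(band$upr - band$fit, hw, tolerance = 1e-8)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
})

test_that("random signatures are uniform draws honoring size, seed and exclusions", {
  uni <- paste0("g", 1:40)
  # forced draw: set_size = |universe|
  s <- random_signatures(uni, 40, B = 3, seed = 1)
  for (sig in s) expect_setequal(sig$genes, uni)
  # reproducibility
  expect_identical(random_signatures(uni, 5, B = 2, seed = 9),
                   random_signatures(uni, 5, B = 2, seed = 9))
  # exclusions never drawn, scanned over many draws
  excl <- gene_signature("ex", paste0("g", 1:10))
  drawn <- random_signatures(uni, 10, B = 1000, seed = 4, exclude = excl)
  expect_false(any(vapply(drawn, function(s)
    any(s$genes %in% excl$genes), logical(1))))
  expect_error(random_signatures(uni, 35, B = 1, seed = 1, exclude = excl),
               "smaller")
  expect_error(random_signatures(uni, 5, B = 0, seed = 1), "B")
})

test_that("add-one empirical p never hits zero and calibrates at the median", {
  nulls <- withr::with_seed(2, runif(999, -1, 1))
  expect_equal(empirical_pvalue(2, nulls, "greater"), 1 / 1000)
  expect_equal(empirical_pvalue(-2, nulls, "greater"), 1)
  expect_gt(empirical_pvalue(2, nulls, "two_sided"), 0)
  # observed at the null median -> p about 0.5
  expect_equal(empirical_pvalue(median(nulls), nulls, "greater"), 0.5,
               tolerance = 0.05)
})

test_that("bootstrap test wires scoring, nulls and the estimator together", {
  ds <- simulate_coactivation(synthetic_spec(
    n_samples = 120, n_genes = 600, rho = 0.9, beta = 1.5, seed = 10))
  x <- vst_log_transform(ds$counts)
  res <- bootstrap_null_test(x, ds$signature_a, ds$signature_b,
                             B = 300, seed = 2)
  expect_length(res$null_rs, 300L)
  expect_true(all(abs(res$null_rs) <= 1))
  expect_identical(res$set_size, 24L)
  expect_gte(res$p_empirical, 1 / 301)
  expect_lte(res$p_empirical, 1)
  # a strongly planted coactivation should beat nearly every random set
  expect_lt(res$p_empirical, 0.05)
  expect_error(bootstrap_null_test(x, ds$signature_a, ds$signature_b, B = 0),
               "B")
})

test_that("bootstrap verdict is invariant to global affine rescaling of expression", {
  ds <- simulate_coactivation(synthetic_spec(
    n_samples = 40, n_genes = 300, rho = 0.5, beta = 1, seed = 6))
  x <- vst_log_transform(ds$counts)
  x2 <- expr_matrix(2 * as.matrix(x) + 3, scale = "normalized_log")
  r1 <- bootstrap_null_test(x, ds$signature_a, ds$signature_b, B = 100, seed = 3)
  r2 <- bootstrap_null_test(x2, ds$signature_a, ds$signature_b, B = 100, seed = 3)
  expect_equal(r1$observed_r, r2$observed_r)
  expect_equal(r1$null_rs, r2$null_rs)
  expect_identical(r1$p_empirical, r2$p_empirical)
})

test_that("null signatures scored in batch equal individually scored ones", {
  ds <- simulate_coactivation(synthetic_spec(
    n_samples = 25, n_genes = 200, seed = 12))
  x <- vst_log_transform(ds$counts)
  res <- bootstrap_null_test(x, ds$signature_a, ds$signature_b,
                             B = 20, seed = 8)
  sigs <- random_signatures(rownames(x), res$set_size, B = 20, seed = 8)
  ranked <- rank_transform(x)
  for (b in c(1, 7, 20)) {
    es_b <- enrichment_score(ranked, sigs[[b]], 0.25)
    expect_equal(res$null_rs[b],
                 cor(res$scores$reference, es_b), tolerance = 1e-12)
  }
})
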