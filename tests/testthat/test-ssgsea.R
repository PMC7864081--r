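log_mat <- function(m) {
  expr_matrix(m, gene_ids = paste0("g", seq_len(nrow(m))),
              sample_ids = paste0("s", seq_len(ncol(m))),
              scale = "normalized_log")
}

test_that("rank transform ranks ascending with average ties and stable order", {
  r <- rank_transform(log_mat(matrix(c(5, 1, 3), ncol = 1)))
  expect_equal(unname(r$ranks[, 1]), c(3, 1, 2))
  expect_equal(unname(r$pos[, 1]), c(1, 3, 2))

  # full tie: all average ranks; positions broken by gene index
  r <- rank_transform(log_mat(matrix(c(7, 7, 7), ncol = 1)))
  expect_equal(unname(r$ranks[, 1]), c(2, 2, 2))
  expect_equal(unname(r$pos[, 1]), c(1, 2, 3))

  # strictly increasing transform of a tie-free sample changes nothing
  v <- c(2.5, 0.1, 9, 4)
  r1 <- rank_transform(log_mat(matrix(v, ncol = 1)))
  r2 <- rank_transform(log_mat(matrix(exp(v), ncol = 1)))
  expect_identical(r1$ranks, r2$ranks)
  expect_identical(r1$pos, r2$pos)
})

test_that("a single top-ranked gene scores exactly N/2 for any alpha", {
  for (n in c(3, 10, 100)) {
    for (alpha in c(0, 0.25, 1, 2)) {
      v <- seq_len(n)  # gene n has the top value
      ranked <- rank_transform(log_mat(matrix(v, ncol = 1)))
      es <- enrichment_score(ranked, gene_signature("top", paste0("g", n)),
                             alpha = alpha)
      expect_equal(unname(es), n / 2, tolerance = 1e-12)
    }
  }
})

test_that("a bottom-concentrated signature scores negative", {
  ranked <- rank_transform(log_mat(matrix(1:20, ncol = 1)))
  es <- enrichment_score(ranked, gene_signature("bottom", "g1"))
  expect_lt(unname(es), 0)
})

test_that("six-gene toy sample matches the position-by-position oracle", {
  v <- c(3.2, 0.5, 7.1, 2.2, 5.0, 1.1)
  ranked <- rank_transform(log_mat(matrix(v, ncol = 1)))
  sig_idx <- c(3, 4)  # |S| = 2
  es <- enrichment_score(ranked, gene_signature("s", c("g3", "g4")),
                         alpha = 0.25)
  expect_equal(unname(es), es_oracle(v, sig_idx, 0.25), tolerance = 1e-12)
})

test_that("degenerate signatures are rejected", {
  ranked <- rank_transform(log_mat(matrix(1:5, ncol = 1)))
  expect_error(enrichment_score(ranked, gene_signature("s", "absent")),
               "no genes")
  expect_error(enrichment_score(ranked, gene_signature("s", paste0("g", 1:5))),
               "every gene")
})

test_that("scores obey the telescoping bound and the shift property", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      v <- rnorm(n)
      k <- sample(seq_len(n - 1), 1)
      idx <- sample(n, k)
      ranked <- rank_transform(log_mat(matrix(v, ncol = 1)))
      sig <- gene_signature("s", paste0("g", idx))
      es <- enrichment_score(ranked, sig, alpha = 0.25)
      expect_lte(abs(unname(es)), n - 1)
      # adding a sample-wide constant changes nothing
      es2 <- enrichment_score(rank_transform(log_mat(matrix(v + 3.7, ncol = 1))),
                              sig, alpha = 0.25)
      expect_identical(es, es2)
    }
  })
})

test_that("score_matrix is deterministic, column-consistent and range-normalized", {
  x <- random_log_matrix(50, 4, seed = 6)
  m <- as.matrix(x)
  m[, 4] <- m[, 3]  # two identical samples
  x <- expr_matrix(m, scale = "normalized_log")
  sigs <- list(gene_signature("a", paste0("g", 1:6)),
               gene_signature("b", paste0("g", 10:29)))
  sc <- score_matrix(x, sigs, normalize = FALSE)
  expect_identical(sc$scores[, 3], sc$scores[, 4], ignore_attr = TRUE)
  expect_identical(dim(sc$scores), c(2L, 4L))

  scn <- score_matrix(x, sigs, normalize = TRUE)
  expect_equal(max(scn$scores) - min(scn$scores), 1)
  # normalization is a global rescale: correlations are unaffected
  expect_equal(cor(sc$scores[1, ], sc$scores[2, ]),
               cor(scn$scores[1, ], scn$scores[2, ]))
})

test_that("batch scoring equals individually scored signatures", {
  x <- random_log_matrix(80, 6, seed = 13)
  ranked <- rank_transform(x)
  sigs <- withr::with_seed(3, lapply(1:10, function(i)
    gene_signature(paste0("s", i), paste0("g", sample(80, 12)))))
  batch <- score_matrix(x, sigs, normalize = FALSE)
  for (i in seq_along(sigs)) {
    expect_equal(unname(batch$scores[i, ]),
                 unname(enrichment_score(ranked, sigs[[i]], 0.25)),
                 tolerance = 1e-12)
  }
})

test_that("signature coverage policy warns on drops and errors below threshold", {
  x <- random_log_matrix(30, 3, seed = 1)
  mostly <- gene_signature("mostly", c(paste0("g", 1:9), "MISSING1"))
  expect_warning(sc <- score_matrix(x, mostly, normalize = FALSE,
                                    min_coverage = 0.8),
                 "MISSING1")
  expect_identical(sc$coverage$n_genes, 9L)
  sparse <- gene_signature("sparse", c("g1", "g2", "NO1", "NO2", "NO3"))
  expect_error(score_matrix(x, sparse, min_coverage = 0.8), "sparse")
})

test_that("gene matching is case-insensitive", {
  x <- random_log_matrix(20, 2, seed = 2)
  ranked <- rank_transform(x)
  a <- enrichment_score(ranked, gene_signature("s", c("g1", "g5")))
  b <- enrichment_score(ranked, gene_signature("s", c("G1", "G5")))
  expect_identical(a, b)
})

test_that("kernel-CDF transform is a within-gene increasing map with sane output", {
  x <- random_log_matrix(15, 8, seed = 21)
  k <- kernel_cdf_transform(x)
  expect_true(all(as.matrix(k) > 0 & as.matrix(k) < 1))
  # strictly increasing within each gene: cross-sample order preserved
  for (g in 1:15) {
    expect_identical(order(as.matrix(x)[g, ]), order(as.matrix(k)[g, ]))
  }
  # constant gene maps to a flat 0.5
  m <- as.matrix(x); m[1, ] <- 2
  kc <- kernel_cdf_transform(expr_matrix(m, scale = "normalized_log"))
  expect_equal(unname(as.matrix(kc)[1, ]), rep(0.5, 8))
})
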