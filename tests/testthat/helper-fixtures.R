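# Brute-force ssGSEA oracle: materializes both ECDFs position by position
# while walking genes in decreasing-expression order, exactly as the
# statistic is defined. Deliberately independent of the package's
# telescoped closed form.
es_oracle <- function(x, sig_idx, alpha) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(-x, seq_along(x))
  inset <- seq_along(x) %in% sig_idx
  in_ord <- inset[ord]
  w_ord <- (r[ord]^alpha) * in_ord
  p_in <- cumsum(w_ord) / sum(w_ord)
  p_out <- cumsum(!in_ord) / (n - sum(inset))
  sum(p_in - p_out)
}

# gene-by-sample matrix with distinct values (tie-free), stamped as
# normalized_log so it can feed rank_transform directly
random_log_matrix <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n_genes * n_samples, 0, 12), n_genes, n_samples)
  })
  expr_matrix(m, gene_ids = paste0("g", seq_len(n_genes)),
              sample_ids = paste0("s", seq_len(n_samples)),
              scale = "normalized_log")
}

toy_counts <- function() {
  m <- matrix(c(10L, 20L, 5L, 100L,
                20L, 40L, 10L, 200L,
                30L, 60L, 15L, 300L), nrow = 4)
  expr_matrix(m, gene_ids = paste0("g", 1:4), sample_ids = paste0("s", 1:3),
              scale = "raw_counts")
}
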