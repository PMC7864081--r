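#' Within-sample rank transform
#'
#' ssGSEA operates on within-sample expression ranks. For each sample,
#' genes are ranked ascending (rank 1 = lowest, rank N = highest
#' expression) with ties receiving average ranks, and a decreasing-
#' expression gene order is derived from the same values with ties broken
#' deterministically by ascending gene index.
#'
#' @param x An [expr_matrix()] on the `normalized_log` scale with >= 2 genes.
#' @return A `ranked_expr` object: list with `ranks` (gene-by-sample matrix
#'   of ascending ranks), `pos` (gene-by-sample matrix of positions in the
#'   decreasing-expression walk; position 1 = highest expressed),
#'   `gene_ids`, `sample_ids`, `n_genes`.
#' @export
rank_transform <- function(x) {
  .check_scale(x, "normalized_log")
  m <- as.matrix(x)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 genes to rank", call. = FALSE)
  ranks <- apply(m, 2, rank, ties.method = "average")
  pos <- apply(m, 2, function(v) {
    ord <- order(-v, seq_along(v))  # decreasing value, ties by gene index
    p <- integer(length(v))
    p[ord] <- seq_along(v)
    p
  })
  dimnames(ranks) <- dimnames(pos) <- dimnames(m)
  structure(list(ranks = ranks, pos = pos, gene_ids = rownames(m),
                 sample_ids = colnames(m), n_genes = n),
            class = "ranked_expr")
}

# Map signature genes into the ranked universe (case-insensitive).
# Returns integer row indices of the genes found.
.match_signature <- function(signature, gene_ids) {
  stopifnot(inherits(signature, "gene_signature"))
  match(toupper(signature$genes), toupper(gene_ids))
}

# Closed-form ssGSEA statistic. Walking genes in decreasing-expression
# order i = 1..N, ES = sum_i [Pin_w(i) - Pout(i)] with the weighted in-set
# ECDF Pin_w and the unweighted out-of-set ECDF Pout. Summing the step
# functions over positions telescopes to sums over genes: a gene at
# position p contributes to every partial sum from p to N, i.e. with
# multiplicity t = N - p + 1. Hence
#   ES = sum_{g in S} w_g t_g / W  -  (N(N+1)/2 - sum_{g in S} t_g) / (N - |S|)
# with w_g = rank_g^alpha and W = sum_{g in S} w_g. `idx` indexes the
# in-universe signature genes; single-sample helper used by the exported
# functions below.
.es_closed_form <- function(ranks_j, pos_j, idx, alpha) {
  n <- length(ranks_j)
  k <- length(idx)
  t_all_sum <- n * (n + 1) / 2
  w <- ranks_j[idx]^alpha
  t_in <- n - pos_j[idx] + 1
  sum(w * t_in) / sum(w) - (t_all_sum - sum(t_in)) / (n - k)
}

#' ssGSEA enrichment score
#'
#' The single-sample GSEA statistic for one signature: the integrated
#' difference between the rank-weighted ECDF of the signature genes and the
#' unweighted ECDF of the remaining genes, accumulated while walking genes
#' from highest to lowest expression. Positive scores mean the signature
#' genes concentrate among the sample's most highly expressed genes. In-set
#' weights are `rank^alpha` with the conventional default `alpha = 0.25`.
#'
#' @param ranked A `ranked_expr` from [rank_transform()].
#' @param signature A [gene_signature()]; genes absent from the matrix are
#'   ignored here (coverage policy lives in [score_matrix()]), but the
#'   in-matrix intersection must be non-empty and must not cover all genes.
#' @param alpha Non-negative rank-weighting exponent.
#' @return Named numeric vector of scores, one per sample. `|ES| <= N - 1`.
#' @export
enrichment_score <- function(ranked, signature, alpha = 0.25) {
  stopifnot(inherits(ranked, "ranked_expr"), alpha >= 0)
  idx <- .match_signature(signature, ranked$gene_ids)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L)
    stop("signature '", signature$name,
         "' has no genes in the expression matrix", call. = FALSE)
  if (length(idx) >= ranked$n_genes)
    stop("signature '", signature$name,
         "' covers every gene; the out-of-set ECDF is undefined", call. = FALSE)
  es <- vapply(seq_along(ranked$sample_ids), function(j) {
    .es_closed_form(ranked$ranks[, j], ranked$pos[, j], idx, alpha)
  }, numeric(1))
  stats::setNames(es, ranked$sample_ids)
}

# Batch scorer: ES for many signatures at once via sparse membership
# algebra; numerically the same closed form as .es_closed_form.
# idx_list: list of integer index vectors (all length >= 1, < n_genes).
# Returns a length(idx_list) x n_samples matrix.
.es_batch <- function(ranked, idx_list, alpha) {
  n <- ranked$n_genes
  b <- length(idx_list)
  ii <- rep.int(seq_len(b), lengths(idx_list))
  memb <- Matrix::sparseMatrix(i = ii, j = unlist(idx_list), x = 1,
                               dims = c(b, n))
  w <- ranked$ranks^alpha
  t_in <- n - ranked$pos + 1
  num <- as.matrix(memb %*% (w * t_in))
  den <- as.matrix(memb %*% w)
  tsum <- as.matrix(memb %*% t_in)
  k <- lengths(idx_list)
  t_all_sum <- n * (n + 1) / 2
  num / den - (t_all_sum - tsum) / (n - k)
}

#' Gaussian-kernel CDF transform
#'
#' Optional pre-ranking step: each gene's values are replaced by a
#' Gaussian-kernel estimate of their cross-sample CDF,
#' \eqn{\hat F(x_{ij}) = n^{-1}\sum_k \Phi((x_{ij} - x_{ik})/h_i)} with
#' bandwidth \eqn{h_i = sd_i/4}. Within a gene this is strictly increasing,
#' but it reweights genes against each other and therefore changes
#' within-sample ranks; it is exposed as an explicit opt-in
#' (`kernel_cdf = TRUE` in [score_matrix()]) rather than a default.
#'
#' @param x An [expr_matrix()] on the `normalized_log` scale.
#' @return An [expr_matrix()] of values in (0, 1), `normalized_log` scale.
#' @export
kernel_cdf_transform <- function(x) {
  .check_scale(x, "normalized_log")
  m <- as.matrix(x)
  out <- t(apply(m, 1, function(v) {
    h <- stats::sd(v) / 4
    if (!is.finite(h) || h == 0) return(rep(0.5, length(v)))
    colMeans(stats::pnorm(outer(v, v, function(a, b) (b - a) / h)))
  }))
  expr_matrix(out, gene_ids = rownames(m), sample_ids = colnames(m),
              scale = "normalized_log")
}

#' Score a set of signatures across all samples
#'
#' Computes the [enrichment_score()] of each signature in each sample.
#' Signature genes missing from the matrix are dropped with a warning, but
#' a signature retaining fewer than `min_coverage` of its genes is an
#' error. With `normalize = TRUE` (the ssGSEA convention) all scores are
#' divided by the global score range; downstream Pearson correlations are
#' invariant to this global affine step.
#'
#' @param x An [expr_matrix()] on the `normalized_log` scale.
#' @param signatures A [gene_signature()] or list of them.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide all scores by (global max - global min)?
#' @param min_coverage Minimum fraction of each signature's genes that must
#'   be present in the matrix (default 0.8).
#' @param kernel_cdf Apply [kernel_cdf_transform()] before ranking?
#' @return An `es_matrix` object: list with `scores`
#'   (signature-by-sample matrix), `signature_names`, `sample_ids`,
#'   `alpha`, `normalized`, `kernel_cdf`, and `coverage` (data frame of
#'   per-signature gene counts and dropped genes).
#' @export
score_matrix <- function(x, signatures, alpha = 0.25, normalize = TRUE,
                         min_coverage = 0.8, kernel_cdf = FALSE) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  stopifnot(length(signatures) >= 1L, alpha >= 0,
            min_coverage >= 0, min_coverage <= 1)
  if (kernel_cdf) x <- kernel_cdf_transform(x)
  ranked <- rank_transform(x)
  nms <- vapply(signatures, `[[`, character(1), "name")
  idx_list <- vector("list", length(signatures))
  dropped <- character(length(signatures))
  for (s in seq_along(signatures)) {
    idx <- .match_signature(signatures[[s]], ranked$gene_ids)
    miss <- is.na(idx)
    cov <- mean(!miss)
    if (cov < min_coverage)
      stop("signature '", nms[s], "' retains ", round(100 * cov), "% of its ",
           "genes (< ", round(100 * min_coverage), "%); missing: ",
           paste(signatures[[s]]$genes[miss], collapse = ", "), call. = FALSE)
    if (any(miss))
      warning("signature '", nms[s], "': dropping ", sum(miss),
              " gene(s) absent from the matrix: ",
              paste(signatures[[s]]$genes[miss], collapse = ", "),
              call. = FALSE)
    if (sum(!miss) >= ranked$n_genes)
      stop("signature '", nms[s], "' covers every gene", call. = FALSE)
    idx_list[[s]] <- idx[!miss]
    dropped[s] <- paste(signatures[[s]]$genes[miss], collapse = ",")
  }
  scores <- .es_batch(ranked, idx_list, alpha)
  dimnames(scores) <- list(nms, ranked$sample_ids)
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(list(scores = scores, signature_names = nms,
                 sample_ids = ranked$sample_ids, alpha = alpha,
                 normalized = normalize, kernel_cdf = kernel_cdf,
                 coverage = data.frame(
                   signature = nms,
                   n_genes = lengths(idx_list),
                   n_dropped = vapply(dropped, function(d)
                     if (nzchar(d)) length(strsplit(d, ",")[[1]]) else 0L,
                     integer(1), USE.NAMES = FALSE),
                   dropped = dropped)),
            class = "es_matrix")
}

#' @export
print.es_matrix <- function(x, ...) {
  cat("ssGSEA scores: ", nrow(x$scores), " signature(s) x ",
      ncol(x$scores), " samples (alpha = ", x$alpha,
      if (x$normalized) ", range-normalized" else "", ")\n", sep = "")
  invisible(x)
}
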