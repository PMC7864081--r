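#' Pearson correlation with a regression fit and 95% confidence band
#'
#' Correlates two pathway-activity vectors across samples and fits the
#' ordinary least-squares line of `y` on `x`, with the pointwise 95%
#' confidence band of the fitted mean from the t distribution on n - 2
#' degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return A `correlation_result` list: `r`, `n`, `slope`, `intercept`, and
#'   `ci95_band` (data frame `x`, `fit`, `lwr`, `upr`, ordered by `x`).
#' @examples
#' pearson_correlation(1:5, c(2, 1, 4, 3, 6))$r
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need n >= 3 samples", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  ord <- order(x)
  band <- stats::predict(fit, newdata = data.frame(x = x[ord]),
                         interval = "confidence", level = 0.95)
  structure(list(
    r = stats::cor(x, y), n = n,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    ci95_band = data.frame(x = x[ord], fit = band[, "fit"],
                           lwr = band[, "lwr"], upr = band[, "upr"])
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d); fit y = %.4f x + %.4f\n",
              x$r, x$n, x$slope, x$intercept))
  invisible(x)
}

#' Draw random size-matched gene signatures
#'
#' Each of the `B` signatures is a uniform without-replacement draw of
#' `set_size` genes from `universe` (optionally minus the genes of
#' `exclude`); draws are independent across signatures and fully
#' reproducible from `seed`.
#'
#' @param universe Character vector of candidate gene identifiers.
#' @param set_size Genes per random signature.
#' @param B Number of signatures (>= 1).
#' @param seed Integer seed.
#' @param exclude Optional [gene_signature()] whose genes are removed from
#'   the candidate pool (case-insensitive).
#' @return List of `B` [gene_signature()] objects named `random_0001`, ...
#' @export
random_signatures <- function(universe, set_size, B, seed, exclude = NULL) {
  universe <- as.character(universe)
  if (!is.null(exclude)) {
    stopifnot(inherits(exclude, "gene_signature"))
    universe <- universe[!(toupper(universe) %in% toupper(exclude$genes))]
  }
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (length(universe) < set_size)
    stop("universe (", length(universe), " genes after exclusions) smaller ",
         "than set_size = ", set_size, call. = FALSE)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(B), function(b) {
      gene_signature(sprintf("random_%04d", b), sample(universe, set_size))
    })
  })
}

#' Add-one empirical p-value
#'
#' The positively biased permutation estimator
#' `p = (1 + #\{b : T(null_b) >= T(obs)\}) / (1 + B)`, with `T(r) = |r|`
#' for a two-sided test and `T(r) = r` for a one-sided (greater) test.
#' The estimator never returns 0: its floor is `1 / (1 + B)`.
#'
#' @param observed Observed statistic.
#' @param nulls Numeric vector of B null statistics.
#' @param sidedness `"greater"` or `"two_sided"`.
#' @return The empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, nulls,
                             sidedness = c("greater", "two_sided")) {
  sidedness <- match.arg(sidedness)
  tf <- if (sidedness == "two_sided") abs else identity
  (1 + sum(tf(nulls) >= tf(observed))) / (1 + length(nulls))
}

#' Bootstrap null test of pathway coactivation
#'
#' Tests whether the cross-sample correlation between the activities of a
#' reference and a target signature exceeds what random size-matched gene
#' signatures produce. The reference and target are ssGSEA-scored, their
#' Pearson correlation is the observed statistic, and the null
#' distribution is the correlation of the reference scores with each of
#' `B` random signatures of `set_size` genes drawn from the matrix's gene
#' universe. Significance is the add-one empirical p-value
#' ([empirical_pvalue()]), one-sided (`greater`) by default since the
#' hypothesis of interest is positive coactivation.
#'
#' Reference scores are computed once and reused across all B null
#' correlations (exact, and B-fold faster). Scores enter the correlations
#' unnormalized; Pearson r is invariant to the global range normalization,
#' so this choice cannot affect the result.
#'
#' @param x An [expr_matrix()] on the `normalized_log` scale.
#' @param reference,target [gene_signature()] objects (e.g. the built-in
#'   G12/13 and YAP/TAZ signatures).
#' @param B Number of random signatures (default 10000).
#' @param seed Integer seed for the null draws.
#' @param set_size Random-signature size; defaults to the target's size in
#'   the matrix.
#' @param alpha ssGSEA weighting exponent.
#' @param sidedness `"greater"` (default) or `"two_sided"`.
#' @param exclude Optional [gene_signature()] removed from the random-draw
#'   pool (sensitivity analysis; the default pool is all matrix genes).
#' @param kernel_cdf Apply the kernel-CDF pre-transform before ranking?
#' @param min_coverage Coverage threshold passed to [score_matrix()].
#' @return A `bootstrap_null_result` list: `observed_r`, `null_rs` (length
#'   B), `B`, `set_size`, `seed`, `p_empirical`, `sidedness`, plus the
#'   observed [pearson_correlation()] fit in `$correlation` and the
#'   reference/target score vectors in `$scores`.
#' @export
bootstrap_null_test <- function(x, reference, target, B = 10000L, seed = 1L,
                                set_size = NULL, alpha = 0.25,
                                sidedness = c("greater", "two_sided"),
                                exclude = NULL, kernel_cdf = FALSE,
                                min_coverage = 0.8) {
  sidedness <- match.arg(sidedness)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  obs <- score_matrix(x, list(reference, target), alpha = alpha,
                      normalize = FALSE, min_coverage = min_coverage,
                      kernel_cdf = kernel_cdf)
  ref_scores <- obs$scores[1, ]
  tgt_scores <- obs$scores[2, ]
  if (is.null(set_size)) set_size <- obs$coverage$n_genes[2]
  corr <- pearson_correlation(ref_scores, tgt_scores)

  if (kernel_cdf) x <- kernel_cdf_transform(x)
  ranked <- rank_transform(x)
  sigs <- random_signatures(ranked$gene_ids, set_size = set_size, B = B,
                            seed = seed, exclude = exclude)
  idx_list <- lapply(sigs, function(s) .match_signature(s, ranked$gene_ids))
  null_scores <- .es_batch(ranked, idx_list, alpha)
  null_rs <- as.numeric(stats::cor(ref_scores, t(null_scores)))

  structure(list(
    observed_r = corr$r, null_rs = null_rs, B = as.integer(B),
    set_size = as.integer(set_size), seed = as.integer(seed),
    p_empirical = empirical_pvalue(corr$r, null_rs, sidedness),
    sidedness = sidedness, correlation = corr,
    scores = list(reference = ref_scores, target = tgt_scores),
    settings = list(alpha = alpha, kernel_cdf = kernel_cdf,
                    min_coverage = min_coverage,
                    excluded = if (is.null(exclude)) NULL else exclude$name)
  ), class = "bootstrap_null_result")
}

#' @export
print.bootstrap_null_result <- function(x, ...) {
  cat(sprintf(
    "Coactivation test: observed r = %.4f, p = %.3g (%s; B = %d random %d-gene signatures)\n",
    x$observed_r, x$p_empirical, x$sidedness, x$B, x$set_size))
  invisible(x)
}
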