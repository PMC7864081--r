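#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth normalizers: for each sample the median,
#' over reference genes, of the ratio between the sample's count and the
#' gene's geometric mean across samples. Reference genes are those with
#' strictly positive counts in every sample (the geometric mean is zero
#' otherwise). Factors are rescaled to have geometric mean 1, which makes
#' them identifiable and the all-identical-columns case exactly 1.
#'
#' @param counts An [expr_matrix()] of raw counts with >= 2 samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  .check_scale(counts, "raw_counts")
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  m <- as.matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no gene has positive counts in every sample; ",
         "pre-filter the matrix (see filter_low_expression)", call. = FALSE)
  log_geo <- rowMeans(log(m[ref, , drop = FALSE]))
  f <- apply(log(m[ref, , drop = FALSE]) - log_geo, 2, stats::median)
  f <- exp(f - mean(f))  # geometric mean 1
  stats::setNames(f, colnames(m))
}

#' Depth-normalized log transform
#'
#' Converts raw counts to `log2(count / size_factor + 1)`, a
#' variance-compressing log scale suitable for rank-based scoring. The
#' pseudo-count of 1 keeps zeros at zero. Because downstream ssGSEA ranks
#' genes within each sample, any strictly increasing per-sample map yields
#' identical scores; this transform's role is comparability and sane
#' intermediate values, not the final statistic.
#'
#' @param counts An [expr_matrix()] of raw counts.
#' @return An [expr_matrix()] on the `normalized_log` scale, same
#'   dimensions and identifiers.
#' @export
vst_log_transform <- function(counts) {
  f <- size_factors(counts)
  m <- sweep(as.matrix(counts), 2, f, "/")
  expr_matrix(log2(m + 1), gene_ids = rownames(counts),
              sample_ids = colnames(counts), scale = "normalized_log")
}

#' Drop genes with insufficient expression
#'
#' Keeps genes observed at `count >= min_count` in at least `min_fraction`
#' of samples; gene order is preserved. With the defaults this removes
#' genes detected in fewer than 20% of samples.
#'
#' @param counts An [expr_matrix()] of raw counts.
#' @param min_count Minimum count to call a gene detected in a sample.
#' @param min_fraction Minimum fraction of samples with detection.
#' @return The filtered [expr_matrix()].
#' @export
filter_low_expression <- function(counts, min_count = 1L, min_fraction = 0.2) {
  .check_scale(counts, "raw_counts")
  stopifnot(min_count >= 0, min_fraction >= 0, min_fraction <= 1)
  m <- as.matrix(counts)
  keep <- rowMeans(m >= min_count) >= min_fraction
  if (!any(keep)) stop("filter removed all genes", call. = FALSE)
  expr_matrix(m[keep, , drop = FALSE], scale = "raw_counts")
}
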