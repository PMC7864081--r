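#' Translate gene identifiers of an expression matrix
#'
#' Applies a two-column identifier mapping (source -> target, e.g. Ensembl
#' ID -> HGNC symbol) to the matrix's gene identifiers. Rows whose source
#' has no mapping are dropped (count reported via `message()`). When
#' several source rows map to the same target, the row with the highest
#' total count is kept — the common expression-matrix collapse convention.
#'
#' @param x An [expr_matrix()].
#' @param mapping Two-column data frame (source, target) or path to a
#'   headerless two-column TSV. Source identifiers must be unique.
#' @return An [expr_matrix()] with translated gene identifiers.
#' @export
map_gene_ids <- function(x, mapping) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE,
                                 col.names = c("source", "target"))
  stopifnot(is.data.frame(mapping), ncol(mapping) >= 2L)
  src <- as.character(mapping[[1]]); tgt <- as.character(mapping[[2]])
  if (anyDuplicated(src)) stop("mapping source IDs must be unique", call. = FALSE)
  hit <- match(rownames(x), src)
  n_unmapped <- sum(is.na(hit))
  if (n_unmapped > 0)
    message("map_gene_ids: dropping ", n_unmapped, " unmapped gene row(s)")
  keep <- which(!is.na(hit))
  if (length(keep) == 0L) stop("no gene rows survive the mapping", call. = FALSE)
  m <- as.matrix(x)[keep, , drop = FALSE]
  new_ids <- tgt[hit[keep]]
  # many-to-one collisions: keep the row with the highest total count
  if (anyDuplicated(new_ids)) {
    tot <- rowSums(m)
    best <- unlist(lapply(split(seq_along(new_ids), new_ids),
                          function(i) i[which.max(tot[i])]), use.names = FALSE)
    best <- sort(best)  # preserve original row order
    message("map_gene_ids: collapsing ", length(new_ids) - length(best),
            " row(s) mapping to an already-used target")
    m <- m[best, , drop = FALSE]
    new_ids <- new_ids[best]
  }
  expr_matrix(m, gene_ids = new_ids, sample_ids = colnames(x),
              scale = expr_scale(x))
}

#' Run the full coactivation analysis
#'
#' One call from raw counts to the bootstrap verdict:
#' filter low-expression genes, depth-normalize and log-transform, ssGSEA-
#' score the two signatures, correlate their activities across samples,
#' and test the observed Pearson r against a bootstrap null of `B` random
#' size-matched signatures. Each stage logs its parameters via
#' `message()`. If `output_dir` is given, the run writes a score TSV, a
#' null-correlation TSV, a JSON summary, scatter/histogram figures, and a
#' manifest JSON recording the package version, an MD5 hash of the
#' configuration, and every tunable used.
#'
#' @param counts An [expr_matrix()] of raw counts, or path to a counts
#'   TSV/CSV readable with [read_counts()].
#' @param reference,target [gene_signature()] objects; defaults are the
#'   built-in G12/13 and YAP/TAZ signatures.
#' @param mapping Optional identifier mapping passed to [map_gene_ids()].
#' @param samples Optional character vector of sample IDs to subset to
#'   (e.g. primary tumors only).
#' @param min_count,min_fraction Low-expression filter thresholds
#'   ([filter_low_expression()]); `min_fraction = 0` disables filtering.
#' @param alpha,normalize,kernel_cdf,min_coverage Scoring options
#'   ([score_matrix()]); `normalize` affects only the emitted score table,
#'   never the test (Pearson r is invariant to it).
#' @param B,seed,set_size,sidedness,exclude Bootstrap options
#'   ([bootstrap_null_test()]).
#' @param output_dir Optional directory for result files.
#' @return The `bootstrap_null_result`, invisibly if `output_dir` is set.
#' @export
run_coactivation_pipeline <- function(counts,
                                      reference = builtin_signature("G12_13"),
                                      target = builtin_signature("YAP_TAZ"),
                                      mapping = NULL, samples = NULL,
                                      min_count = 1L, min_fraction = 0.2,
                                      alpha = 0.25, normalize = TRUE,
                                      kernel_cdf = FALSE, min_coverage = 0.8,
                                      B = 10000L, seed = 1L, set_size = NULL,
                                      sidedness = c("greater", "two_sided"),
                                      exclude = NULL, output_dir = NULL) {
  sidedness <- match.arg(sidedness)
  if (is.character(counts)) counts <- read_counts(counts)
  .check_scale(counts, "raw_counts")
  if (!is.null(mapping)) counts <- map_gene_ids(counts, mapping)
  if (!is.null(samples)) {
    keep <- colnames(counts) %in% samples
    message("subset: keeping ", sum(keep), "/", ncol(counts), " samples")
    counts <- expr_matrix(as.matrix(counts)[, keep, drop = FALSE],
                          scale = "raw_counts")
  }
  message("filter: min_count = ", min_count, ", min_fraction = ", min_fraction)
  filtered <- if (min_fraction > 0 || min_count > 0)
    filter_low_expression(counts, min_count, min_fraction) else counts
  message("filter: ", nrow(filtered), "/", nrow(counts), " genes retained")
  normed <- vst_log_transform(filtered)
  message("normalize: median-of-ratios size factors + log2(x/f + 1)")
  result <- bootstrap_null_test(normed, reference, target, B = B, seed = seed,
                                set_size = set_size, alpha = alpha,
                                sidedness = sidedness, exclude = exclude,
                                kernel_cdf = kernel_cdf,
                                min_coverage = min_coverage)
  message(sprintf("test: observed r = %.4f, empirical p = %.3g (B = %d)",
                  result$observed_r, result$p_empirical, result$B))
  if (is.null(output_dir)) return(result)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  scored <- score_matrix(normed, list(reference, target), alpha = alpha,
                         normalize = normalize, min_coverage = min_coverage,
                         kernel_cdf = kernel_cdf)
  utils::write.table(
    data.frame(signature = rownames(scored$scores), scored$scores,
               check.names = FALSE),
    file.path(output_dir, "scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(null_r = result$null_rs),
                     file.path(output_dir, "null_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(observed_r = result$observed_r,
                  p_empirical = result$p_empirical,
                  B = result$B, set_size = result$set_size,
                  seed = result$seed, alpha = alpha,
                  sidedness = sidedness)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- list(min_count = min_count, min_fraction = min_fraction,
                 alpha = alpha, normalize = normalize,
                 kernel_cdf = kernel_cdf, min_coverage = min_coverage,
                 B = B, set_size = result$set_size, seed = seed,
                 sidedness = sidedness,
                 exclude = if (is.null(exclude)) NA else exclude$name,
                 reference = reference$name, target = target$name)
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(tool = "pathcoact",
                   version = as.character(utils::packageVersion("pathcoact")),
                   config_hash = unname(tools::md5sum(cfg_file)),
                   config = config,
                   n_samples = ncol(filtered), n_genes = nrow(filtered))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ggplot2::ggsave(file.path(output_dir, "coactivation_scatter.png"),
                  plot_coactivation(result), width = 5, height = 4, dpi = 150)
  ggplot2::ggsave(file.path(output_dir, "null_distribution.png"),
                  plot_null_distribution(result), width = 5, height = 4,
                  dpi = 150)
  message("wrote results to ", output_dir)
  invisible(result)
}

#' Scatter plot of pathway activities with the regression fit
#'
#' Reference-signature scores on the x axis, target scores on the y axis,
#' the least-squares line, and its pointwise 95% confidence band.
#'
#' @param result A `bootstrap_null_result`.
#' @return A ggplot object.
#' @export
plot_coactivation <- function(result) {
  stopifnot(inherits(result, "bootstrap_null_result"))
  df <- data.frame(x = as.numeric(result$scores$reference),
                   y = as.numeric(result$scores$target))
  band <- result$correlation$ci95_band
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$lwr,
                                      ymax = .data$upr),
                         inherit.aes = FALSE, fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::labs(x = "reference pathway activity (ssGSEA)",
                  y = "target pathway activity (ssGSEA)",
                  subtitle = sprintf("Pearson r = %.3f (n = %d)",
                                     result$observed_r, result$correlation$n)) +
    ggplot2::theme_classic()
}

#' Histogram of the bootstrap null with the observed correlation
#'
#' @param result A `bootstrap_null_result`.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(result) {
  stopifnot(inherits(result, "bootstrap_null_result"))
  df <- data.frame(r = result$null_rs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(xintercept = result$observed_r, linetype = "dashed") +
    ggplot2::labs(x = sprintf("null correlation (B = %d random %d-gene signatures)",
                              result$B, result$set_size),
                  y = "count",
                  subtitle = sprintf("observed r = %.3f, empirical p = %.3g",
                                     result$observed_r, result$p_empirical)) +
    ggplot2::theme_classic()
}
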