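#' Specify a synthetic coactivation cohort
#'
#' Parameters for an RNA-seq-like count cohort containing two planted gene
#' modules whose per-sample activities are drawn from a standard bivariate
#' normal with correlation `rho`. The generator emulates the statistical
#' structure the coactivation analysis assumes in real tumor cohorts:
#' overdispersed negative-binomial counts, variable sequencing depth, and a
#' large background of genes unrelated to either module.
#'
#' Gene g of module M in sample j has mean
#' \deqn{\mu_{gj} = s_j \exp(m_g + \beta a_{Mj})}
#' where \eqn{m_g} is a per-gene baseline log-mean drawn uniformly over
#' `base_mean_log_range`, \eqn{s_j} a log-normal library-size factor with
#' log-sd `libsize_log_sd`, and \eqn{a_{Mj}} the sample's latent activity of
#' module M. Background genes have \eqn{\beta = 0}. Counts are negative
#' binomial with variance \eqn{\mu + \alpha\mu^2} for dispersion
#' \eqn{\alpha =} `dispersion`.
#'
#' Defaults mirror the study conditions of the analysis this package
#' rehearses: a ~400-tumor cohort, an 8-gene and a 24-gene signature, and a
#' strong planted coactivation (`rho = 0.7`).
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param size_a,size_b Planted module sizes (defaults 8 and 24, matching
#'   the built-in G12/13 and YAP/TAZ signature sizes).
#' @param rho Latent activity correlation in \[-1, 1\].
#' @param beta Log-scale effect size (>= 0) linking latent activity to
#'   module-gene means.
#' @param base_mean_log_range Interval (natural-log scale) for baseline
#'   per-gene log-means; default `log(5)` to `log(500)`.
#' @param dispersion NB dispersion alpha > 0 (variance mu + alpha mu^2).
#' @param libsize_log_sd Log-sd (>= 0) of library-size factors.
#' @param seed Integer seed; same spec implies bit-identical output.
#' @return A `synthetic_spec` list.
#' @seealso [simulate_coactivation()]
#' @export
synthetic_spec <- function(n_samples = 400L, n_genes = 5000L,
                           size_a = 8L, size_b = 24L,
                           rho = 0.7, beta = 1,
                           base_mean_log_range = c(log(5), log(500)),
                           dispersion = 0.2, libsize_log_sd = 0.3,
                           seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               size_a = as.integer(size_a), size_b = as.integer(size_b),
               rho = rho, beta = beta,
               base_mean_log_range = as.numeric(base_mean_log_range),
               dispersion = dispersion, libsize_log_sd = libsize_log_sd,
               seed = as.integer(seed))
  with(spec, {
    if (n_samples < 1L || n_genes < 1L || size_a < 1L || size_b < 1L)
      stop("sample, gene and module counts must be positive", call. = FALSE)
    if (size_a + size_b > n_genes)
      stop("module sizes exceed n_genes", call. = FALSE)
    if (!is.finite(rho) || abs(rho) > 1)
      stop("rho must lie in [-1, 1]", call. = FALSE)
    if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
    if (!is.finite(dispersion) || dispersion <= 0)
      stop("dispersion must be > 0", call. = FALSE)
    if (libsize_log_sd < 0) stop("libsize_log_sd must be >= 0", call. = FALSE)
    if (length(base_mean_log_range) != 2L ||
        base_mean_log_range[1] > base_mean_log_range[2])
      stop("base_mean_log_range must be an increasing interval", call. = FALSE)
  })
  structure(spec, class = "synthetic_spec")
}

#' Simulate a cohort with two planted coactivated modules
#'
#' Draws the cohort described by a [synthetic_spec()]. Module A occupies
#' matrix rows 1..size_a (gene IDs `MODA_*`), module B the next size_b rows
#' (`MODB_*`); the remaining rows are background (`BG_*`). The returned
#' object records the planted signatures and the latent activity vectors,
#' which serve as the ground truth the scoring pipeline should recover.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset` list with elements `counts`
#'   ([expr_matrix()], raw counts), `signature_a`, `signature_b`
#'   ([gene_signature()]), `latent_a`, `latent_b` (numeric vectors of length
#'   `n_samples`), and `spec`.
#' @examples
#' ds <- simulate_coactivation(synthetic_spec(n_samples = 50, n_genes = 200,
#'                                            seed = 7))
#' cor(ds$latent_a, ds$latent_b)
#' @export
simulate_coactivation <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop("'spec' must be a synthetic_spec", call. = FALSE)
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    g <- spec$n_genes
    # latent activities: bivariate standard normal, correlation rho
    a <- stats::rnorm(n)
    b <- spec$rho * a + sqrt(1 - spec$rho^2) * stats::rnorm(n)
    m <- stats::runif(g, spec$base_mean_log_range[1], spec$base_mean_log_range[2])
    s <- exp(stats::rnorm(n, 0, spec$libsize_log_sd))
    eff <- matrix(0, nrow = g, ncol = n)
    idx_a <- seq_len(spec$size_a)
    idx_b <- spec$size_a + seq_len(spec$size_b)
    eff[idx_a, ] <- spec$beta * matrix(a, spec$size_a, n, byrow = TRUE)
    eff[idx_b, ] <- spec$beta * matrix(b, spec$size_b, n, byrow = TRUE)
    mu <- exp(m + eff) * matrix(s, g, n, byrow = TRUE)
    counts <- matrix(stats::rnbinom(g * n, mu = mu, size = 1 / spec$dispersion),
                     nrow = g, ncol = n)
  })
  gene_ids <- c(sprintf("MODA_%d", seq_len(spec$size_a)),
                sprintf("MODB_%d", seq_len(spec$size_b)),
                sprintf("BG_%d", seq_len(spec$n_genes - spec$size_a - spec$size_b)))
  sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))
  names(a) <- names(b) <- sample_ids
  structure(list(
    counts = expr_matrix(counts, gene_ids = gene_ids, sample_ids = sample_ids,
                         scale = "raw_counts"),
    signature_a = gene_signature("module_A", gene_ids[seq_len(spec$size_a)]),
    signature_b = gene_signature("module_B",
                                 gene_ids[spec$size_a + seq_len(spec$size_b)]),
    latent_a = a, latent_b = b, spec = spec
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the counts as TSV, the two planted signatures as GMT, the latent
#' activities as TSV, and the generating parameters as a JSON sidecar.
#'
#' @param ds A `synthetic_dataset` from [simulate_coactivation()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named vector of the four file paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             signatures = file.path(dir, "planted_signatures.gmt"),
             latent = file.path(dir, "latent_activity.tsv"),
             spec = file.path(dir, "spec.json"))
  write_counts(ds$counts, paths[["counts"]])
  write_gmt(list(ds$signature_a, ds$signature_b), paths[["signatures"]])
  utils::write.table(
    data.frame(sample_id = colnames(ds$counts),
               latent_a = as.numeric(ds$latent_a),
               latent_b = as.numeric(ds$latent_b)),
    paths[["latent"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(ds$spec), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
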