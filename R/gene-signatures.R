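#' Construct a gene signature
#'
#' A gene signature is a named, order-preserving list of unique gene
#' identifiers used as a transcriptional proxy for a pathway's activity.
#' Identifiers are matched case-insensitively throughout the package, so
#' uniqueness is enforced after uppercasing (HGNC symbols are uppercase;
#' other identifier schemes can be mapped in with [map_gene_ids()]).
#'
#' @param name Short text label, non-empty.
#' @param genes Character vector of gene identifiers; order is preserved.
#' @return An object of class `gene_signature` with fields `name` and `genes`.
#' @examples
#' sig <- gene_signature("rho", c("RHOA", "RHOB", "RHOC"))
#' signature_size(sig)
#' @export
gene_signature <- function(name, genes) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  if (!is.character(genes) || length(genes) == 0L)
    stop("'genes' must be a non-empty character vector", call. = FALSE)
  if (anyNA(genes) || any(!nzchar(genes)))
    stop("gene identifiers must be non-empty strings", call. = FALSE)
  if (anyDuplicated(toupper(genes)))
    stop("duplicate gene identifiers (case-insensitive) in signature '",
         name, "'", call. = FALSE)
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @rdname gene_signature
#' @param x A `gene_signature`.
#' @export
signature_size <- function(x) {
  stopifnot(inherits(x, "gene_signature"))
  length(x$genes)
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "' (", length(x$genes), " genes)\n", sep = "")
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

# Frozen built-in gene lists. G12/13: the heterotrimeric G-proteins
# Galpha12/13, their effector RhoGEFs, and the Rho GTPases they activate.
# YAP/TAZ: the Hippo effectors plus a 24-gene transcriptional target
# signature used as a downstream activity readout.
.builtin_gene_lists <- list(
  G12_13 = c("GNA12", "GNA13", "ARHGEF1", "ARHGEF11", "ARHGEF12",
             "RHOA", "RHOB", "RHOC"),
  YAP_TAZ = c("YAP1", "WWTR1", "MYOF", "AMOTL2", "LATS2", "CTGF", "CYR61",
              "ANKRD1", "ASAP1", "AXL", "F3", "IGFBP3", "CRIM1", "FJX1",
              "FOXF2", "GADD45A", "CCDC80", "NT5E", "DOCK5", "PTPN14",
              "ARHGEF17", "NUAK2", "TGFB2", "RBMS3")
)

#' Built-in pathway signatures
#'
#' Returns one of the two signatures the coactivation analysis is built
#' around: the 8-gene G12/13 signaling cascade (`"G12_13"`) or the 24-gene
#' YAP/TAZ target signature (`"YAP_TAZ"`).
#'
#' @param which `"G12_13"` or `"YAP_TAZ"`.
#' @return A [gene_signature()].
#' @examples
#' builtin_signature("G12_13")
#' @export
builtin_signature <- function(which = c("G12_13", "YAP_TAZ")) {
  which <- match.arg(which)
  gene_signature(which, .builtin_gene_lists[[which]])
}

#' Read gene signatures from a GMT file
#'
#' Parses the Broad tab-delimited GMT dialect: one signature per line,
#' fields `name<TAB>description<TAB>gene1<TAB>gene2...`, no header. The
#' description field is discarded. Duplicate genes within a line are dropped
#' with a warning; duplicate signature names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_signature()] objects.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sigs <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields, got ",
           length(fields), call. = FALSE)
    genes <- fields[-(1:2)]
    dup <- duplicated(toupper(genes))
    if (any(dup)) {
      warning("GMT line ", i, " ('", fields[1], "'): dropping ", sum(dup),
              " duplicate gene(s): ", paste(unique(genes[dup]), collapse = ", "),
              call. = FALSE)
      genes <- genes[!dup]
    }
    sigs[[i]] <- gene_signature(fields[1], genes)
    nms[i] <- fields[1]
  }
  if (anyDuplicated(nms))
    stop("duplicate signature names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(sigs) <- nms
  sigs
}

#' Write gene signatures to a GMT file
#'
#' Inverse of [read_gmt()]: writing then reading reproduces the input
#' collection. The description column is written as `"na"`. Tabs are the
#' reserved field delimiter, so a tab inside a name or gene is an error.
#'
#' @param signatures A list of [gene_signature()] objects (may be empty).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(signatures, path) {
  stopifnot(is.list(signatures))
  lines <- vapply(signatures, function(s) {
    stopifnot(inherits(s, "gene_signature"))
    if (any(grepl("\t", c(s$name, s$genes), fixed = TRUE)))
      stop("tab character in signature '", s$name,
           "' (reserved GMT delimiter)", call. = FALSE)
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
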