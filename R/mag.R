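# RPKM/TPM normalization of mapped-count tables and MAG-level summaries.
#
# This module consumes post-filter mapped-read count tables (features are
# genes or MAGs), a feature catalog with lengths and, for genes, the parent
# MAG, and explicit per-sample mapped-library sizes. It never infers the
# library size from column sums: the features need not tile the library.

.checkCatalog <- function(counts, catalog) {
  counts <- as.matrix(counts)
  catalog <- as.data.frame(catalog)
  if (!all(c("feature_id", "length_bp") %in% names(catalog)))
    stop("catalog needs columns 'feature_id' and 'length_bp'")
  if (anyDuplicated(catalog$feature_id))
    stop("duplicated feature ids in catalog")
  idx <- match(rownames(counts), catalog$feature_id)
  if (anyNA(idx))
    stop("feature(s) missing from catalog: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5L),
               collapse = ", "))
  len <- catalog$length_bp[idx]
  if (any(len <= 0)) stop("feature lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  list(counts = counts, length_bp = len, catalog = catalog[idx, ])
}

#' RPKM normalization
#'
#' Reads per kilobase of feature per million mapped reads:
#' `RPKM = count / (length_kb * library_size_millions)`.
#'
#' @param counts Feature-by-sample matrix of mapped-read counts.
#' @param catalog `data.frame` with `feature_id`, `length_bp` (and
#'   optionally `parent_mag`).
#' @param libSizes Per-sample total mapped reads, a named vector covering
#'   every sample column (all > 0).
#' @return Matrix of RPKM values with the input dimnames.
#' @export
computeRPKM <- function(counts, catalog, libSizes) {
  ck <- .checkCatalog(counts, catalog)
  m <- ck$counts
  if (!is.null(names(libSizes))) libSizes <- libSizes[colnames(m)]
  if (length(libSizes) != ncol(m) || anyNA(libSizes))
    stop("libSizes must cover every sample")
  if (any(libSizes <= 0)) stop("library sizes must be positive")
  denom <- outer(ck$length_bp / 1e3, libSizes / 1e6)
  m / denom
}

#' TPM normalization
#'
#' Length-normalized read rates rescaled to sum to one million per sample:
#' `rate = count / length_kb; TPM = 1e6 * rate / sum(rate)`. Every sample
#' column of the result sums to exactly 1e6 (up to floating tolerance).
#'
#' @inheritParams computeRPKM
#' @return Matrix of TPM values.
#' @export
computeTPM <- function(counts, catalog) {
  ck <- .checkCatalog(counts, catalog)
  rate <- ck$counts / (ck$length_bp / 1e3)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(ck$counts)[tot == 0], collapse = ", "))
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Relative abundance across MAGs
#'
#' Expresses each MAG's RPKM or TPM value as a percentage of the summed
#' values of all MAGs in the same sample. Invariant to uniform rescaling of
#' the input values.
#'
#' @param values MAG-by-sample matrix of RPKM or TPM values.
#' @return Matrix of percentages; each column sums to 100.
#' @export
magRelativeAbundance <- function(values) {
  values <- as.matrix(values)
  tot <- colSums(values)
  if (any(tot == 0))
    stop("zero summed value in sample(s): ",
         paste(colnames(values)[tot == 0], collapse = ", "))
  sweep(values, 2L, tot, "/") * 100
}

#' Top expressed genes of a MAG
#'
#' Ranks the genes of one MAG by TPM, descending, with ties broken by
#' lexicographic gene id, and returns the top `n` (all genes when the MAG
#' has fewer than `n`). With several samples the ranking statistic is the
#' mean (default) or maximum TPM across samples. Lists are per-MAG: the
#' same gene family appearing in several MAGs is reported once per MAG,
#' never merged across MAGs.
#'
#' @param tpm Gene-by-sample TPM matrix (from [computeTPM()]).
#' @param catalog Catalog with `feature_id` and `parent_mag`.
#' @param mag MAG label to report.
#' @param n Number of genes (default 10).
#' @param statistic `"mean"` or `"max"` across samples.
#' @return `data.frame` with `gene_id`, `mag`, `tpm` (the ranking
#'   statistic) and `rank`.
#' @export
topExpressedGenes <- function(tpm, catalog, mag, n = 10,
                              statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  catalog <- as.data.frame(catalog)
  if (!"parent_mag" %in% names(catalog))
    stop("catalog needs a 'parent_mag' column")
  genes <- catalog$feature_id[catalog$parent_mag == mag]
  genes <- intersect(rownames(tpm), genes)
  if (length(genes) == 0L) stop("MAG '", mag, "' has no genes")
  sub <- tpm[genes, , drop = FALSE]
  score <- if (statistic == "mean") rowMeans(sub) else
    apply(sub, 1L, max)
  ord <- order(-score, genes)
  top <- utils::head(ord, n)
  data.frame(gene_id = genes[top], mag = mag, tpm = unname(score[top]),
             rank = seq_along(top), stringsAsFactors = FALSE)
}

#' Highly transcribed MAGs
#'
#' Flags MAGs whose TPM reaches `threshold` (default 1000) in at least one
#' sample -- the working definition of a MAG with relatively high
#' transcription.
#'
#' @param tpm MAG-by-sample TPM matrix.
#' @param threshold TPM cutoff (default 1000).
#' @return Character vector of MAG ids.
#' @export
highlyTranscribedMags <- function(tpm, threshold = 1000) {
  tpm <- as.matrix(tpm)
  rownames(tpm)[apply(tpm >= threshold, 1L, any)]
}
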