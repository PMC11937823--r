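#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData assay<- colData<- rowData<-
NULL

#' AmpliconExperiment: a molecule-tagged feature-by-sample count table
#'
#' An `AmpliconExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one `counts` assay of non-negative integers (features in rows,
#' samples in columns), with a mandatory per-sample `molecule` tag in
#' `colData` recording whether the library was amplified from the 16S gene
#' (`"rDNA"`, an abundance proxy) or from reverse-transcribed 16S
#' transcripts (`"rRNA"`, an activity proxy). Taxonomic lineages, when
#' supplied, live in `rowData` under the six ranks of [TAXONOMIC_RANKS].
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @name AmpliconExperiment-class
#' @exportClass AmpliconExperiment
setClass("AmpliconExperiment", contains = "SummarizedExperiment")

setValidity("AmpliconExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have feature and sample names")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicated feature ids")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicated sample ids")
  if (!is.numeric(m) || !.isWholeNumber(m) || any(m < 0))
    msg <- c(msg, "counts must be non-negative integers")
  if (!"molecule" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain a 'molecule' column")
  } else if (!all(object$molecule %in% .MOLECULES)) {
    msg <- c(msg, "molecule must be 'rDNA' or 'rRNA'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AmpliconExperiment
#'
#' @param counts Numeric matrix of non-negative integer counts with feature
#'   row names and sample column names.
#' @param molecule Molecule tag, `"rDNA"` or `"rRNA"`; either one value
#'   recycled to all samples or one value per sample.
#' @param sampleData Optional `data.frame` of additional per-sample columns
#'   (e.g. site, layer, biome, pair_id) with a `sample_id` column or row
#'   names matching `colnames(counts)`.
#' @param taxonomy Optional taxonomy map as returned by [readTaxonomyMap()];
#'   matched rows are stored in `rowData`.
#' @return An [AmpliconExperiment-class] object.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
#' ae <- AmpliconExperiment(m, molecule = "rDNA")
#' counts(ae)
AmpliconExperiment <- function(counts, molecule, sampleData = NULL,
                               taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (length(molecule) == 1L) molecule <- rep(molecule, ncol(counts))
  cd <- DataFrame(molecule = as.character(molecule),
                  row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    key <- if ("sample_id" %in% names(sampleData))
      sampleData$sample_id else rownames(sampleData)
    idx <- match(colnames(counts), key)
    if (anyNA(idx))
      stop("sampleData does not cover samples: ",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
    extra <- sampleData[idx, setdiff(names(sampleData),
                                     c("sample_id", "molecule")),
                        drop = FALSE]
    rownames(extra) <- colnames(counts)
    cd <- cbind(cd, DataFrame(extra))
  }
  rd <- NULL
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    idx <- match(rownames(counts), taxonomy$feature_id)
    rd <- DataFrame(taxonomy[idx, TAXONOMIC_RANKS, drop = FALSE],
                    row.names = rownames(counts))
  }
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  if (!is.null(rd)) rowData(se) <- rd
  new("AmpliconExperiment", se)
}

#' @describeIn AmpliconExperiment-class Access the integer count matrix.
#' @param object An `AmpliconExperiment`.
#' @export
setMethod("counts", "AmpliconExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @describeIn AmpliconExperiment-class Per-sample molecule tags
#'   (`"rDNA"`/`"rRNA"`).
#' @export
setMethod("molecule", "AmpliconExperiment", function(object) {
  stats::setNames(object$molecule, colnames(object))
})

setMethod("show", "AmpliconExperiment", function(object) {
  tab <- table(object$molecule)
  cat("AmpliconExperiment:", nrow(object), "features x",
      ncol(object), "samples (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  cat("  column sums:", paste(format(colSums(counts(object)), trim = TRUE),
                              collapse = " "), "\n")
})

#' PairedAmplicon: matched rDNA and rRNA tables
#'
#' Holds the rDNA and rRNA count tables of one survey after feature
#' reconciliation (union of feature sets, absences zero-padded, identical
#' row order in both tables) together with the list of complete sample
#' pairs. Unpaired samples remain in the tables -- they still contribute to
#' diversity summaries -- but only complete pairs enter ratio analyses.
#'
#' @slot rdna,rrna [AmpliconExperiment-class] objects sharing one feature
#'   universe.
#' @slot pairs `data.frame` with columns `rdna_sample`, `rrna_sample`,
#'   `pair_id`.
#' @name PairedAmplicon-class
#' @exportClass PairedAmplicon
setClass("PairedAmplicon",
         representation(rdna = "AmpliconExperiment",
                        rrna = "AmpliconExperiment",
                        pairs = "data.frame"))

setValidity("PairedAmplicon", function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("rdna_sample", "rrna_sample", "pair_id")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) < 1L) msg <- c(msg, "no complete sample pairs")
  if (!all(p$rdna_sample %in% colnames(object@rdna)))
    msg <- c(msg, "pairs reference unknown rDNA samples")
  if (!all(p$rrna_sample %in% colnames(object@rrna)))
    msg <- c(msg, "pairs reference unknown rRNA samples")
  if (anyDuplicated(p$pair_id)) msg <- c(msg, "duplicated pair_id")
  if (!all(object@rdna$molecule == "rDNA"))
    msg <- c(msg, "rdna table contains non-rDNA samples")
  if (!all(object@rrna$molecule == "rRNA"))
    msg <- c(msg, "rrna table contains non-rRNA samples")
  if (!identical(rownames(object@rdna), rownames(object@rrna)))
    msg <- c(msg, "feature universes are not reconciled")
  if (length(msg)) msg else TRUE
})

#' @describeIn PairedAmplicon-class The rDNA table.
#' @param x A `PairedAmplicon`.
#' @export
rdnaTable <- function(x) x@rdna

#' @describeIn PairedAmplicon-class The rRNA table.
#' @export
rrnaTable <- function(x) x@rrna

#' @describeIn PairedAmplicon-class The complete sample pairs.
#' @export
samplePairs <- function(x) x@pairs

setMethod("show", "PairedAmplicon", function(object) {
  cat("PairedAmplicon:", nrow(object@rdna), "features;",
      ncol(object@rdna), "rDNA and", ncol(object@rrna), "rRNA samples;",
      nrow(object@pairs), "complete pairs\n")
})
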