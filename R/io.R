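# Readers and writers for the plain-text table dialects: tab-separated
# feature-by-sample count matrices, two-column taxonomy maps with
# rank-prefixed lineages, and six-column sample metadata sheets.

#' Read a tab-separated count table
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' every remaining cell must be a non-negative integer. Cell order and
#' column totals are preserved exactly.
#'
#' @param path Path to a tab-separated file.
#' @param molecule Molecule tag for the samples in this file, `"rDNA"` or
#'   `"rRNA"`.
#' @return An [AmpliconExperiment-class].
#' @export
readCountTable <- function(path, molecule = c("rDNA", "rRNA")) {
  molecule <- match.arg(molecule)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (nrow(raw) == 0L) stop("no features in ", path)
  if (ncol(raw) < 2L) stop("no samples in ", path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample ids in ", path)
  m <- matrix(NA_real_, nrow(raw), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(!is.finite(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad))
      stop("invalid count at feature '", ids[bad[1L]], "', sample '",
           samples[j], "': '", raw[[j + 1L]][bad[1L]], "'")
    m[, j] <- v
  }
  AmpliconExperiment(m, molecule = molecule)
}

#' Read a count table from a BIOM file (JSON dialect)
#'
#' Thin wrapper around \pkg{biomformat} for surveys distributed in BIOM
#' format rather than TSV.
#'
#' @inheritParams readCountTable
#' @return An [AmpliconExperiment-class].
#' @export
readBiomTable <- function(path, molecule = c("rDNA", "rRNA")) {
  molecule <- match.arg(molecule)
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("package 'biomformat' is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  AmpliconExperiment(m, molecule = molecule)
}

#' Read a taxonomy map
#'
#' Parses a two-column tab-separated file of feature id and lineage string
#' (e.g. `"d__Bacteria;p__Myxococcota"`). Rank prefixes
#' `d__/p__/c__/o__/f__/g__` are stripped; missing trailing ranks become
#' `"Unassigned"`. A leading header row is tolerated. A feature listed twice
#' with conflicting lineages is an error; identical repeats are collapsed.
#'
#' @param path Path to the file.
#' @param delimiter Separator between lineage ranks (default `";"`).
#' @return `data.frame` with columns `feature_id` and the six
#'   [TAXONOMIC_RANKS].
#' @export
readTaxonomyMap <- function(path, delimiter = ";") {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("taxonomy file must have two columns: ", path)
  if (nrow(raw) > 0L &&
      tolower(gsub("[ #]", "_", raw[[1L]][1L])) %in%
        c("feature_id", "_otu_id", "otu_id", "feature_id_"))
    raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no taxonomy records in ", path)
  ids <- raw[[1L]]
  lineages <- t(vapply(raw[[2L]], .parseLineage, character(6L),
                       delimiter = delimiter, USE.NAMES = FALSE))
  colnames(lineages) <- TAXONOMIC_RANKS
  out <- data.frame(feature_id = ids, lineages,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- unique(out)
  if (anyDuplicated(out$feature_id))
    stop("conflicting lineages for feature(s): ",
         paste(unique(out$feature_id[duplicated(out$feature_id)]),
               collapse = ", "))
  out
}

.parseLineage <- function(lineage, delimiter = ";") {
  parts <- trimws(strsplit(lineage, delimiter, fixed = TRUE)[[1L]])
  parts <- sub("^[dpcofg]__", "", parts)
  parts[parts == ""] <- "Unassigned"
  length(parts) <- 6L
  parts[is.na(parts)] <- "Unassigned"
  parts
}

#' Read a sample metadata sheet
#'
#' Tab-separated with required columns `sample_id`, `site`, `layer`
#' (surface/middle/bottom), `biome` (FL/PA), `molecule` (rDNA/rRNA) and
#' `pair_id` linking each rDNA library to its matched rRNA library. A
#' pair_id may occur in at most one sample per molecule.
#'
#' @param path Path to the file.
#' @return Validated `data.frame`, one row per sample.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("sample_id", "site", "layer", "biome", "molecule", "pair_id")
  missing <- setdiff(need, names(md))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  validateSampleMetadata(md)
}

#' Validate sample metadata
#'
#' Applies the same checks as [readSampleMetadata()] to an in-memory
#' `data.frame`.
#'
#' @param md `data.frame` with the six required metadata columns.
#' @return `md`, invisibly unchanged, after validation.
#' @export
validateSampleMetadata <- function(md) {
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata")
  .checkEnum <- function(col, allowed) {
    bad <- setdiff(unique(md[[col]]), allowed)
    if (length(bad))
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  .checkEnum("layer", .LAYERS)
  .checkEnum("biome", .BIOMES)
  .checkEnum("molecule", .MOLECULES)
  dup <- duplicated(md[, c("pair_id", "molecule")])
  if (any(dup))
    stop("pair_id bound to two ", md$molecule[dup][1L], " samples: ",
         paste(unique(md$pair_id[dup]), collapse = ", "))
  md
}

#' Write a count table or summary to a tab-separated file
#'
#' Integer count tables round-trip bit-identically through
#' [readCountTable()]. Data frames (e.g. taxon summaries, activity records)
#' are written with their column order as header.
#'
#' @param x An [AmpliconExperiment-class] or a `data.frame`.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
setGeneric("writeTable", function(x, path) standardGeneric("writeTable"))

#' @rdname writeTable
setMethod("writeTable", "AmpliconExperiment", function(x, path) {
  m <- counts(x)
  df <- data.frame(feature_id = rownames(m),
                   format(m, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, path)
})

#' @rdname writeTable
setMethod("writeTable", "data.frame", function(x, path) {
  .writeTsv(x, path)
})

.writeTsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}
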