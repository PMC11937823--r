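# Core analysis: relative abundances, taxon aggregation, rRNA:rDNA activity
# ratios, four-quadrant classification of taxon-sample points, rRNA-only
# feature detection and tabular summaries.

.PSV_CATEGORIES <- c("high_high", "low_high", "low_low", "high_low")

#' Relative abundance profile
#'
#' Converts counts to per-sample percentages (each column sums to 100).
#' Values are kept at full precision; round only at presentation with
#' [roundHalfUp()].
#'
#' @param x An [AmpliconExperiment-class] or a numeric count matrix.
#' @return Numeric matrix of percentages with the same dimnames.
#' @export
relativeAbundance <- function(x) {
  m <- if (methods::is(x, "AmpliconExperiment")) counts(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(m, 2L, tot, "/") * 100
}

#' Aggregate a count table at a taxonomic rank
#'
#' Sums feature counts over features sharing the same name at `rank`.
#' Features whose lineage is `Unassigned` at that rank are pooled into a
#' bucket called `"Unknown"`. Output rows are sorted by descending total
#' count; per-sample column sums are conserved exactly.
#'
#' @param x An [AmpliconExperiment-class].
#' @param taxonomy Taxonomy map from [readTaxonomyMap()].
#' @param rank One of [TAXONOMIC_RANKS].
#' @param missingFeatures Features absent from the taxonomy: `"error"`
#'   (default) or `"unknown"` to pool them into the `"Unknown"` bucket.
#' @return An [AmpliconExperiment-class] whose features are taxa at `rank`.
#' @export
aggregateByRank <- function(x, taxonomy, rank = "phylum",
                            missingFeatures = c("error", "unknown")) {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  missingFeatures <- match.arg(missingFeatures)
  m <- counts(x)
  taxonomy <- as.data.frame(taxonomy)
  lab <- taxonomy[[rank]][match(rownames(m), taxonomy$feature_id)]
  if (anyNA(lab)) {
    if (missingFeatures == "error")
      stop("feature(s) missing from taxonomy: ",
           paste(utils::head(rownames(m)[is.na(lab)], 5L), collapse = ", "))
    lab[is.na(lab)] <- "Unassigned"
  }
  lab[lab == "Unassigned"] <- "Unknown"
  agg <- rowsum(m, group = lab, reorder = FALSE)
  agg <- agg[order(-rowSums(agg), rownames(agg)), , drop = FALSE]
  AmpliconExperiment(agg, molecule = x$molecule,
                     sampleData = as.data.frame(colData(x)))
}

#' rRNA:rDNA activity ratios per taxon and sample pair
#'
#' For every complete sample pair and every taxon at `rank`, computes the
#' taxon's relative rDNA and rRNA abundance (percent of the respective
#' library), their ratio, and the plotting coordinates
#' `X = log10(rel_rdna_pct)` and `Y = log10(ratio + 1)` (the +1 admits
#' taxa with ratio 0). Because abundance is expressed in percent, `X > 0`
#' exactly when a taxon exceeds 1% relative abundance. Bookkeeping of the
#' degenerate cells:
#' \itemize{
#'   \item rRNA absent, rDNA present: ratio 0, `Y = 0` -- a silent taxon.
#'   \item rDNA absent, rRNA present: record emitted with category
#'     `"undefined"` (ratio undefined); excluded from quadrant counts.
#'   \item both absent: no record, which is why a survey of `p` taxa and
#'     `n` pairs yields fewer than `p * n` defined points.
#' }
#'
#' @param paired A [PairedAmplicon-class]; rarefy the tables first if
#'   ratios should be computed on a common depth (the default workflow).
#' @param taxonomy Taxonomy map.
#' @param rank Aggregation rank, default `"phylum"`.
#' @param missingFeatures Passed to [aggregateByRank()].
#' @return `data.frame` with columns `taxon`, `pair_id`, `rel_rdna_pct`,
#'   `rel_rrna_pct`, `ratio`, `X`, `Y`, `category` (`NA` until
#'   [psvClassify()] is applied; `"undefined"` where rDNA is absent).
#' @export
activityRatio <- function(paired, taxonomy, rank = "phylum",
                          missingFeatures = c("error", "unknown")) {
  stopifnot(methods::is(paired, "PairedAmplicon"))
  pairs <- samplePairs(paired)
  if (nrow(pairs) == 0L) stop("no sample pairs")
  agg_d <- aggregateByRank(rdnaTable(paired), taxonomy, rank,
                           missingFeatures)
  agg_r <- aggregateByRank(rrnaTable(paired), taxonomy, rank,
                           missingFeatures)
  taxa <- union(rownames(agg_d), rownames(agg_r))
  expand <- function(ae) {
    p <- relativeAbundance(ae)
    full <- matrix(0, length(taxa), ncol(p), dimnames = list(taxa,
                                                             colnames(p)))
    full[rownames(p), ] <- p
    full
  }
  pd <- expand(agg_d)
  pr <- expand(agg_r)
  recs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    d <- pd[, pairs$rdna_sample[i]]
    r <- pr[, pairs$rrna_sample[i]]
    keep <- d > 0 | r > 0
    data.frame(taxon = taxa[keep], pair_id = pairs$pair_id[i],
               rel_rdna_pct = d[keep], rel_rrna_pct = r[keep],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  defined <- recs$rel_rdna_pct > 0
  recs$ratio <- ifelse(defined, recs$rel_rrna_pct / recs$rel_rdna_pct,
                       NA_real_)
  recs$X <- ifelse(defined, log10(recs$rel_rdna_pct), NA_real_)
  recs$Y <- ifelse(defined, log10(recs$ratio + 1), NA_real_)
  recs$category <- ifelse(defined, NA_character_, "undefined")
  recs
}

#' Classify taxon-sample points into abundance-activity quadrants
#'
#' A point is \emph{high abundance} when its relative rDNA abundance is at
#' least `abundanceThresholdPct` (default 1%) and \emph{highly active} when
#' its raw rRNA:rDNA ratio is at least `ratioThreshold` (default 10). Both
#' boundaries are inclusive. The four quadrant labels are `high_high`,
#' `low_high`, `low_low`, `high_low` (abundance first, activity second).
#' Records with category `"undefined"` (no rDNA signal) pass through
#' untouched. Classification uses the raw ratio; the log-transformed `Y`
#' coordinate is for plotting and reporting only.
#'
#' @param records Output of [activityRatio()].
#' @param abundanceThresholdPct High-abundance cutoff in percent (> 0).
#' @param ratioThreshold High-activity cutoff on the raw ratio (> 0).
#' @return `records` with `category` filled in.
#' @export
psvClassify <- function(records, abundanceThresholdPct = 1.0,
                        ratioThreshold = 10) {
  if (abundanceThresholdPct <= 0 || ratioThreshold <= 0)
    stop("thresholds must be positive")
  defined <- is.na(records$category) |
    records$category %in% .PSV_CATEGORIES
  hiA <- records$rel_rdna_pct >= abundanceThresholdPct
  hiR <- records$ratio >= ratioThreshold
  lab <- ifelse(hiA,
                ifelse(hiR, "high_high", "high_low"),
                ifelse(hiR, "low_high", "low_low"))
  records$category[defined] <- lab[defined]
  records
}

#' Summarize quadrant counts
#'
#' Counts classified taxon-sample points per quadrant. The four counts
#' partition the defined records; `"undefined"` records are excluded from
#' the total. Percentages are reported both at full precision and rounded
#' to the nearest integer (the conventional presentation).
#'
#' @param records Classified records from [psvClassify()].
#' @return `data.frame` with one row per quadrant (`category`, `n`,
#'   `percent`, `percent_rounded`) and attribute `"total"` holding the
#'   defined-record total.
#' @export
psvSummary <- function(records) {
  defined <- records[!is.na(records$category) &
                       records$category != "undefined", , drop = FALSE]
  if (nrow(defined) && !all(defined$category %in% .PSV_CATEGORIES))
    stop("records contain unclassified categories; run psvClassify() first")
  n <- vapply(.PSV_CATEGORIES,
              function(k) sum(defined$category == k), integer(1L))
  total <- sum(n)
  pct <- if (total > 0) 100 * n / total else rep(0, 4L)
  out <- data.frame(category = .PSV_CATEGORIES, n = unname(n),
                    percent = unname(pct),
                    percent_rounded = unname(roundHalfUp(pct, 0)),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Features detected only in rRNA libraries
#'
#' Flags features with zero counts across \emph{all} rDNA samples but at
#' least one read in an rRNA sample: taxa too rare to register at the gene
#' level yet visible through their transcripts, i.e. candidate
#' low-abundance/high-activity organisms. Detection is global and strict --
#' a single rDNA read anywhere disqualifies a feature.
#'
#' @param paired A [PairedAmplicon-class] (feature universes reconciled).
#' @param taxonomy Optional taxonomy map; when given, lineage columns are
#'   attached.
#' @return `data.frame` with `feature_id`, `n_rrna_samples` (number of rRNA
#'   samples with a detection) and, if available, the lineage ranks.
#' @export
rrnaOnlyFeatures <- function(paired, taxonomy = NULL) {
  d <- counts(rdnaTable(paired))
  r <- counts(rrnaTable(paired))
  flag <- rowSums(d) == 0 & rowSums(r > 0) >= 1
  out <- data.frame(feature_id = rownames(d)[flag],
                    n_rrna_samples = rowSums(r > 0)[flag],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    idx <- match(out$feature_id, taxonomy$feature_id)
    out <- cbind(out, taxonomy[idx, TAXONOMIC_RANKS, drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Per-taxon sequence and feature-count summary
#'
#' Builds the standard survey summary at `rank`: sequence counts and
#' percentages for the combined, rDNA and rRNA strata (percent of the
#' respective stratum total; combined percent of the grand total), feature
#' (OTU) counts per stratum, rRNA-only feature counts with the maximum
#' per-feature sample occurrence, and a grand-total row. Percent columns
#' are rounded half-up to two decimals; counts are exact.
#'
#' @param paired A [PairedAmplicon-class].
#' @param taxonomy Taxonomy map.
#' @param rank Summary rank (e.g. `"domain"` for whole-survey totals,
#'   `"phylum"` or `"order"` for clade tables).
#' @param missingFeatures Passed to [aggregateByRank()].
#' @return `data.frame`, one row per taxon sorted by descending combined
#'   sequences, plus a final `"Total"` row.
#' @export
taxonSummary <- function(paired, taxonomy, rank = "phylum",
                         missingFeatures = c("error", "unknown")) {
  d <- counts(rdnaTable(paired))
  r <- counts(rrnaTable(paired))
  taxonomy <- as.data.frame(taxonomy)
  lab <- taxonomy[[match.arg(rank, TAXONOMIC_RANKS)]][
    match(rownames(d), taxonomy$feature_id)]
  if (anyNA(lab)) {
    if (match.arg(missingFeatures, c("error", "unknown")) == "error")
      stop("feature(s) missing from taxonomy: ",
           paste(utils::head(rownames(d)[is.na(lab)], 5L), collapse = ", "))
    lab[is.na(lab)] <- "Unassigned"
  }
  lab[lab == "Unassigned"] <- "Unknown"

  rd_feat <- rowSums(d)
  rr_feat <- rowSums(r)
  rna_only <- rd_feat == 0 & rr_feat > 0
  occ <- rowSums(r > 0)

  taxa <- unique(lab)
  rows <- lapply(taxa, function(tx) {
    i <- lab == tx
    data.frame(
      taxon = tx,
      combined_sequences = sum(rd_feat[i]) + sum(rr_feat[i]),
      rdna_sequences = sum(rd_feat[i]),
      rrna_sequences = sum(rr_feat[i]),
      combined_otus = sum(i & (rd_feat + rr_feat) > 0),
      rdna_otus = sum(i & rd_feat > 0),
      rrna_otus = sum(i & rr_feat > 0),
      rna_only_otus = sum(i & rna_only),
      rna_only_max_samples = if (any(i & rna_only))
        max(occ[i & rna_only]) else 0L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$combined_sequences, out$taxon), ]

  tot_d <- sum(rd_feat)
  tot_r <- sum(rr_feat)
  grand <- tot_d + tot_r
  out$combined_pct <- roundHalfUp(100 * out$combined_sequences / grand, 2)
  out$rdna_pct <- roundHalfUp(100 * out$rdna_sequences / tot_d, 2)
  out$rrna_pct <- roundHalfUp(100 * out$rrna_sequences / tot_r, 2)

  total_row <- data.frame(
    taxon = "Total",
    combined_sequences = grand, rdna_sequences = tot_d,
    rrna_sequences = tot_r,
    combined_otus = sum((rd_feat + rr_feat) > 0),
    rdna_otus = sum(rd_feat > 0), rrna_otus = sum(rr_feat > 0),
    rna_only_otus = sum(rna_only),
    rna_only_max_samples = if (any(rna_only)) max(occ[rna_only]) else 0L,
    combined_pct = 100, rdna_pct = 100, rrna_pct = 100,
    stringsAsFactors = FALSE)
  out <- rbind(out, total_row)
  rownames(out) <- NULL
  out
}
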