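# Rarefaction and rDNA/rRNA sample pairing.

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample column without replacement to exactly `depth`
#' reads: the column's reads are treated as an urn of labelled balls and
#' `depth` of them are drawn, so the marginal distribution of each cell is
#' hypergeometric with mean `depth * count / total`. Samples whose total is
#' below `depth` are either dropped with a warning or cause an error, per
#' `shallow`. The result is deterministic for a given `seed`; columns
#' already at exactly `depth` are returned unchanged.
#'
#' @param x An [AmpliconExperiment-class], or a plain count matrix
#'   (features x samples), in which case a matrix is returned.
#' @param depth Target reads per sample (positive integer); surveys rarefied
#'   before diversity or ratio analysis typically anchor this to the
#'   shallowest retained library.
#' @param seed Integer seed; required, no hidden RNG state.
#' @param shallow What to do with samples whose total is below `depth`:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return A rarefied [AmpliconExperiment-class]; every retained column sums
#'   to `depth`.
#' @export
rarefyCounts <- function(x, depth, seed, shallow = c("drop", "error")) {
  shallow <- match.arg(shallow)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1 ||
      abs(depth - round(depth)) > 1e-8)
    stop("'depth' must be a positive integer")
  isAE <- methods::is(x, "AmpliconExperiment")
  m <- if (isAE) counts(x) else as.matrix(x)
  tot <- colSums(m)
  keep <- tot >= depth
  if (!any(keep))
    stop("empty table: all samples are below depth ", depth)
  if (any(!keep)) {
    if (shallow == "error")
      stop("sample(s) below depth ", depth, ": ",
           paste(colnames(m)[!keep], collapse = ", "))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(m)[!keep], collapse = ", "))
  }
  sub <- m[, keep, drop = FALSE]
  rar <- withSeed(seed, {
    vapply(seq_len(ncol(sub)), function(j) {
      col <- sub[, j]
      if (sum(col) == depth) return(col)    # already at depth
      urn <- rep.int(seq_along(col), col)   # one ball per read
      drawn <- sample(urn, depth)           # without replacement
      as.double(tabulate(drawn, nbins = length(col)))
    }, numeric(nrow(sub)))
  })
  rar <- matrix(rar, nrow = nrow(sub), dimnames = dimnames(sub))
  if (!isAE) return(rar)
  out <- x[, keep]
  SummarizedExperiment::assay(out, "counts") <- rar
  methods::validObject(out)
  out
}

#' Pair rDNA and rRNA samples by pair id
#'
#' Matches each rDNA library to its rRNA counterpart through the metadata
#' `pair_id`, reconciles the two feature universes to their union with
#' zero-padding (so "absent from rDNA" is representable, as needed for
#' rRNA-only detection), and attaches the metadata columns to both tables.
#' Samples without a complete partner are reported via [message()] and stay
#' in the tables -- they still count for diversity -- but are excluded from
#' ratio analyses, which iterate over `samplePairs()`.
#'
#' @param rdna,rrna [AmpliconExperiment-class] tables of the two molecules.
#' @param metadata Sample metadata covering every sample of both tables
#'   (see [readSampleMetadata()]).
#' @return A [PairedAmplicon-class].
#' @export
pairSamples <- function(rdna, rrna, metadata) {
  metadata <- validateSampleMetadata(as.data.frame(metadata))
  all_samples <- c(colnames(rdna), colnames(rrna))
  uncovered <- setdiff(all_samples, metadata$sample_id)
  if (length(uncovered))
    stop("metadata does not cover sample(s): ",
         paste(uncovered, collapse = ", "))
  md <- metadata[match(all_samples, metadata$sample_id), ]
  tagged <- c(rep("rDNA", ncol(rdna)), rep("rRNA", ncol(rrna)))
  if (!all(md$molecule == tagged))
    stop("metadata molecule disagrees with table molecule for: ",
         paste(all_samples[md$molecule != tagged], collapse = ", "))

  md_d <- metadata[metadata$sample_id %in% colnames(rdna), ]
  md_r <- metadata[metadata$sample_id %in% colnames(rrna), ]
  shared <- intersect(md_d$pair_id, md_r$pair_id)
  if (length(shared) == 0L)
    stop("no complete rDNA/rRNA pair")
  pairs <- data.frame(
    rdna_sample = md_d$sample_id[match(shared, md_d$pair_id)],
    rrna_sample = md_r$sample_id[match(shared, md_r$pair_id)],
    pair_id = shared, stringsAsFactors = FALSE)
  unpaired <- setdiff(all_samples,
                      c(pairs$rdna_sample, pairs$rrna_sample))
  if (length(unpaired))
    message("unpaired sample(s) kept for diversity only: ",
            paste(unpaired, collapse = ", "))

  feats <- union(rownames(rdna), rownames(rrna))
  pad <- function(ae, mol) {
    m <- counts(ae)
    full <- matrix(0, length(feats), ncol(m),
                   dimnames = list(feats, colnames(m)))
    full[rownames(m), ] <- m
    AmpliconExperiment(full, molecule = mol, sampleData = metadata)
  }
  new("PairedAmplicon", rdna = pad(rdna, "rDNA"), rrna = pad(rrna, "rRNA"),
      pairs = pairs)
}
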