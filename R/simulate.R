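# Synthetic paired rDNA/rRNA communities and MAG count tables with known
# ground truth, so every pipeline stage is testable without any download.
#
# Generative model: phylum weights are lognormal draws with a wide spread
# (so dominant phyla hold tens of percent while the tail sits well below
# 1%, as in real surveys); within each phylum, OTU shares are a second,
# narrower lognormal. The product, normalized, is the rDNA community. A
# fixed fraction of phyla is flagged
# active; every OTU of an active phylum carries the phylum's activity
# multiplier m (log-uniform over [10, 200] by default, after the 10- to
# 200-fold rRNA:rDNA excesses observed for the most active taxa in paired
# surveys), all other OTUs have m = 1. The rRNA community is the
# renormalized product p*m / sum(p*m). Sequencing is multinomial sampling
# at the configured depth; no chimeras, taxonomy error or rDNA copy-number
# variation is modelled (deliberate caveat: the ratio method itself does
# not correct for copy number).

#' Specify a synthetic paired community
#'
#' Collects the generator's parameters with validated defaults. The
#' defaults describe a 20-phylum survey of 12 sample pairs sequenced at
#' 20818 reads per library, with 10% of phyla active at multipliers
#' log-uniform in \[10, 200\].
#'
#' @param nPhyla Number of phyla (default 20).
#' @param otusPerPhylum OTUs per phylum (default 15).
#' @param phylumSdlog Lognormal sd of the between-phylum weights (default
#'   2.5): wide enough that roughly two thirds of phyla fall below 1%
#'   relative abundance while a handful dominate, the structure seen in
#'   marine amplicon surveys.
#' @param meanlog,sdlog Lognormal parameters of the within-phylum OTU
#'   shares (defaults 0 and 1).
#' @param activeFraction Fraction of phyla flagged active in \[0, 1\]
#'   (default 0.1).
#' @param multiplierRange Range of the log-uniform activity multiplier,
#'   both ends >= 1 (default `c(10, 200)`).
#' @param rdnaDepth,rrnaDepth Reads per sample for each molecule (default
#'   20818).
#' @param nPairs Number of sample pairs (default 12).
#' @param otuJitterSdlog Optional lognormal sd of per-OTU multiplier jitter
#'   around the phylum multiplier (0 = off, the default).
#' @return Validated list of class `"communitySpec"`.
#' @export
communitySpec <- function(nPhyla = 20L, otusPerPhylum = 15L,
                          phylumSdlog = 2.5, meanlog = 0, sdlog = 1,
                          activeFraction = 0.1,
                          multiplierRange = c(10, 200),
                          rdnaDepth = 20818L, rrnaDepth = 20818L,
                          nPairs = 12L, otuJitterSdlog = 0) {
  if (activeFraction < 0 || activeFraction > 1)
    stop("activeFraction must lie in [0, 1]")
  if (length(multiplierRange) != 2L || any(multiplierRange < 1) ||
      multiplierRange[1L] > multiplierRange[2L])
    stop("multiplierRange must be an increasing pair with both ends >= 1")
  if (nPhyla < 1 || otusPerPhylum < 1 || nPairs < 1 ||
      rdnaDepth < 1 || rrnaDepth < 1)
    stop("counts and depths must be positive")
  if (phylumSdlog < 0) stop("phylumSdlog must be non-negative")
  spec <- list(nPhyla = as.integer(nPhyla),
               otusPerPhylum = as.integer(otusPerPhylum),
               phylumSdlog = phylumSdlog,
               meanlog = meanlog, sdlog = sdlog,
               activeFraction = activeFraction,
               multiplierRange = multiplierRange,
               rdnaDepth = as.integer(rdnaDepth),
               rrnaDepth = as.integer(rrnaDepth),
               nPairs = as.integer(nPairs),
               otuJitterSdlog = otuJitterSdlog)
  class(spec) <- "communitySpec"
  spec
}

.simulateCommunityImpl <- function(spec) {
  nOtu <- spec$nPhyla * spec$otusPerPhylum
  phylum <- rep(sprintf("SimPhylum_%02d", seq_len(spec$nPhyla)),
                each = spec$otusPerPhylum)
  otu_id <- sprintf("OTU%04d", seq_len(nOtu))
  w <- stats::rlnorm(spec$nPhyla, 0, spec$phylumSdlog)   # phylum weights
  w <- w / sum(w)
  within <- stats::rlnorm(nOtu, spec$meanlog, spec$sdlog)
  p <- rep(w, each = spec$otusPerPhylum) * within /
    rep(tapply(within, phylum, sum)[unique(phylum)],
        each = spec$otusPerPhylum)
  p <- p / sum(p)
  nActive <- round(spec$activeFraction * spec$nPhyla)
  active_phyla <- sort(sample(unique(phylum), nActive))
  m_phylum <- stats::setNames(rep(1, spec$nPhyla), unique(phylum))
  if (nActive > 0) {
    lo <- log(spec$multiplierRange[1L])
    hi <- log(spec$multiplierRange[2L])
    m_phylum[active_phyla] <- exp(stats::runif(nActive, lo, hi))
  }
  m <- unname(m_phylum[phylum])
  if (spec$otuJitterSdlog > 0) {
    jitter <- stats::rlnorm(nOtu, 0, spec$otuJitterSdlog)
    m <- ifelse(m > 1, m * jitter, m)
  }
  p_rrna <- p * m / sum(p * m)

  otu <- data.frame(otu_id = otu_id, phylum = phylum,
                    p_rdna = p, multiplier = m, p_rrna = p_rrna,
                    stringsAsFactors = FALSE)
  ph_d <- 100 * tapply(p, phylum, sum)
  ph_r <- 100 * tapply(p_rrna, phylum, sum)
  ph <- data.frame(taxon = names(ph_d),
                   active = names(ph_d) %in% active_phyla,
                   rel_rdna_pct = as.numeric(ph_d),
                   rel_rrna_pct = as.numeric(ph_r[names(ph_d)]),
                   stringsAsFactors = FALSE)
  ph$ratio <- ph$rel_rrna_pct / ph$rel_rdna_pct
  ph$category <- NA_character_
  ph <- psvClassify(ph)
  truth <- list(otu = otu, phylum = ph, spec = spec)
  class(truth) <- "groundTruth"
  truth
}

#' Simulate a community with known ground truth
#'
#' Draws OTU base proportions, assigns activity multipliers to the OTUs of
#' the active phyla, and derives the infinite-depth truth: per-phylum
#' relative rDNA/rRNA abundance, rRNA:rDNA ratio and quadrant category
#' under the default [psvClassify()] thresholds. The true rRNA proportion
#' of OTU i is `p_i * m_i / sum(p_j * m_j)`.
#'
#' @param spec A [communitySpec()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return List of class `"groundTruth"` with elements `otu` (per-OTU
#'   proportions and multipliers), `phylum` (per-phylum truth incl.
#'   `category`) and `spec`.
#' @export
simulateCommunity <- function(spec, seed) {
  stopifnot(inherits(spec, "communitySpec"))
  withSeed(seed, .simulateCommunityImpl(spec))
}

#' Draw one sequencing sample from the truth
#'
#' Multinomial draw of `depth` reads with probabilities equal to the true
#' OTU proportions of the requested molecule. OTUs with zero true
#' proportion can never be observed, and the column sums to `depth`
#' exactly.
#'
#' @param truth A `"groundTruth"` from [simulateCommunity()].
#' @param molecule `"rDNA"` or `"rRNA"`.
#' @param depth Reads to draw (positive integer).
#' @param seed Integer seed.
#' @return Named integer vector of OTU counts.
#' @export
sampleReads <- function(truth, molecule = c("rDNA", "rRNA"), depth, seed) {
  molecule <- match.arg(molecule)
  stopifnot(inherits(truth, "groundTruth"), depth >= 1)
  prob <- if (molecule == "rDNA") truth$otu$p_rdna else truth$otu$p_rrna
  cnt <- withSeed(seed, stats::rmultinom(1L, size = depth, prob = prob))
  stats::setNames(as.integer(cnt), truth$otu$otu_id)
}

#' Simulate a full paired rDNA/rRNA dataset
#'
#' Generates the community truth, draws multinomial rDNA and rRNA libraries
#' for every sample pair, and packages them with a taxonomy map and sample
#' metadata into a [PairedAmplicon-class]. Running the activity-profile
#' stages on the result and comparing against `$truth` is the end-to-end
#' test of the pipeline.
#'
#' @param spec A [communitySpec()].
#' @param seed Integer seed; the whole dataset is byte-identical given the
#'   same spec and seed.
#' @return List of class `"syntheticDataset"` with `paired`
#'   ([PairedAmplicon-class]), `taxonomy`, `metadata` and `truth`.
#' @export
simulatePairedDataset <- function(spec, seed) {
  stopifnot(inherits(spec, "communitySpec"))
  withSeed(seed, {
    truth <- .simulateCommunityImpl(spec)
    nP <- spec$nPairs
    pair_id <- sprintf("P%02d", seq_len(nP))
    d_names <- paste0(pair_id, "-DNA")
    r_names <- paste0(pair_id, "-RNA")
    d <- stats::rmultinom(nP, spec$rdnaDepth, truth$otu$p_rdna)
    r <- stats::rmultinom(nP, spec$rrnaDepth, truth$otu$p_rrna)
    dimnames(d) <- list(truth$otu$otu_id, d_names)
    dimnames(r) <- list(truth$otu$otu_id, r_names)
    taxonomy <- data.frame(feature_id = truth$otu$otu_id,
                           domain = "Bacteria",
                           phylum = truth$otu$phylum,
                           class = "Unassigned", order = "Unassigned",
                           family = "Unassigned", genus = "Unassigned",
                           stringsAsFactors = FALSE)
    metadata <- data.frame(
      sample_id = c(d_names, r_names),
      site = "SIM1",
      layer = rep(rep_len(c("surface", "middle", "bottom"), nP), 2L),
      biome = rep(rep_len(c("FL", "PA"), nP), 2L),
      molecule = rep(c("rDNA", "rRNA"), each = nP),
      pair_id = rep(pair_id, 2L),
      stringsAsFactors = FALSE)
    rdna <- AmpliconExperiment(d, molecule = "rDNA", sampleData = metadata,
                               taxonomy = taxonomy)
    rrna <- AmpliconExperiment(r, molecule = "rRNA", sampleData = metadata,
                               taxonomy = taxonomy)
    paired <- suppressMessages(pairSamples(rdna, rrna, metadata))
    out <- list(paired = paired, taxonomy = taxonomy, metadata = metadata,
                truth = truth)
    class(out) <- "syntheticDataset"
    out
  })
}

#' Quadrant-label recovery rate of the activity pipeline
#'
#' Parameter-recovery experiment: simulates `length(seeds)` independent
#' datasets from `spec`, runs [activityRatio()] + [psvClassify()] on each,
#' and compares every (phylum, pair) quadrant label against the
#' infinite-depth ground-truth label, pooling over all replicates. Phylum
#' pairs whose true relative rDNA abundance is below
#' `minTrueAbundancePct` are excluded -- at finite depth such taxa may not
#' be observed at all.
#'
#' @param spec A [communitySpec()].
#' @param seeds Integer vector of replicate seeds.
#' @param minTrueAbundancePct Eligibility threshold on the true rDNA
#'   abundance, in percent (default 0.05).
#' @return List with `recovery` (pooled fraction of matching labels),
#'   `n_compared`, and `per_seed` (per-replicate fractions).
#' @export
quadrantRecovery <- function(spec, seeds, minTrueAbundancePct = 0.05) {
  match_n <- 0L
  tot_n <- 0L
  per_seed <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    ds <- simulatePairedDataset(spec, seeds[k])
    recs <- psvClassify(activityRatio(ds$paired, ds$taxonomy, "phylum"))
    truth <- ds$truth$phylum
    eligible <- truth$taxon[truth$rel_rdna_pct >= minTrueAbundancePct]
    recs <- recs[recs$taxon %in% eligible &
                   recs$category != "undefined", , drop = FALSE]
    true_cat <- truth$category[match(recs$taxon, truth$taxon)]
    ok <- recs$category == true_cat
    per_seed[k] <- mean(ok)
    match_n <- match_n + sum(ok)
    tot_n <- tot_n + length(ok)
  }
  list(recovery = match_n / tot_n, n_compared = tot_n, per_seed = per_seed)
}

#' Simulate a MAG mapped-count dataset
#'
#' Genes get integer lengths uniform over `lengthRange` and lognormal true
#' expression rates; mapped counts are multinomial with probability
#' proportional to `length * rate`, so length-normalizing the counts (TPM)
#' recovers the true rates. Library size equals `depth` in every sample.
#'
#' @param nMags Number of MAGs (default 12).
#' @param genesPerMag Genes per MAG (default 10).
#' @param lengthRange Gene length range in bp (default `c(300, 3000)`).
#' @param exprMeanlog,exprSdlog Lognormal parameters of the true expression
#'   rates (defaults 0 and 1).
#' @param depth Mapped reads per sample (default 1e6).
#' @param nSamples Number of samples (default 4).
#' @param seed Integer seed.
#' @return List with `counts` (gene x sample), `catalog` (`feature_id`,
#'   `length_bp`, `parent_mag`), `libSizes`, and `trueTPM` (the
#'   infinite-depth TPM of every gene).
#' @export
simulateMagDataset <- function(nMags = 12L, genesPerMag = 10L,
                               lengthRange = c(300, 3000),
                               exprMeanlog = 0, exprSdlog = 1,
                               depth = 1e6, nSamples = 4L, seed) {
  stopifnot(nMags >= 1, genesPerMag >= 1, depth >= 1, nSamples >= 1,
            all(lengthRange > 0))
  withSeed(seed, {
    nGenes <- nMags * genesPerMag
    mags <- sprintf("MAG%02d", seq_len(nMags))
    gene_id <- sprintf("%s_g%03d", rep(mags, each = genesPerMag),
                       rep(seq_len(genesPerMag), nMags))
    len <- round(stats::runif(nGenes, lengthRange[1L], lengthRange[2L]))
    rate <- stats::rlnorm(nGenes, exprMeanlog, exprSdlog)
    prob <- len * rate
    cnt <- stats::rmultinom(nSamples, size = depth, prob = prob / sum(prob))
    dimnames(cnt) <- list(gene_id, sprintf("S%02d", seq_len(nSamples)))
    catalog <- data.frame(feature_id = gene_id, length_bp = len,
                          parent_mag = rep(mags, each = genesPerMag),
                          stringsAsFactors = FALSE)
    libSizes <- stats::setNames(rep(depth, nSamples), colnames(cnt))
    trueTPM <- stats::setNames(1e6 * rate / sum(rate), gene_id)
    list(counts = cnt, catalog = catalog, libSizes = libSizes,
         trueTPM = trueTPM)
  })
}
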