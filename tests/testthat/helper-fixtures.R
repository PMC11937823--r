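# shared in-code fixtures

extfile <- function(...) {
  system.file("extdata", ..., package = "riboactivity", mustWork = TRUE)
}

makeAE <- function(counts, molecule = "rDNA") {
  AmpliconExperiment(as.matrix(counts), molecule = molecule)
}

# A tiny two-pair survey with exactly known percentages:
# pair P1: rDNA (A:1, B:999, C:0), rRNA (A:20, B:970, C:10)
#   -> A: 0.1% vs 2.0%, ratio 20; C undefined (rDNA absent)
# pair P2: rDNA (A:5, B:990, C:5), rRNA (A:0, B:1000, C:0)
#   -> A: 0.5% vs 0, ratio 0; C: 0.5% vs 0, ratio 0
makeToyPaired <- function() {
  d <- matrix(c(1, 999, 0,
                5, 990, 5), ncol = 2,
              dimnames = list(c("OTU_A", "OTU_B", "OTU_C"),
                              c("P1-DNA", "P2-DNA")))
  r <- matrix(c(20, 970, 10,
                0, 1000, 0), ncol = 2,
              dimnames = list(c("OTU_A", "OTU_B", "OTU_C"),
                              c("P1-RNA", "P2-RNA")))
  md <- data.frame(
    sample_id = c("P1-DNA", "P2-DNA", "P1-RNA", "P2-RNA"),
    site = "S1",
    layer = c("surface", "middle", "surface", "middle"),
    biome = "FL",
    molecule = c("rDNA", "rDNA", "rRNA", "rRNA"),
    pair_id = c("P1", "P2", "P1", "P2"),
    stringsAsFactors = FALSE)
  paired <- pairSamples(makeAE(d, "rDNA"), makeAE(r, "rRNA"), md)
  taxonomy <- data.frame(
    feature_id = c("OTU_A", "OTU_B", "OTU_C"),
    domain = "Bacteria",
    phylum = c("PhyA", "PhyB", "PhyC"),
    class = "Unassigned", order = "Unassigned",
    family = "Unassigned", genus = "Unassigned",
    stringsAsFactors = FALSE)
  list(paired = paired, taxonomy = taxonomy, metadata = md)
}

# Synthetic OTU-level paired table realizing published marginal totals for
# one clade: `nTotal` OTUs of which `nRdna` have rDNA detections and
# `nRnaOnly` appear exclusively in the rRNA library.
makeMarginalPaired <- function(phylum, nTotal, nRdna, nRnaOnly) {
  stopifnot(nRdna + nRnaOnly == nTotal)
  ids <- sprintf("%s_OTU%04d", phylum, seq_len(nTotal))
  d <- matrix(0, nTotal, 1, dimnames = list(ids, "D1"))
  r <- matrix(0, nTotal, 1, dimnames = list(ids, "R1"))
  d[seq_len(nRdna), 1] <- 1
  r[(nRdna + 1):nTotal, 1] <- 1
  md <- data.frame(sample_id = c("D1", "R1"), site = "S1",
                   layer = "surface", biome = "FL",
                   molecule = c("rDNA", "rRNA"), pair_id = "P1",
                   stringsAsFactors = FALSE)
  taxonomy <- data.frame(feature_id = ids, domain = "Bacteria",
                         phylum = phylum, class = "Unassigned",
                         order = "Unassigned", family = "Unassigned",
                         genus = "Unassigned", stringsAsFactors = FALSE)
  list(paired = pairSamples(makeAE(d, "rDNA"), makeAE(r, "rRNA"), md),
       taxonomy = taxonomy)
}
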