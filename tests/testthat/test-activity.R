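test_that("relative abundances normalize to 100 percent per sample", {
  # domain counts of a pooled survey: Bacteria at 92.58% of the library
  m <- matrix(c(80069, 1006483, 604), 3,
              dimnames = list(c("Archaea", "Bacteria", "Unknown"), "s"))
  p <- relativeAbundance(m)
  expect_equal(roundHalfUp(p["Bacteria", 1], 2), 92.58)
  expect_equal(sum(p), 100, tolerance = 1e-9)

  expect_equal(unname(relativeAbundance(matrix(7, 1, 1,
    dimnames = list("a", "s")))[1, 1]), 100)
  expect_equal(unname(relativeAbundance(matrix(c(1, 1), 2,
    dimnames = list(c("a", "b"), "s")))[, 1]), c(50, 50))

  z <- matrix(c(1, 0), 1, dimnames = list("a", c("ok", "empty")))
  expect_error(relativeAbundance(z), "empty")
})

test_that("rank aggregation sums clades, pools Unassigned and conserves totals", {
  toy <- makeToyPaired()
  m <- matrix(c(3, 4, 2), 3, dimnames = list(paste0("OTU", 1:3), "s1"))
  tx <- data.frame(feature_id = paste0("OTU", 1:3),
                   domain = "Bacteria",
                   phylum = c("Myxococcota", "Myxococcota", "Unassigned"),
                   class = "Unassigned", order = "Unassigned",
                   family = "Unassigned", genus = "Unassigned")
  agg <- aggregateByRank(makeAE(m), tx, "phylum")
  expect_equal(counts(agg)["Myxococcota", 1], 7)
  expect_equal(counts(agg)["Unknown", 1], 2)
  expect_equal(colSums(counts(agg)), colSums(m))

  # missing feature: error by default, poolable on request
  agg2 <- aggregateByRank(makeAE(m), tx[1:2, ], "phylum",
                          missingFeatures = "unknown")
  expect_equal(counts(agg2)["Unknown", 1], 2)
  expect_error(aggregateByRank(makeAE(m), tx[1:2, ], "phylum"), "missing")

  # per-sample sums invariant at every rank
  for (rk in TAXONOMIC_RANKS) {
    agg <- aggregateByRank(rdnaTable(toy$paired), toy$taxonomy, rk)
    expect_equal(colSums(counts(agg)),
                 colSums(counts(rdnaTable(toy$paired))))
    expect_equal(unname(colSums(relativeAbundance(agg))),
                 rep(100, ncol(agg)), tolerance = 1e-9)
  }
})

test_that("activity ratios implement the log-ratio bookkeeping", {
  toy <- makeToyPaired()
  recs <- activityRatio(toy$paired, toy$taxonomy, "phylum")
  p1a <- recs[recs$pair_id == "P1" & recs$taxon == "PhyA", ]
  expect_equal(p1a$rel_rdna_pct, 0.1)
  expect_equal(p1a$rel_rrna_pct, 2.0)
  expect_equal(p1a$ratio, 20)
  expect_equal(p1a$Y, log10(21), tolerance = 1e-6)  # ~1.3222
  expect_equal(p1a$X, -1)

  # rRNA absent -> ratio 0 and Y = 0
  p2a <- recs[recs$pair_id == "P2" & recs$taxon == "PhyA", ]
  expect_equal(p2a$rel_rdna_pct, 0.5)
  expect_equal(p2a$ratio, 0)
  expect_equal(p2a$Y, 0)

  # rDNA absent but rRNA present -> undefined, excluded from totals
  p1c <- recs[recs$pair_id == "P1" & recs$taxon == "PhyC", ]
  expect_equal(p1c$category, "undefined")
  s <- psvSummary(psvClassify(recs))
  expect_equal(attr(s, "total"),
               sum(recs$rel_rdna_pct > 0))
  # taxon absent from both molecules of a pair contributes no record
  expect_equal(nrow(recs), 6L)
})

test_that("quadrant classification respects the inclusive thresholds", {
  recs <- data.frame(
    taxon = c("a", "b", "c", "d"), pair_id = "P1",
    rel_rdna_pct = c(2.0, 0.1, 1.0, 0.5),
    rel_rrna_pct = NA, ratio = c(15, 20, 10, 2),
    X = NA, Y = NA, category = NA_character_)
  out <- psvClassify(recs)
  expect_equal(out$category,
               c("high_high", "low_high", "high_high", "low_low"))
  expect_error(psvClassify(recs, abundanceThresholdPct = 0), "positive")
  expect_error(psvClassify(recs, ratioThreshold = -1), "positive")
})

test_that("Y and X coordinates track ratio and abundance monotonically", {
  toy <- makeToyPaired()
  recs <- activityRatio(toy$paired, toy$taxonomy, "phylum")
  ok <- !is.na(recs$ratio)
  expect_true(all((recs$Y[ok] == 0) == (recs$ratio[ok] == 0)))
  ord <- order(recs$ratio[ok])
  expect_true(all(diff(recs$Y[ok][ord]) >= 0))
  expect_true(all((recs$X[ok] > 0) == (recs$rel_rdna_pct[ok] > 1)))
})

test_that("quadrant summary partitions the defined records", {
  # realize the published bookkeeping: 3 + 30 + 101 + 69 points
  n <- c(high_high = 3L, low_high = 30L, low_low = 101L, high_low = 69L)
  recs <- data.frame(
    taxon = sprintf("t%03d", seq_len(sum(n))),
    pair_id = "P1",
    rel_rdna_pct = rep(c(5, 0.2, 0.2, 5), n),
    rel_rrna_pct = NA,
    ratio = rep(c(50, 50, 0.5, 0.5), n),
    X = NA, Y = NA, category = NA_character_)
  s <- psvSummary(psvClassify(recs))
  expect_equal(s$n[match(names(n), s$category)], unname(n))
  expect_equal(attr(s, "total"), 203L)
  expect_equal(sum(s$n), attr(s, "total"))
  expect_equal(s$percent_rounded[s$category == "low_high"], 15)

  empty <- psvSummary(psvClassify(recs[0, ]))
  expect_equal(sum(empty$n), 0L)
  expect_equal(attr(empty, "total"), 0L)
})

test_that("rRNA-only features require strict rDNA absence", {
  d <- matrix(c(0, 0, 1, 0, 0, 0), 3,
              dimnames = list(c("only", "ghost", "seen"),
                              c("D1", "D2")))
  r <- matrix(c(2, 0, 1, 3, 0, 0), 3,
              dimnames = list(c("only", "ghost", "seen"),
                              c("R1", "R2")))
  md <- data.frame(sample_id = c("D1", "D2", "R1", "R2"), site = "S",
                   layer = "surface", biome = "FL",
                   molecule = c("rDNA", "rDNA", "rRNA", "rRNA"),
                   pair_id = c("P1", "P2", "P1", "P2"))
  paired <- pairSamples(makeAE(d, "rDNA"), makeAE(r, "rRNA"), md)
  out <- rrnaOnlyFeatures(paired)
  expect_equal(out$feature_id, "only")       # one rDNA read disqualifies
  expect_equal(out$n_rrna_samples, 2L)
  # flagged set is disjoint from features with any rDNA signal
  expect_length(intersect(out$feature_id,
                          rownames(d)[rowSums(d) > 0]), 0L)
})

test_that("rRNA-only fractions reproduce published clade marginals", {
  # 359 OTUs, 191 rDNA-detected, 168 rRNA-only -> 46.8%
  fx <- makeMarginalPaired("Bdellovibrionota", 359L, 191L, 168L)
  out <- rrnaOnlyFeatures(fx$paired, fx$taxonomy)
  expect_equal(nrow(out), 168L)
  expect_equal(roundHalfUp(100 * nrow(out) / 359, 1), 46.8)
})

test_that("taxon summaries add up across strata", {
  toy <- makeToyPaired()
  ts <- taxonSummary(toy$paired, toy$taxonomy, "phylum")
  expect_equal(ts$combined_sequences,
               ts$rdna_sequences + ts$rrna_sequences)
  tot <- ts[ts$taxon == "Total", ]
  expect_equal(tot$combined_sequences,
               sum(counts(rdnaTable(toy$paired))) +
                 sum(counts(rrnaTable(toy$paired))))
  # PhyC has no rDNA reads in P2? -- check a zero stratum reports 0
  phyC <- ts[ts$taxon == "PhyC", ]
  expect_equal(phyC$rdna_sequences, 5)
  expect_equal(phyC$rna_only_otus, 0L)
  # percents recomputable from counts
  expect_equal(phyC$rdna_pct,
               roundHalfUp(100 * 5 / tot$rdna_sequences, 2))
})
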