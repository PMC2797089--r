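genome2 <- makeGenome(c("c1", "c2"), c(1e6, 5e5))

test_that("permutation preserves per-chromosome counts and widths", {
  set.seed(3)
  ss <- siteSetAt(sample(c("c1", "c2"), 200, TRUE),
                  sample.int(490000L, 200) + 1000L, "F", genome2)
  perm <- permuteSites(genome2, ss, seed = 8L)
  expect_equal(table(as.character(seqnames(perm))),
               table(as.character(seqnames(ss))))
  expect_equal(sort(width(perm)), sort(width(ss)))
  expect_identical(siteMidpoints(permuteSites(genome2, ss, seed = 8L)),
                   siteMidpoints(perm))
  # uniform placement: mean midpoint on c1 near the centre
  one <- siteSetAt("c1", 5000L, "F", genome2)
  mids <- vapply(1:2000, function(i)
    as.numeric(siteMidpoints(permuteSites(genome2, one, seed = i))), 0)
  se <- 1e6 / sqrt(12) / sqrt(2000)
  expect_lt(abs(mean(mids) - 5e5), 3 * se)
  orphan <- siteSetAt("c9", 100L, "F")
  expect_error(permuteSites(genome2, orphan), "absent")
  expect_equal(length(permuteSites(genome2, siteSetAt(character(), integer(), "F"))), 0L)
})

test_that("signed nearest distances honour strand and match brute force", {
  feats <- data.frame(chrom = "c1", pos = c(1000L, 5000L),
                      strand = c("+", "-"))
  ss <- siteSetAt(c("c1", "c1", "c1"), c(1000L, 900L, 5100L), "F")
  d <- signedDistanceToNearest(ss, feats)
  expect_equal(d[siteMidpoints(ss) == 1000L], 0)
  expect_equal(d[siteMidpoints(ss) == 900L], -100)   # upstream of + TSS
  expect_equal(d[siteMidpoints(ss) == 5100L], -100)  # 5' of - TSS
  set.seed(12)
  feats2 <- data.frame(chrom = sample(c("c1", "c2"), 20, TRUE),
                       pos = sample.int(50000, 20),
                       strand = sample(c("+", "-"), 20, TRUE))
  ss2 <- siteSetAt(sample(c("c1", "c2"), 100, TRUE),
                   sample.int(50000, 100), "F")
  expect_equal(signedDistanceToNearest(ss2, feats2),
               bfSignedNearest(as.character(seqnames(ss2)),
                               siteMidpoints(ss2), feats2))
})

test_that("positional profile is well-formed even at nSim = 1", {
  feats <- data.frame(chrom = "c1", pos = seq(10000L, 90000L, 10000L),
                      strand = "+")
  set.seed(5)
  ss <- siteSetAt("c1", sample.int(9e5, 300), "F", genome2)
  pr <- positionalProfile(ss, feats, genome2,
                          cfg = enrichmentConfig(nSim = 1L, seed = 2L))
  tab <- profileTable(pr)
  expect_equal(nrow(tab), 40L)
  expect_equal(tab$null_lo, tab$null_hi)   # single null draw collapses CI
  expect_true(all(tab$p_enriched >= 1 / 2 & tab$p_enriched <= 1))
})

test_that("uniform sites give calibrated positional profiles", {
  feats <- data.frame(chrom = rep(c("c1", "c2"), c(8, 4)),
                      pos = c(seq(1e5, 8e5, 1e5), seq(1e5, 4e5, 1e5)),
                      strand = "+")
  set.seed(77)
  ss <- siteSetAt(sample(c("c1", "c2"), 400, TRUE, prob = c(2, 1)),
                  sample.int(480000, 400) + 1000L, "F", genome2)
  pr <- positionalProfile(ss, feats, genome2,
                          cfg = enrichmentConfig(nSim = 400L, seed = 3L))
  tab <- profileTable(pr)
  covered <- with(tab, observed >= null_lo & observed <= null_hi)
  expect_gt(mean(covered), 0.85)
})

test_that("promoter pair selection applies the distance windows inclusively", {
  # hand-built transcripts: TSS layout engineered per case
  mkGm <- function(df) {
    tx <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                  tx_id = paste0("t", seq_len(nrow(df))),
                  gene_id = df$gene)
    g <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                 gene_id = df$gene, alt_promoter = FALSE)
    GeneModels(g, tx, tx)
  }
  # +strand TSS 1000 apart: excluded from adjacent (<1500) and divergent
  gm1 <- mkGm(data.frame(chrom = "c1", start = c(1001, 2001),
                         end = c(1900, 2900), strand = "+",
                         gene = c("g1", "g2")))
  expect_equal(nrow(selectPromoterPairs(gm1, "adjacent")), 0L)
  expect_equal(nrow(selectPromoterPairs(gm1, "divergent")), 0L)
  # divergent pair exactly 2500 apart is included (inclusive bound)
  gm2 <- mkGm(data.frame(chrom = "c1", start = c(1, 3500),
                         end = c(1000, 4500), strand = c("-", "+"),
                         gene = c("g1", "g2")))
  dv <- selectPromoterPairs(gm2, "divergent")
  expect_equal(nrow(dv), 1L)
  expect_equal(dv$b - dv$a, 2500L)
  # convergent orientation is not divergent
  gm3 <- mkGm(data.frame(chrom = "c1", start = c(1, 3500),
                         end = c(1000, 4500), strand = c("+", "-"),
                         gene = c("g1", "g2")))
  expect_equal(nrow(selectPromoterPairs(gm3, "divergent")), 0L)
  # adjacent keeps TSS-to-TSS gaps of exactly 1500 and 20000 (inclusive)
  gm4 <- mkGm(data.frame(chrom = "c1",
                         start = c(1001, 2501, 22501, 100001),
                         end = c(1500, 3400, 23500, 101000), strand = "+",
                         gene = paste0("g", 1:4)))
  ad <- selectPromoterPairs(gm4, "adjacent")
  expect_equal(ad$b - ad$a, c(1500L, 20000L))
  # alternative promoters: one pair per distinct TSS pair of a gene
  gm5 <- mkGm(data.frame(chrom = "c1", start = c(1001, 1501, 2001),
                         end = 5000, strand = "+", gene = "g1"))
  al <- selectPromoterPairs(gm5, "alternative")
  expect_equal(nrow(al), 3L)  # choose(3, 2)
  expect_error(selectPromoterPairs(gm5, "bogus"))
})

test_that("intervening counts are strict and match brute force", {
  pairs <- data.frame(chrom = "c1", a = c(1000L, 5000L),
                      b = c(2000L, 6000L))
  ss <- siteSetAt("c1", c(1000L, 1001L, 1999L, 2000L, 5500L), "F", genome2)
  pe <- interveningEnrichment(ss, pairs, genome2,
                              enrichmentConfig(nSim = 10L, seed = 1L))
  # endpoints excluded: 1001, 1999, 5500 count; 1000 and 2000 do not
  expect_equal(pe@observed, 3)
  set.seed(19)
  ss2 <- siteSetAt(sample(c("c1", "c2"), 400, TRUE),
                   sample.int(400000, 400) + 1000L, "F", genome2)
  pairs2 <- data.frame(chrom = sample(c("c1", "c2"), 60, TRUE),
                       a = sample.int(300000, 60))
  pairs2$b <- pairs2$a + sample.int(30000, 60)
  pe2 <- interveningEnrichment(ss2, pairs2, genome2,
                               enrichmentConfig(nSim = 5L, seed = 2L))
  expect_equal(pe2@observed,
               bfIntervening(as.character(seqnames(ss2)),
                             siteMidpoints(ss2), pairs2))
  expect_error(interveningEnrichment(ss2, pairs2[0, ], genome2), "nonempty")
})

test_that("fixed seeds make enrichment results identical to the last bit", {
  set.seed(4)
  ss <- siteSetAt("c1", sample.int(9e5, 200), "F", genome2)
  pairs <- data.frame(chrom = "c1", a = seq(1e5, 5e5, 1e5))
  pairs$b <- pairs$a + 20000L
  cfg <- enrichmentConfig(nSim = 50L, seed = 99L)
  p1 <- interveningEnrichment(ss, pairs, genome2, cfg)
  p2 <- interveningEnrichment(ss, pairs, genome2, cfg)
  expect_identical(asPairRow(p1), asPairRow(p2))
})

test_that("active promoter calling is strictly conjunctive", {
  gff <- tinyGffFile()
  gm <- readGenes(gff)
  # gene gA: TSS at 1000 (+). Build evidence around it.
  h3 <- siteSetAt("2L", 1000L, "H3K4me3", width = 300L)
  pol <- siteSetAt("2L", 1100L, "PolII", width = 300L)
  rnaHit <- siteSetAt("2L", 1200L, "RNA", width = 100L)   # inside exon 1
  rnaMiss <- siteSetAt("2L", 1550L, "RNA", width = 20L)   # in the intron
  act <- callActivePromoters(gm, h3, pol, rnaHit)
  expect_true(act$active[act$gene_id == "gA"])
  act2 <- callActivePromoters(gm, h3, pol, rnaMiss)
  expect_false(act2$active[act2$gene_id == "gA"])
  empty <- siteSetAt(character(), integer(), "x")
  act3 <- callActivePromoters(gm, empty, pol, rnaHit)
  expect_false(any(act3$active))
})

test_that("stratified enrichment is invariant under label swap", {
  cfg <- scenarioConfig(chromLengths = c(c1 = 2e6), nGenes = 150L,
                        factors = "A", nSites = 300L, seed = 33L)
  scen <- generateScenario(cfg)
  act <- callActivePromoters(scen$genes, scen$activity$h3k4me3,
                             scen$activity$polII, scen$activity$rna)
  pairs <- selectPromoterPairs(scen$genes, "adjacent")
  ecfg <- enrichmentConfig(nSim = 50L, seed = 7L)
  r1 <- stratifiedPairEnrichment(scen$sites$A, pairs, act, scen$genome, ecfg)
  actSwap <- act
  actSwap$active <- !actSwap$active
  r2 <- stratifiedPairEnrichment(scen$sites$A, pairs, actSwap, scen$genome,
                                 ecfg)
  expect_equal(asPairRow(r1$differential), asPairRow(r2$differential))
  expect_equal(asPairRow(r1$non_differential),
               asPairRow(r2$non_differential))
  # all-active labels empty the differential stratum
  actAll <- act; actAll$active <- TRUE
  r3 <- stratifiedPairEnrichment(scen$sites$A, pairs, actAll, scen$genome,
                                 ecfg)
  expect_null(r3$differential)
  expect_false(is.null(r3$non_differential))
  # unlabeled endpoint errors
  expect_error(stratifiedPairEnrichment(scen$sites$A, pairs, act[0, ],
                                        scen$genome, ecfg), "label")
})

test_that("CRM partition builds the three pair classes", {
  cfg <- scenarioConfig(chromLengths = c(c1 = 2e6), nGenes = 100L,
                        factors = "A", nSites = 300L, nCrms = 40L,
                        seed = 44L)
  scen <- generateScenario(cfg)
  res <- crmPartitionEnrichment(scen$sites$A, scen$crms, scen$genes,
                                scen$genome, enrichmentConfig(nSim = 30L,
                                                              seed = 2L))
  expect_s4_class(res$target, "PairEnrichment")
  expect_s4_class(res$non_target, "PairEnrichment")
  # genes sampled with replacement leave some multi-CRM genes
  expect_false(is.null(res$crm_crm))
  expect_equal(res$crm_crm@nPairs,
               sum(pmax(table(scen$crms$target_gene) - 1L, 0L)))
  # a CRM pointing at a gene id with no TSS errors
  badCrm <- scen$crms[1, ]
  badCrm$target_gene <- "nonexistent"
  expect_error(crmPartitionEnrichment(scen$sites$A, badCrm, scen$genes,
                                      scen$genome), "TSS")
})

test_that("site categories partition with the documented precedence", {
  gm <- readGenes(tinyGffFile())
  genomeT <- makeGenome(c("2L", "2R"), c(10000L, 10000L))
  # gA (+, GFF 1001..2000): exons 1001-1400, 1601-2000; no UTR features
  # in this fixture, so precedence runs exon > intron > intergenic.
  ss <- siteSetAt(c("2L", "2L", "2L"), c(1200L, 1500L, 4000L), "F",
                  width = 10L)
  res <- annotateSiteCategories(ss, gm, genomeT)
  expect_equal(unname(res$counts["exon"]), 1L)
  expect_equal(unname(res$counts["intron"]), 1L)
  expect_equal(unname(res$counts["intergenic"]), 1L)
  expect_equal(sum(res$counts), length(ss))
  expect_equal(sum(res$genome_fraction), 1)
  # UTR precedence: a 5' UTR inside an exon classifies as UTR
  cfg <- scenarioConfig(chromLengths = c(c1 = 1e6), nGenes = 40L,
                        factors = "A", nSites = 200L, seed = 3L)
  scen <- generateScenario(cfg)
  u5 <- utr5Ranges(scen$genes)[1]
  mp <- as.integer((start(u5) - 1 + end(u5)) %/% 2)
  ss2 <- siteSetAt(as.character(seqnames(u5)), mp, "F", width = 4L)
  res2 <- annotateSiteCategories(ss2, scen$genes, scen$genome)
  expect_equal(unname(res2$counts["utr5"]), 1L)
})
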