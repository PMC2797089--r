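smallCfg <- function(seed = 1L, ...) {
  scenarioConfig(chromLengths = c(c1 = 1e6, c2 = 1e6), nGenes = 60L,
                 nSites = 100L, nCrms = 20L, seed = seed, ...)
}

test_that("same seed reproduces the scenario byte for byte", {
  s1 <- generateScenario(smallCfg(seed = 9L))
  s2 <- generateScenario(smallCfg(seed = 9L))
  expect_identical(start(geneRanges(s1$genes)), start(geneRanges(s2$genes)))
  expect_identical(siteMidpoints(s1$sites[[1]]), siteMidpoints(s2$sites[[1]]))
  expect_identical(trackValues(s1$track), trackValues(s2$track))
  expect_identical(s1$truth$activity$active, s2$truth$activity$active)
  d1 <- tempfile(); d2 <- tempfile()
  writeScenario(s1, d1); writeScenario(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("forced promoter-geometry fractions are honoured", {
  s0 <- generateGenomeAndGenes(smallCfg(seed = 2L, fracDivergent = 0))
  expect_null(s0$truth$divergent_pairs)
  s1 <- generateGenomeAndGenes(smallCfg(seed = 3L, fracAltPromoter = 1))
  expect_true(all(mcols(geneRanges(s1$genes))$alt_promoter))
  # every gene then has >= 2 distinct TSS
  tss <- tssPoints(s1$genes)
  expect_true(all(table(tss$gene_id) >= 2))
  s2 <- generateGenomeAndGenes(smallCfg(seed = 4L, fracAltPromoter = 0))
  expect_false(any(mcols(geneRanges(s2$genes))$alt_promoter))
})

test_that("realized divergent fraction matches its binomial target", {
  p <- 0.5
  n <- 200L
  fr <- vapply(1:10, function(sd) {
    cfg <- scenarioConfig(chromLengths = c(c1 = 4e6, c2 = 4e6),
                          nGenes = n, fracDivergent = p, seed = sd)
    generateGenomeAndGenes(cfg)$truth$frac_divergent_realized
  }, 0)
  sdv <- sqrt(p * (1 - p) / (n / 2))
  expect_true(all(abs(fr - p) <= 3 * sdv))
  # and the realized pairs actually satisfy the divergent selector
  cfg <- scenarioConfig(chromLengths = c(c1 = 4e6), nGenes = 100L,
                        fracDivergent = 0.6, fracAltPromoter = 0, seed = 5L)
  gg <- generateGenomeAndGenes(cfg)
  sel <- selectPromoterPairs(gg$genes, "divergent")
  tp <- gg$truth$divergent_pairs
  key <- paste(sel$chrom, sel$a, sel$b)
  expect_true(all(paste(tp$chrom, tp$tss1, tp$tss2) %in% key))
})

test_that("infeasible gene packing raises a capacity error", {
  cfg <- scenarioConfig(chromLengths = c(tiny = 20000L), nGenes = 50L,
                        seed = 1L)
  expect_error(generateGenomeAndGenes(cfg), "capacity")
})

test_that("planted promoter fraction is recovered within binomial error", {
  cfg <- scenarioConfig(seed = 21L, factors = "A", nSites = 1000L,
                        promoterFrac = 0.8)
  gg <- generateGenomeAndGenes(cfg)
  st <- generateSites(cfg, gg$genome, gg$genes, gg$truth$divergent_pairs)
  pf <- st$truth$promoter_frac_realized["A"]
  expect_true(abs(pf - 0.8) <= 3 * sqrt(0.8 * 0.2 / 1000))
  # and the sites really are promoter-proximal
  sp <- splitByPromoterProximity(st$sites$A, gg$genes)
  expect_gt(length(sp$promoter) / 1000, 0.7)
})

test_that("full co-binding places every donor site within 250 bp", {
  cb <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  cb["A", "B"] <- 1
  cfg <- smallCfg(seed = 6L, factors = c("A", "B"), cobind = cb)
  gg <- generateGenomeAndGenes(cfg)
  st <- generateSites(cfg, gg$genome, gg$genes, gg$truth$divergent_pairs)
  frac <- bfOverlapFraction(
    as.character(seqnames(st$sites$A)), siteMidpoints(st$sites$A),
    as.character(seqnames(st$sites$B)), siteMidpoints(st$sites$B))
  expect_equal(frac, 1)
})

test_that("noiseless domain track is a step function matching truth", {
  cfg <- smallCfg(seed = 7L, sigma = 0, muIn = 2, muOut = 0)
  gg <- generateGenomeAndGenes(cfg)
  dt <- generateDomainTrack(cfg, gg$genome)
  expect_setequal(unique(trackValues(dt$track)), c(0, 2))
  # probes valued mu_in are exactly those inside true domains
  tr <- dt$truth
  pts <- GRanges(trackChroms(dt$track),
                 IRanges(trackPositions(dt$track) + 1L, width = 1L))
  inside <- countOverlaps(pts, tr) > 0
  expect_identical(trackValues(dt$track) == 2, inside)
})

test_that("zero domains yields pure background and bad specs error", {
  cfg <- smallCfg(seed = 8L, nDomains = 0L, sigma = 0.5, muOut = 0)
  gg <- generateGenomeAndGenes(cfg)
  dt <- generateDomainTrack(cfg, gg$genome)
  expect_equal(length(dt$truth), 0L)
  v <- trackValues(dt$track)
  expect_lt(abs(mean(v)), 3 * 0.5 / sqrt(length(v)))
  cfg2 <- smallCfg(seed = 8L, probeSpacing = 0L)
  expect_error(generateDomainTrack(cfg2, gg$genome), "probe_spacing")
  cfg3 <- smallCfg(seed = 8L, muIn = 0, muOut = 1)
  expect_error(generateDomainTrack(cfg3, gg$genome), "mu_in")
})

test_that("domain-track means match their generating distribution", {
  cfg <- scenarioConfig(chromLengths = c(c1 = 2e6), nGenes = 30L,
                        nDomains = 10L, domainMeanLen = 20000L,
                        muIn = 2, muOut = 0, sigma = 0.5, seed = 13L)
  gg <- generateGenomeAndGenes(cfg)
  dt <- generateDomainTrack(cfg, gg$genome)
  pts <- GRanges(trackChroms(dt$track),
                 IRanges(trackPositions(dt$track) + 1L, width = 1L))
  inside <- countOverlaps(pts, dt$truth) > 0
  vin <- trackValues(dt$track)[inside]
  expect_true(abs(mean(vin) - 2) <= 3 * 0.5 / sqrt(length(vin)))
})

test_that("activity evidence is exhaustive at p=1 and absent at p=0", {
  cfg1 <- smallCfg(seed = 10L, pActive = 1)
  gg <- generateGenomeAndGenes(cfg1)
  act <- generateActivityEvidence(cfg1, gg$genes)
  called <- callActivePromoters(gg$genes, act$h3k4me3, act$polII, act$rna)
  expect_true(all(called$active))
  cfg0 <- smallCfg(seed = 10L, pActive = 0)
  act0 <- generateActivityEvidence(cfg0, gg$genes)
  called0 <- callActivePromoters(gg$genes, act0$h3k4me3, act0$polII,
                                 act0$rna)
  expect_false(any(called0$active))
  expect_equal(length(act0$h3k4me3), 0L)
})
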