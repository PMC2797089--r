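hmmCfg <- function(seed, sigma = 0.5) {
  scenarioConfig(chromLengths = c(cL = 5e5), nGenes = 15L, nSites = 30L,
                 nDomains = 20L, domainMeanLen = 5000L,
                 muIn = 2, muOut = 0, sigma = sigma, probeSpacing = 50L,
                 seed = seed)
}

hmmScenario <- function(seed, sigma = 0.5) {
  cfg <- hmmCfg(seed, sigma)
  gg <- generateGenomeAndGenes(cfg)
  dt <- generateDomainTrack(cfg, gg$genome)
  list(genome = gg$genome, track = dt$track, truth = dt$truth)
}

test_that("noiseless two-valued tracks are fitted and decoded exactly", {
  sc <- hmmScenario(1L, sigma = 0)
  expect_warning(p <- fitDomainHmm(sc$track, seed = 1L), "floor")
  expect_equal(hmmMeans(p), c(0, 2), tolerance = 1e-6)
  ds <- decodeDomains(sc$track, p, minLen = 1000L)
  tr <- sc$truth[width(sc$truth) >= 1000L]
  dg <- domainRanges(ds)
  # every decoded domain nests in a true domain (probes quantise edges)
  expect_equal(length(dg), length(tr))
  expect_true(all(countOverlaps(dg, tr) == 1))
  d0 <- abs(start(dg) - start(tr)) + abs(end(dg) - end(tr))
  expect_true(all(d0 <= 2 * 50L))
})

test_that("log-likelihood is monotone and parameters recover the truth", {
  errs <- c(); recalls <- c()
  for (sd in 1:3) {
    sc <- hmmScenario(sd)
    p <- fitDomainHmm(sc$track, seed = sd)
    expect_true(all(diff(hmmLogLik(p)) > -1e-8))
    errs <- c(errs, mean(abs(hmmMeans(p) - c(0, 2))))
    ds <- decodeDomains(sc$track, p)
    tb <- sort(c(start(sc$truth) - 1L, end(sc$truth)))
    db <- mcols(boundaryPoints(ds))$pos
    recalls <- c(recalls, mean(vapply(tb, function(b)
      any(abs(db - b) <= 100L), TRUE)))
  }
  expect_lt(mean(errs), 0.1)
  expect_gte(mean(recalls), 0.9)
})

test_that("decoding respects minLen and extreme inputs", {
  sc <- hmmScenario(5L)
  p <- fitDomainHmm(sc$track, seed = 2L)
  ds <- decodeDomains(sc$track, p, minLen = 10000000L)
  expect_equal(length(domainRanges(ds)), 0L)
  expect_equal(length(boundaryPoints(ds)), 0L)
  # decoding is deterministic
  d1 <- decodeDomains(sc$track, p)
  d2 <- decodeDomains(sc$track, p)
  expect_identical(start(domainRanges(d1)), start(domainRanges(d2)))
  expect_error(fitDomainHmm(SignalTrack("c", 1:5 * 10L, rnorm(5))), "probes")
})

test_that("Pearson chi-squared matches the hand formula", {
  r <- pearsonChi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- pearsonChi2(matrix(c(30, 5, 5, 30), 2))
  # n (ad - bc)^2 / (r1 r2 c1 c2) = 70 * 875^2 / 35^4
  expect_equal(r2$statistic, 70 * (30 * 30 - 5 * 5)^2 / 35^4,
               tolerance = 1e-10)
  expect_equal(round(r2$statistic, 2), 35.71)
  expect_equal(r2$df, 1L)
  # agreement with the uncorrected textbook test
  ref <- suppressWarnings(chisq.test(matrix(c(30, 5, 5, 30), 2),
                                     correct = FALSE))
  expect_equal(r2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-10)
  expect_false(pearsonChi2(matrix(c(0, 0, 5, 30), 2))$computable)
})

test_that("boundary contingency test wires distances and marginals", {
  sc <- hmmScenario(6L)
  p <- fitDomainHmm(sc$track, seed = 3L)
  ds <- decodeDomains(sc$track, p)
  b <- mcols(boundaryPoints(ds))$pos
  # plant sites exactly at half the boundaries, TSS at the other half
  sites <- siteSetAt("cL", b[seq(1, length(b), 2)] + 10L, "F")
  tssDf <- data.frame(chrom = "cL", pos = b[seq(2, length(b), 2)] + 10L)
  res <- boundaryTssIndependence(sites, tssDf, ds, window = 100L)
  expect_true(res$computable)
  expect_equal(sum(res$table), length(b))
  expect_gt(res$statistic, 0)
  # no boundaries -> not computable
  empty <- new("DomainSet", domains = GRanges(), boundaries = GRanges(),
               source = "x")
  expect_false(boundaryTssIndependence(sites, tssDf, empty)$computable)
  expect_error(boundaryTssIndependence(sites, tssDf, ds, window = 0), "window")
})

test_that("inside/outside enrichment detects planted placement", {
  sc <- hmmScenario(7L)
  tr <- sc$truth
  ecfg <- enrichmentConfig(nSim = 200L, seed = 5L)
  # sites planted only outside true domains
  set.seed(8)
  mids <- integer(0)
  while (length(mids) < 150) {
    cand <- sample.int(499000L, 300) + 500L
    pts <- GRanges("cL", IRanges(cand + 1L, width = 1L))
    cand <- cand[countOverlaps(pts, tr) == 0]
    mids <- c(mids, cand)
  }
  ssOut <- siteSetAt("cL", mids[1:150], "F", sc$genome)
  io <- insideOutsideEnrichment(ssOut, tr, sc$genome, ecfg)
  expect_equal(io$inside@observed, 0)
  expect_lt(io$inside@pDepleted, 0.05)
  expect_gt(io$outside@log2Enrichment, 0)
  # domains covering the whole genome leave nothing outside
  whole <- GRanges("cL", IRanges(1, 5e5))
  io2 <- insideOutsideEnrichment(ssOut, whole, sc$genome, ecfg)
  expect_equal(io2$outside@observed, 0)
})

test_that("boundary profile peaks where sites are planted", {
  sc <- hmmScenario(9L)
  ds <- decodeDomains(sc$track, fitDomainHmm(sc$track, seed = 4L))
  b <- boundaryPoints(ds)
  ecfg <- enrichmentConfig(nSim = 200L, seed = 6L)
  # plant sites 300-500 bp outside each boundary
  off <- ifelse(as.character(strand(b)) == "-", -400L, 400L)
  ss <- siteSetAt(as.character(seqnames(b)), mcols(b)$pos + off, "F",
                  sc$genome)
  pr <- boundaryDistanceProfile(ss, ds, sc$genome, cfg = ecfg)
  tab <- profileTable(pr)
  peak <- tab[tab$bin_lo == 400, ]
  expect_gt(peak$observed, peak$null_hi)
  expect_equal(peak$p_enriched, 1 / 201)
  # all planted offsets are positive (outside)
  inner <- tab[tab$bin_hi <= 0, ]
  expect_true(all(inner$observed == 0))
})

test_that("synteny blocks reuse the domain statistics", {
  genome <- makeGenome("cL", 5e5)
  blocks <- GRanges("cL", IRanges(c(1, 200001, 350001),
                                  c(200000, 350000, 500000)))
  set.seed(10)
  ss <- siteSetAt("cL", sample.int(490000L, 200) + 2000L, "F", genome)
  res <- syntenyBlockEnrichment(ss, blocks, genome,
                                tss = data.frame(chrom = "cL",
                                                 pos = seq(5e4, 4.5e5, 5e4)),
                                cfg = enrichmentConfig(nSim = 100L,
                                                       seed = 3L))
  # blocks partition the chromosome: everything is inside
  expect_equal(res$inside@observed, 200)
  expect_equal(res$outside@observed, 0)
  # 2 internal breakpoints, both edges of the middle block
  expect_false(is.null(res$profile))
  expect_false(is.null(res$chisq))
  # single whole-chromosome block: no breakpoints, no profile
  res2 <- syntenyBlockEnrichment(ss, GRanges("cL", IRanges(1, 5e5)), genome,
                                 cfg = enrichmentConfig(nSim = 10L,
                                                        seed = 1L))
  expect_null(res2$profile)
})
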