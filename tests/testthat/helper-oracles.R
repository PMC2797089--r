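# Brute-force reference implementations used as independent oracles, and
# tiny fixture builders. These deliberately use the simplest possible
# O(n^2) logic so they share nothing with the package's fast paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# all-pairs fraction of A sites with a B midpoint strictly within maxDist
bfOverlapFraction <- function(chromA, midA, chromB, midB, maxDist = 250) {
  if (!length(midA)) return(NA_real_)
  hits <- vapply(seq_along(midA), function(i)
    any(chromB == chromA[i] & abs(midB - midA[i]) < maxDist), TRUE)
  mean(hits)
}

# union-find single-linkage components under the midpoint criterion
bfComponents <- function(chrom, mid, maxDist = 250) {
  n <- length(mid)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] && abs(mid[i] - mid[j]) < maxDist) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# nearest signed distance, one feature scan per site
bfSignedNearest <- function(chromS, midS, feat) {
  vapply(seq_along(midS), function(i) {
    sel <- feat$chrom == chromS[i]
    if (!any(sel)) return(NA_real_)
    p <- feat$pos[sel]; st <- feat$strand[sel]
    d <- midS[i] - p
    j <- which(abs(d) == min(abs(d)))
    j <- j[which.min(p[j])]   # ties -> smaller coordinate
    if (st[j] == "-") -d[j] else d[j]
  }, 0)
}

# total midpoints strictly between pair endpoints, summed over pairs
bfIntervening <- function(chromS, midS, pairs) {
  tot <- 0L
  for (r in seq_len(nrow(pairs)))
    tot <- tot + sum(chromS == pairs$chrom[r] &
                       midS > pairs$a[r] & midS < pairs$b[r])
  tot
}

# exact hypergeometric tails by factorial summation
bfHyper <- function(k, K, n, N, upper = TRUE) {
  xs <- if (upper) k:min(K, n) else 0:k
  sum(vapply(xs, function(x)
    choose(n, x) * choose(N - n, K - x), 0)) / choose(N, K)
}

# random valid BED content
randomBedLines <- function(n, chroms = c("2L", "2R", "X"), maxLen = 1e5) {
  s <- sample.int(maxLen, n, replace = TRUE) - 1L
  w <- sample.int(500L, n, replace = TRUE)
  sprintf("%s\t%d\t%d", sample(chroms, n, replace = TRUE), s, s + w)
}

writeTempLines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# a hand-written GFF3 with one + gene, one - gene, one alt-promoter gene
tinyGffFile <- function() {
  writeTempLines(c(
    "##gff-version 3",
    "2L\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "2L\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "2L\tsrc\texon\t1001\t1400\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
    "2L\tsrc\texon\t1601\t2000\t.\t+\t.\tID=gA.e2;Parent=gA.t1",
    "2L\tsrc\tgene\t5001\t8000\t.\t-\t.\tID=gB",
    "2L\tsrc\tmRNA\t5001\t8000\t.\t-\t.\tID=gB.t1;Parent=gB",
    "2L\tsrc\texon\t5001\t5800\t.\t-\t.\tID=gB.e1;Parent=gB.t1",
    "2L\tsrc\texon\t7001\t8000\t.\t-\t.\tID=gB.e2;Parent=gB.t1",
    "2R\tsrc\tgene\t1\t3000\t.\t+\t.\tID=gC",
    "2R\tsrc\tmRNA\t1\t3000\t.\t+\t.\tID=gC.t1;Parent=gC",
    "2R\tsrc\texon\t1\t3000\t.\t+\t.\tID=gC.e1;Parent=gC.t1",
    "2R\tsrc\tmRNA\t501\t3000\t.\t+\t.\tID=gC.t2;Parent=gC",
    "2R\tsrc\texon\t501\t3000\t.\t+\t.\tID=gC.e2;Parent=gC.t2"
  ))
}

# SiteSet from parallel vectors of midpoints (width 100); midpoints are
# clamped away from position 0 so the interval stays valid
siteSetAt <- function(chrom, mid, factor = "F", genome = NULL, width = 100L) {
  mid <- pmax(width %/% 2L, as.integer(mid))
  SiteSet(chrom, mid - width %/% 2L, mid + width - width %/% 2L,
          factorName = factor, genome = genome)
}

# brute-force score-tail oracle: enumerate all 4^w sequences
bfTailThreshold <- function(pwm, p, resolution = 1e-3) {
  M <- round(insulatR::pwmLogOdds(pwm) / resolution)
  w <- ncol(M)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- vapply(seq_len(nrow(grid)), function(i)
    sum(M[cbind(grid[i, ], seq_len(w))]), 0)
  prob <- vapply(seq_len(nrow(grid)), function(i)
    prod(pwm@background[grid[i, ]]), 0)
  o <- order(scores)
  scores <- scores[o]; prob <- prob[o]
  tail <- rev(cumsum(rev(prob)))
  uniq <- !duplicated(scores)
  s <- scores[uniq]
  tl <- tail[uniq]
  s[which(tl <= p)[1]] * resolution
}

consensusPwm <- function(letters, strong = 0.97) {
  m <- matrix((1 - strong) / 3, 4, length(letters))
  for (j in seq_along(letters))
    m[match(letters[j], c("A", "C", "G", "T")), j] <- strong
  makePWM(m, name = paste(letters, collapse = ""))
}
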