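test_that("threshold DP matches exhaustive enumeration", {
  set.seed(2)
  for (rep in 1:3) {
    probs <- matrix(rgamma(20, 1), 4, 5)
    pwm <- makePWM(probs)
    for (p in c(4^-4, 1e-3, 0.05)) {
      expect_equal(pwmThresholdFromPvalue(pwm, p),
                   bfTailThreshold(pwm, p), tolerance = 1e-9)
    }
  }
  # p near 1 admits (nearly) everything: the threshold drops to the
  # bottom of the attainable score range, matching the oracle
  pwm <- makePWM(matrix(rgamma(16, 1), 4, 4))
  M <- pwmLogOdds(pwm)
  expect_equal(pwmThresholdFromPvalue(pwm, 0.999),
               bfTailThreshold(pwm, 0.999), tolerance = 1e-9)
  # p below the attainable granularity warns and returns the max score
  expect_warning(t <- pwmThresholdFromPvalue(pwm, 1e-12), "granularity")
  expect_equal(t, sum(apply(round(M / 1e-3), 2, max)) * 1e-3,
               tolerance = 1e-9)
  expect_error(pwmThresholdFromPvalue(pwm, 0), "p must be")
})

test_that("only the consensus passes at p = 4^-width for a sharp PWM", {
  # one dominant letter per column; p = 4^-4 admits exactly one word
  pwm <- consensusPwm(c("A", "C", "G", "T"))
  thr <- pwmThresholdFromPvalue(pwm, 4^-4)
  hits <- scanInstances("AACGTA", pwm, thr)
  fw <- hits[hits$strand == "+", ]
  expect_equal(fw$start0, 1L)
  # random scan: no non-consensus forward window passes
  set.seed(9)
  seqr <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  h <- scanInstances(seqr, pwm, thr)
  fwh <- h[h$strand == "+", ]
  for (s in fwh$start0)
    expect_equal(substr(seqr, s + 1, s + 4), "ACGT")
})

test_that("scanning skips N windows and is strand symmetric", {
  pwm <- consensusPwm(c("A", "C", "G", "T", "A"))
  thr <- pwmThresholdFromPvalue(pwm, 4^-5)
  expect_equal(nrow(scanInstances("NNNNNNNNNN", pwm, thr)), 0L)
  expect_equal(nrow(scanInstances("ACNGTACGTA", pwm, thr)[
    scanInstances("ACNGTACGTA", pwm, thr)$start0 < 3, ]), 0L)
  set.seed(4)
  seqr <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seqr, "")[[1]]),
                                     collapse = ""))
  h1 <- scanInstances(seqr, pwm, thr)
  h2 <- scanInstances(rc, pwm, thr)
  # mirrored coordinates, flipped strands
  L <- nchar(seqr); w <- pwmWidth(pwm)
  key1 <- sort(paste(h1$start0, h1$strand))
  key2 <- sort(paste(L - h2$end0, chartr("+-", "-+", h2$strand)))
  expect_equal(key1, key2)
})

test_that("instance counts on random sequence respect the Poisson bound", {
  set.seed(21)
  pwm <- makePWM(matrix(rgamma(32, 1), 4, 8))
  p <- 4^-6
  thr <- pwmThresholdFromPvalue(pwm, p)
  L <- 50000L
  seqr <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  n <- nrow(scanInstances(seqr, pwm, thr))
  lambda <- 2 * (L - 8 + 1) * p
  expect_gte(n, qpois(0.005, lambda))
  expect_lte(n, qpois(0.995, lambda))
})

test_that("uniquely bound windows respect separation, flanks, exclusions", {
  sets <- list(
    A = siteSetAt("c1", c(10000L, 20000L, 30000L), "A"),
    B = siteSetAt("c1", c(10999L, 25000L), "B"))
  # site at 10000 is 999 bp from a B centre -> excluded; 20000 and 30000
  # are >= 1000 bp away from every B centre -> kept
  win <- uniqueBoundWindows(sets, "A")
  expect_equal(start(win) - 1L, c(20000L - 100L, 30000L - 100L))
  expect_equal(width(win), c(201L, 201L))
  # no other factors: everything is eligible
  winAll <- uniqueBoundWindows(sets["A"], "A")
  expect_equal(length(winAll), 3L)
  # an exclusion clipping half a window
  excl <- GRanges("c1", IRanges(20001L, 20050L))
  winEx <- uniqueBoundWindows(sets, "A", exclusions = excl)
  expect_true(all(width(GenomicRanges::intersect(winEx, excl)) == 0))
  # a window fully inside an exclusion disappears
  excl2 <- GRanges("c1", IRanges(29000L, 31000L))
  winEx2 <- uniqueBoundWindows(sets, "A", exclusions = excl2)
  expect_equal(start(winEx2) - 1L, 20000L - 100L)
  expect_error(uniqueBoundWindows(sets, "Z"), "focal")
})

test_that("hypergeometric p-values equal exact factorial summation", {
  # documented small case: all 5 draws in a 5-bp region of 50
  r <- hypergeometricEnrichment(5, 5, 5, 50)
  expect_equal(unname(r["p_enriched"]), 1 / choose(50, 5), tolerance = 1e-12)
  r0 <- hypergeometricEnrichment(0, 5, 5, 50)
  expect_equal(unname(r0["p_depleted"]), choose(45, 5) / choose(50, 5),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    N <- sample(20:100, 1)
    n <- sample.int(N, 1)
    K <- sample.int(N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    r <- hypergeometricEnrichment(k, K, n, N)
    expect_equal(unname(r["p_enriched"]), bfHyper(k, K, n, N, TRUE),
                 tolerance = 1e-10)
    expect_equal(unname(r["p_depleted"]), bfHyper(k, K, n, N, FALSE),
                 tolerance = 1e-10)
  }
  # a count at the null expectation is not significant either way
  r <- hypergeometricEnrichment(10, 100, 100, 1000)
  expect_gte(unname(r["p_enriched"]), 0.05)
  expect_gte(unname(r["p_depleted"]), 0.05)
  expect_error(hypergeometricEnrichment(6, 5, 5, 50), "k must not")
})

test_that("Wilson bounds follow the closed form and the ratio is conservative", {
  # direct formula at p-hat = 0.5, n = 100, z = 1.5
  phat <- 0.5; n <- 100; z <- 1.5
  ref <- (phat + z^2 / (2 * n) -
            z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(wilsonBound(0.5, 100, 1.5, lower = TRUE), ref,
               tolerance = 1e-12)
  expect_equal(round(wilsonBound(0.5, 100, 1.5, TRUE), 4), 0.4258)
  # equal counts on both sides give a ratio below 1
  r <- wilsonRatioEnrichment(50, 100, 50, 100)
  expect_lt(r$ratio, 1)
  expect_false(r$infinite)
  # zero-control with z = 0 flags an infinite ratio
  r2 <- wilsonRatioEnrichment(100, 100, 0, 100, z = 0)
  expect_true(r2$infinite)
  # monotone: more bound hits never lower, more control hits never raise
  rk <- vapply(seq(10, 90, 10), function(k)
    wilsonRatioEnrichment(k, 100, 20, 100)$ratio, 0)
  expect_true(all(diff(rk) >= 0))
  rc <- vapply(seq(10, 90, 10), function(k)
    wilsonRatioEnrichment(50, 100, k, 100)$ratio, 0)
  expect_true(all(diff(rc) <= 0))
})

test_that("shuffled control PWMs permute columns reproducibly", {
  pwm <- makePWM(matrix(c(0.9, 0.05, 0.03, 0.02,
                          0.1, 0.6, 0.2, 0.1), 4, 2))
  s <- shuffledControlPwms(pwm, 1, seed = 1L)
  expect_equal(s[[1]]@probs, pwm@probs[, 2:1], ignore_attr = TRUE)
  pwm5 <- makePWM(matrix(rgamma(20, 1), 4, 5))
  s5a <- shuffledControlPwms(pwm5, 10, seed = 7L)
  s5b <- shuffledControlPwms(pwm5, 10, seed = 7L)
  expect_identical(lapply(s5a, function(x) x@probs),
                   lapply(s5b, function(x) x@probs))
  colEntropy <- function(m) sort(apply(m, 2, function(p)
    -sum(p * log(p + 1e-12))))
  for (s in s5a) {
    expect_equal(colEntropy(s@probs), colEntropy(pwm5@probs),
                 tolerance = 1e-12)
    expect_false(identical(s@probs, pwm5@probs))
  }
  expect_error(shuffledControlPwms(makePWM(matrix(0.25, 4, 1)), 1), "width")
})

test_that("MEME minimal format round-trips through the parser", {
  f <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "0.3 0.2 0.2 0.3", "",
    "MOTIF m1", "letter-probability matrix: alength= 4 w= 3",
    " 0.7 0.1 0.1 0.1",
    " 0.1 0.7 0.1 0.1",
    " 0.1 0.1 0.1 0.7"
  ), f)
  pwms <- readMemePwms(f)
  expect_equal(names(pwms), "m1")
  expect_equal(pwmWidth(pwms$m1), 3L)
  expect_equal(pwms$m1@probs[, 1], c(A = 0.7, C = 0.1, G = 0.1, T = 0.1))
  expect_equal(pwms$m1@background, c(0.3, 0.2, 0.2, 0.3))
})
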