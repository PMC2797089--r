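# Gaussian hidden Markov segmentation of broad chromatin-mark signal.
# A 2-state model with sticky transitions is the default reading of
# "HMM-based segmentation" for domain calling: one state per signal
# level, Baum-Welch fitting, Viterbi decoding, and boundary statistics
# downstream. Transitions are per probe, not per bp (an approximation
# under irregular probe spacing, documented in the vignette).

#' Fit a Gaussian HMM to a signal track by Baum-Welch
#'
#' Chromosomes are treated as independent observation sequences.
#' Initialisation is k-means on the probe values (deterministic given
#' \code{seed}) with sticky uniform transitions (0.99 self-transition).
#' Emission variances are floored at 1e-6 of the data variance, with a
#' warning when the floor binds. States are returned ordered by
#' increasing mean.
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param nStates number of states (default 2).
#' @param seed integer seed for the k-means initialisation.
#' @param maxIter maximum EM iterations (default 500).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @return an \linkS4class{HmmParams}; \code{hmmLogLik()} exposes the
#'   non-decreasing per-iteration log-likelihood trace.
#' @export
fitDomainHmm <- function(track, nStates = 2L, seed = NULL,
                         maxIter = 500L, tol = 1e-6) {
  y <- trackValues(track)
  if (length(y) < 10L * nStates)
    stop("need at least 10 probes per state")
  seqs <- split(y, trackChroms(track))
  k <- nStates
  vFloor <- 1e-6 * max(var(y), .Machine$double.eps)

  km <- withSeed(if (is.null(seed)) 1L else seed,
                 kmeans(y, centers = k, nstart = 5))
  o <- order(km$centers)
  mu <- as.numeric(km$centers[o])
  sig2 <- vapply(o, function(j) {
    v <- var(y[km$cluster == j])
    if (!is.finite(v) || v < vFloor) vFloor else v
  }, 0)
  A <- matrix((1 - 0.99) / max(k - 1, 1), k, k)
  diag(A) <- if (k > 1) 0.99 else 1
  pi0 <- rep(1 / k, k)

  ll <- numeric(0)
  flooring <- FALSE
  for (iter in seq_len(maxIter)) {
    totalLL <- 0
    g_sum <- matrix(0, length(y), k)   # posteriors, concatenated
    xi_sum <- matrix(0, k, k)
    pi_acc <- rep(0, k)
    offset <- 0L
    for (ys in seqs) {
      Tn <- length(ys)
      # scaled forward-backward (Rabiner c_t normalisation)
      B <- vapply(seq_len(k), function(j)
        dnorm(ys, mu[j], sqrt(sig2[j])), numeric(Tn))
      B <- matrix(pmax(B, 1e-300), nrow = Tn)
      al <- matrix(0, Tn, k)
      cs <- numeric(Tn)
      v <- pi0 * B[1, ]
      cs[1] <- sum(v); al[1, ] <- v / cs[1]
      for (t in 2:Tn) {
        v <- (al[t - 1, ] %*% A) * B[t, ]
        cs[t] <- sum(v)
        al[t, ] <- v / cs[t]
      }
      be <- matrix(0, Tn, k)
      be[Tn, ] <- 1
      for (t in (Tn - 1):1)
        be[t, ] <- (A %*% (B[t + 1, ] * be[t + 1, ])) / cs[t + 1]
      totalLL <- totalLL + sum(log(cs))
      g <- al * be
      g <- g / rowSums(g)
      g_sum[offset + seq_len(Tn), ] <- g
      pi_acc <- pi_acc + g[1, ]
      M <- (B * be) / cs            # rows 2..Tn used
      xi_sum <- xi_sum +
        A * crossprod(al[seq_len(Tn - 1), , drop = FALSE],
                      M[2:Tn, , drop = FALSE])
      offset <- offset + Tn
    }
    ll <- c(ll, totalLL)
    if (iter > 1 && abs(ll[iter] - ll[iter - 1]) < tol) break

    yAll <- unlist(seqs, use.names = FALSE)
    Nk <- colSums(g_sum)
    mu <- as.numeric(crossprod(g_sum, yAll) / Nk)
    sig2 <- vapply(seq_len(k), function(j)
      sum(g_sum[, j] * (yAll - mu[j])^2) / Nk[j], 0)
    if (any(sig2 < vFloor)) {
      flooring <- TRUE
      sig2 <- pmax(sig2, vFloor)
    }
    A <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.eps)
    A <- A / rowSums(A)
    pi0 <- pi_acc / sum(pi_acc)
  }
  if (flooring)
    warning("emission variance hit the floor (1e-6 of data variance)")
  o <- order(mu)
  new("HmmParams", means = mu[o], variances = sig2[o],
      transition = A[o, o, drop = FALSE], initial = pi0[o],
      logLik = ll, converged = length(ll) < maxIter)
}

viterbiPath <- function(y, params) {
  k <- length(params@means)
  lA <- log(params@transition)
  Tn <- length(y)
  lB <- vapply(seq_len(k), function(j)
    dnorm(y, params@means[j], sqrt(params@variances[j]), log = TRUE),
    numeric(Tn))
  lB <- matrix(lB, nrow = Tn)
  dp <- matrix(-Inf, Tn, k)
  bt <- matrix(0L, Tn, k)
  dp[1, ] <- log(params@initial) + lB[1, ]
  for (t in 2:Tn)
    for (j in seq_len(k)) {
      v <- dp[t - 1, ] + lA[, j]
      bt[t, j] <- which.max(v)
      dp[t, j] <- v[bt[t, j]] + lB[t, j]
    }
  path <- integer(Tn)
  path[Tn] <- which.max(dp[Tn, ])
  if (Tn > 1)
    for (t in (Tn - 1):1) path[t] <- bt[t + 1, path[t + 1]]
  path
}

#' Decode domains from a fitted HMM
#'
#' Viterbi-decodes the track and turns maximal runs of the highest-mean
#' state into domains spanning the first to last probe of each run.
#' Runs spanning less than \code{minLen} bp are discarded. Boundary
#' points are emitted at both edges of each kept domain; left edges
#' carry strand \code{-} and right edges \code{+} so that signed
#' distances from \code{\link{boundaryDistanceProfile}} are negative
#' inside the domain.
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param params an \linkS4class{HmmParams} fitted on the same signal
#'   scale.
#' @param minLen minimum domain span in bp (default 1000).
#' @param source id recorded on the result.
#' @return a \linkS4class{DomainSet}.
#' @export
decodeDomains <- function(track, params, minLen = 1000L,
                          source = "track") {
  chroms <- trackChroms(track)
  hi <- length(params@means)   # states ordered by mean
  doms <- NULL
  for (cn in unique(chroms)) {
    sel <- chroms == cn
    y <- trackValues(track)[sel]
    pos <- trackPositions(track)[sel]
    path <- viterbiPath(y, params)
    r <- rle(path == hi)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      s0 <- pos[starts[i]]
      e0 <- pos[ends[i]] + 1L
      if (e0 - s0 >= minLen)
        doms <- rbind(doms, data.frame(chrom = cn, s0 = s0, e0 = e0))
    }
  }
  if (is.null(doms)) {
    return(new("DomainSet", domains = GRanges(), boundaries = GRanges(),
               source = source))
  }
  doms <- doms[order(doms$chrom, doms$s0), , drop = FALSE]
  dgr <- GRanges(doms$chrom, IRanges(doms$s0 + 1L, doms$e0))
  bnd <- GRanges(rep(doms$chrom, 2),
                 IRanges(c(doms$s0, doms$e0) + 1L, width = 1L),
                 strand = rep(c("-", "+"), each = nrow(doms)),
                 side = rep(c("left", "right"), each = nrow(doms)),
                 pos = c(doms$s0, doms$e0))
  bnd <- BiocGenerics::sort(bnd, ignore.strand = TRUE)
  new("DomainSet", domains = dgr, boundaries = bnd, source = source)
}

#' Site enrichment inside versus outside domains
#'
#' Counts site midpoints inside and outside the domain set, each
#' normalised by the uniform permutation null.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param domains a \linkS4class{DomainSet} or \code{GRanges}.
#' @param genome \code{Seqinfo}.
#' @param cfg an \code{\link{enrichmentConfig}}.
#' @return list of \linkS4class{PairEnrichment}-shaped results,
#'   \code{inside} and \code{outside}.
#' @export
insideOutsideEnrichment <- function(sites, domains, genome,
                                    cfg = enrichmentConfig()) {
  dgr <- if (is(domains, "DomainSet")) domainRanges(domains) else domains
  chrom <- as.character(seqnames(sites))
  mid <- siteMidpoints(sites)
  dSplit <- lapply(split(dgr, as.character(seqnames(dgr))), function(g)
    list(s0 = start(g) - 1L, e0 = end(g)))
  insideCount <- function(ch, m) {
    n_in <- 0
    for (cn in unique(ch)) {
      d <- dSplit[[cn]]
      if (is.null(d)) next
      mm <- m[ch == cn]
      fi <- findInterval(mm, d$s0)
      n_in <- n_in + sum(fi > 0 & mm < d$e0[pmax(fi, 1L)])
    }
    n_in
  }
  obsIn <- insideCount(chrom, mid)
  obsOut <- length(sites) - obsIn
  lens <- seqlengths(genome)
  ci <- match(chrom, GenomeInfoDb::seqnames(genome))
  if (anyNA(ci)) stop("site on chromosome absent from genome")
  nullIn <- withSeed(cfg$seed, {
    vapply(seq_len(cfg$nSim), function(i)
      insideCount(chrom, runifInt(length(mid), lens[ci])), 0)
  })
  nullOut <- length(sites) - nullIn
  list(
    inside = pairEnrichmentFromCounts(obsIn, nullIn, "inside",
                                      length(dgr), cfg),
    outside = pairEnrichmentFromCounts(obsOut, nullOut, "outside",
                                       length(dgr), cfg)
  )
}

#' Positional profile around domain boundaries
#'
#' \code{\link{positionalProfile}} with the boundary points as oriented
#' features: negative offsets are inside the adjacent domain, positive
#' outside.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param domains a \linkS4class{DomainSet} (its boundaries are used) or
#'   a boundary data.frame with \code{chrom}, \code{pos}, \code{strand}.
#' @param genome \code{Seqinfo}.
#' @param bins bin edges (default \code{seq(-2000, 2000, 100)}).
#' @param cfg an \code{\link{enrichmentConfig}}.
#' @return an \linkS4class{EnrichmentProfile}.
#' @export
boundaryDistanceProfile <- function(sites, domains, genome,
                                    bins = seq(-2000L, 2000L, 100L),
                                    cfg = enrichmentConfig()) {
  feats <- if (is(domains, "DomainSet")) {
    b <- boundaryPoints(domains)
    data.frame(chrom = as.character(seqnames(b)), pos = mcols(b)$pos,
               strand = as.character(strand(b)), stringsAsFactors = FALSE)
  } else domains
  if (!nrow(feats)) stop("boundaries must be nonempty")
  positionalProfile(sites, feats, genome, bins, cfg)
}

#' Pearson chi-squared test of site/TSS boundary-overlap independence
#'
#' Builds the 2x2 contingency table over domain boundaries -- (has a
#' site midpoint within \code{window} bp) x (has a TSS within
#' \code{window} bp) -- and applies Pearson's chi-squared test without
#' continuity correction.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param tss data.frame with \code{chrom}, \code{pos}.
#' @param domains a \linkS4class{DomainSet} or boundary data.frame.
#' @param window overlap window in bp (default 1000; |distance| <=
#'   window counts as overlap).
#' @return list: \code{table}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{direction} ("enriched" when site-and-TSS-free
#'   boundaries are rarer than independence predicts), or
#'   \code{computable = FALSE} when a table marginal is zero.
#' @export
boundaryTssIndependence <- function(sites, tss, domains, window = 1000L) {
  if (window <= 0) stop("window must be > 0")
  feats <- if (is(domains, "DomainSet")) {
    b <- boundaryPoints(domains)
    data.frame(chrom = as.character(seqnames(b)), pos = mcols(b)$pos)
  } else domains
  if (is.null(feats) || !nrow(feats))
    return(list(computable = FALSE, reason = "no boundaries"))
  hasSite <- hasNeighbor(feats$chrom, feats$pos,
                         as.character(seqnames(sites)), siteMidpoints(sites),
                         window + 1L)
  hasTss <- hasNeighbor(feats$chrom, feats$pos, tss$chrom, tss$pos,
                        window + 1L)
  tab <- table(factor(hasSite, c(FALSE, TRUE)),
               factor(hasTss, c(FALSE, TRUE)))
  res <- pearsonChi2(unclass(tab))
  if (!res$computable) return(c(res, list(table = tab)))
  expSiteTss <- sum(hasSite) * sum(hasTss) / nrow(feats)
  list(table = tab, statistic = res$statistic, df = res$df,
       p_value = res$p_value,
       direction = if (tab[2, 2] >= expSiteTss) "enriched" else "depleted",
       computable = TRUE)
}

#' Pearson chi-squared statistic for a 2x2 table (no continuity
#' correction)
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return list: \code{statistic}, \code{df = 1}, \code{p_value},
#'   \code{computable} (FALSE when a marginal is zero).
#' @export
pearsonChi2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    return(list(computable = FALSE, reason = "zero marginal"))
  expd <- outer(rs, cs) / n
  stat <- sum((tab - expd)^2 / expd)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
       computable = TRUE)
}

#' Syntenic-block boundary analysis
#'
#' Treats syntenic blocks as domains: inside/outside enrichment,
#' breakpoint distance profile, and (when TSS are supplied) the
#' chi-squared independence test against TSS overlap.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param blocks \code{GRanges} of syntenic blocks.
#' @param genome \code{Seqinfo}.
#' @param tss optional data.frame with \code{chrom}, \code{pos}.
#' @param bins profile bin edges.
#' @param cfg an \code{\link{enrichmentConfig}}.
#' @param window chi-squared overlap window (default 1000 bp).
#' @return list: \code{inside}, \code{outside}, \code{profile},
#'   \code{chisq} (NULL without TSS). With no internal breakpoints the
#'   profile is NULL.
#' @export
syntenyBlockEnrichment <- function(sites, blocks, genome, tss = NULL,
                                   bins = seq(-2000L, 2000L, 100L),
                                   cfg = enrichmentConfig(),
                                   window = 1000L) {
  io <- insideOutsideEnrichment(sites, blocks, genome, cfg)
  # breakpoints: block edges not at chromosome ends
  lens <- seqlengths(genome)
  bchrom <- rep(as.character(seqnames(blocks)), 2)
  bpos <- c(start(blocks) - 1L, end(blocks))
  bstr <- rep(c("-", "+"), each = length(blocks))
  keep <- bpos > 0L & bpos < lens[bchrom]
  feats <- data.frame(chrom = bchrom[keep], pos = bpos[keep],
                      strand = bstr[keep], stringsAsFactors = FALSE)
  prof <- if (nrow(feats))
    positionalProfile(sites, feats, genome, bins, cfg) else NULL
  chi <- if (!is.null(tss) && nrow(feats))
    boundaryTssIndependence(sites, tss, feats[, c("chrom", "pos")],
                            window) else NULL
  list(inside = io$inside, outside = io$outside, profile = prof,
       chisq = chi)
}
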