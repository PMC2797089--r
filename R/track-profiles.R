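# Meta-profiles of probe-level signal around site midpoints, the
# promoter / non-promoter split, and per-class score summaries.

#' Average a signal track around site midpoints
#'
#' For each site, probes within \code{halfWidth} bp of the midpoint are
#' assigned to offset bins (probe position minus midpoint, binned in
#' \code{binWidth} bp steps); the profile is the per-bin mean over all
#' (site, probe) pairs. Bins without data have \code{n = 0} and
#' \code{NaN} mean.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param track a \linkS4class{SignalTrack}.
#' @param halfWidth window half-width in bp (default 3000).
#' @param binWidth bin width in bp (default 50).
#' @return a \linkS4class{MetaProfile}.
#' @export
aggregateTrack <- function(sites, track, halfWidth = 3000L, binWidth = 50L) {
  edges <- seq.int(-halfWidth, halfWidth, by = binWidth)
  nb <- length(edges) - 1L
  sums <- numeric(nb)
  counts <- integer(nb)
  chrom <- as.character(seqnames(sites))
  mid <- siteMidpoints(sites)
  tc <- trackChroms(track)
  for (cn in unique(chrom)) {
    psel <- tc == cn
    if (!any(psel)) next
    pos <- trackPositions(track)[psel]
    val <- trackValues(track)[psel]
    m <- mid[chrom == cn]
    lo <- findInterval(m - halfWidth - 1L, pos) + 1L  # first probe >= m-hw
    hi <- findInterval(m + halfWidth, pos)            # last probe <= m+hw
    keep <- hi >= lo
    if (!any(keep)) next
    m <- m[keep]; lo <- lo[keep]; hi <- hi[keep]
    cnt <- hi - lo + 1L
    pidx <- sequence(cnt) + rep(lo, cnt) - 1L
    offs <- pos[pidx] - rep(m, cnt)
    bidx <- findInterval(offs, edges)
    ok <- bidx >= 1L & bidx <= nb & offs < edges[nb + 1L]
    rs <- rowsum(val[pidx][ok], bidx[ok])
    sums[as.integer(rownames(rs))] <- sums[as.integer(rownames(rs))] + rs[, 1]
    counts <- counts + tabulate(bidx[ok], nbins = nb)
  }
  new("MetaProfile",
      offsets = (edges[-1] + edges[-length(edges)]) / 2,
      means = ifelse(counts > 0, sums / pmax(counts, 1L), NaN),
      counts = counts,
      halfWidth = as.integer(halfWidth), binWidth = as.integer(binWidth))
}

#' Split sites by promoter proximity
#'
#' A site is promoter-proximal iff its midpoint lies in the interval
#' from \code{upstream} bp upstream of a TSS to the TSS itself,
#' strand-aware and inclusive at both ends (a midpoint exactly at the
#' TSS is a promoter site; one 501 bp upstream is not, at the default
#' width).
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param genes a \linkS4class{GeneModels}.
#' @param upstream window size in bp (default 500).
#' @return list with \code{promoter} and \code{nonpromoter}
#'   \linkS4class{SiteSet}s; the two part sizes sum to the input size.
#' @export
splitByPromoterProximity <- function(sites, genes, upstream = 500L) {
  tss <- tssPoints(genes)
  lo <- ifelse(tss$strand == "+", tss$pos - upstream, tss$pos)
  hi <- ifelse(tss$strand == "+", tss$pos, tss$pos + upstream)
  win <- GRanges(tss$chrom, IRanges(lo + 1L, hi + 1L))
  pts <- GRanges(as.character(seqnames(sites)),
                 IRanges(siteMidpoints(sites) + 1L, width = 1L))
  isProm <- countOverlaps(pts, win, ignore.strand = TRUE) > 0
  subsetSiteSet <- function(s, sel) {
    new("SiteSet", granges_subset(s, sel), factorName = factorName(s))
  }
  list(promoter = subsetSiteSet(sites, isProm),
       nonpromoter = subsetSiteSet(sites, !isProm))
}

# subset a SiteSet's underlying GRanges, keeping metadata
granges_subset <- function(s, sel) {
  gr <- GRanges(as.character(seqnames(s))[sel],
                IRanges(start(s)[sel], end(s)[sel]),
                score = mcols(s)$score[sel],
                midpoint = mcols(s)$midpoint[sel])
  if (!any(is.na(seqlengths(s)))) seqinfo(gr) <- seqinfo(s)[seqlevels(gr)]
  gr
}

#' Median and MAD of track scores per site class
#'
#' For each class, every site contributes the mean track value over its
#' span ([start, end), 0-based); the class summary is the median and the
#' unscaled median absolute deviation (no 1.4826 consistency factor) of
#' those per-site scores.
#'
#' @param siteSetsByClass named list of \linkS4class{SiteSet}.
#' @param track a \linkS4class{SignalTrack} of scores.
#' @return data.frame with \code{class}, \code{n}, \code{median},
#'   \code{mad}; classes with no scored sites are omitted.
#' @export
scoreSummaryByClass <- function(siteSetsByClass, track) {
  rows <- lapply(names(siteSetsByClass), function(cl) {
    s <- siteSetsByClass[[cl]]
    if (!length(s)) return(NULL)
    sc <- siteSpanScores(s, track)
    sc <- sc[!is.na(sc)]
    if (!length(sc)) return(NULL)
    m <- median(sc)
    data.frame(class = cl, n = length(sc), median = m,
               mad = median(abs(sc - m)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

# mean track value over each site's [start0, end0) span; NA when no
# probe falls in the span
siteSpanScores <- function(sites, track) {
  out <- rep(NA_real_, length(sites))
  chrom <- as.character(seqnames(sites))
  tc <- trackChroms(track)
  for (cn in unique(chrom)) {
    psel <- tc == cn
    if (!any(psel)) next
    pos <- trackPositions(track)[psel]
    val <- trackValues(track)[psel]
    cval <- cumsum(val)
    sel <- which(chrom == cn)
    s0 <- start(sites)[sel] - 1L
    e0 <- end(sites)[sel]
    lo <- findInterval(s0 - 1L, pos)      # probes <= s0-1 (before span)
    hi <- findInterval(e0 - 1L, pos)      # probes <= e0-1 (in/below span)
    n <- hi - lo
    ok <- n > 0L
    out[sel[ok]] <- (c(0, cval)[hi[ok] + 1L] - c(0, cval)[lo[ok] + 1L]) /
      n[ok]
  }
  out
}
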