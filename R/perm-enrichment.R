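# Permutation null models for positional and pairwise enrichment. The
# null places, per chromosome, the observed number of sites uniformly
# along the chromosome (widths preserved); observed statistics are
# normalised by the null median, intervals come from the 2.5/97.5 null
# percentiles, and empirical p-values are the pseudo-counted fraction of
# simulations at least as extreme as the observation.

#' Configuration for permutation enrichment analyses
#'
#' @param nSim number of permutations (default 10000).
#' @param ciLo,ciHi null percentiles for the interval (default 2.5/97.5).
#' @param seed integer seed or NULL.
#' @return an object of class \code{EnrichmentConfig}.
#' @export
enrichmentConfig <- function(nSim = 10000L, ciLo = 2.5, ciHi = 97.5,
                             seed = NULL) {
  if (nSim < 1L) stop("nSim must be >= 1")
  if (!(0 < ciLo && ciLo < ciHi && ciHi < 100))
    stop("need 0 < ciLo < ciHi < 100")
  structure(list(nSim = as.integer(nSim), ciLo = ciLo, ciHi = ciHi,
                 seed = seed), class = "EnrichmentConfig")
}

# internal: build a raw SiteSet keeping a caller-supplied midpoint
makeSiteSetRaw <- function(chrom, s0, e0, mid, factor, score, genome = NULL) {
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0), score = score,
                midpoint = as.integer(mid))
  if (!is.null(genome)) seqinfo(gr) <- genome[seqlevels(gr)]
  o <- order(as.character(seqnames(gr)), start(gr))
  new("SiteSet", gr[o], factorName = factor)
}

#' Uniform per-chromosome permutation of a site set
#'
#' Re-places every site at a uniform midpoint on its own chromosome
#' (so per-chromosome counts are preserved), keeping each site's width;
#' intervals are clipped at chromosome bounds.
#'
#' @param genome \code{Seqinfo} covering all site chromosomes.
#' @param sites a \linkS4class{SiteSet}.
#' @param seed integer seed or NULL.
#' @return a permuted \linkS4class{SiteSet}.
#' @export
permuteSites <- function(genome, sites, seed = NULL) {
  if (!length(sites)) return(sites)
  chrom <- as.character(seqnames(sites))
  lens <- seqlengths(genome)[chrom]
  if (anyNA(lens)) stop("site on chromosome absent from genome")
  w <- width(sites)
  withSeed(seed, {
    mid <- runifInt(length(sites), lens)
    half <- w %/% 2L
    s0 <- pmax(0L, mid - half)
    e0 <- pmin(as.integer(lens), mid + (w - half))
    makeSiteSetRaw(chrom, s0, e0, mid, factorName(sites),
                   mcols(sites)$score, genome)
  })
}

# internal: per-chromosome sorted feature tables from a data.frame with
# chrom/pos/strand columns.
featureSplit <- function(features) {
  sp <- split(seq_len(nrow(features)), features$chrom)
  lapply(sp, function(i) {
    o <- i[order(features$pos[i])]
    list(pos = features$pos[o],
         strand = if ("strand" %in% names(features))
           features$strand[o] else rep("+", length(o)))
  })
}

#' Signed distance from each site to its nearest feature
#'
#' Distance is midpoint minus feature position; for minus-strand
#' features the sign is flipped so that negative always means upstream
#' of the feature in its own orientation. Equidistant neighbours resolve
#' to the left (smaller-coordinate) feature. Sites on chromosomes
#' without features get \code{NA}.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param features data.frame with \code{chrom}, \code{pos} (0-based) and
#'   optional \code{strand} columns.
#' @return numeric vector of signed distances, one per site.
#' @export
signedDistanceToNearest <- function(sites, features) {
  if (!nrow(features)) stop("features must be nonempty")
  signedDistCore(as.character(seqnames(sites)), siteMidpoints(sites),
                 featureSplit(features))
}

signedDistCore <- function(chrom, mid, fsplit) {
  out <- rep(NA_real_, length(mid))
  for (cn in unique(chrom)) {
    f <- fsplit[[cn]]
    if (is.null(f)) next
    sel <- chrom == cn
    m <- mid[sel]
    p <- f$pos
    fi <- findInterval(m, p)
    li <- pmax(fi, 1L)
    ri <- pmin(fi + 1L, length(p))
    dl <- abs(m - p[li]); dr <- abs(m - p[ri])
    useLeft <- fi >= 1L & (fi >= length(p) | dl <= dr)
    ni <- ifelse(useLeft, li, ri)
    d <- m - p[ni]
    d <- ifelse(f$strand[ni] == "-", -d, d)
    out[sel] <- d
  }
  out
}

# histogram of signed distances over half-open bins [edges[i], edges[i+1])
binCounts <- function(d, edges) {
  d <- d[!is.na(d)]
  nb <- length(edges) - 1L
  idx <- findInterval(d, edges)
  idx <- idx[idx >= 1L & idx <= nb & d < edges[nb + 1L]]
  tabulate(idx, nbins = nb)
}

#' Positional enrichment profile around point features
#'
#' Histogram of signed nearest-feature distances, per bin compared to
#' the permutation null (uniform site placement per chromosome).
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param features data.frame with \code{chrom}, \code{pos}, optional
#'   \code{strand}.
#' @param genome \code{Seqinfo} for the permutation universe.
#' @param bins bin edges in bp relative to the feature (default
#'   \code{seq(-2000, 2000, 100)}).
#' @param cfg an \code{\link{enrichmentConfig}}.
#' @return an \linkS4class{EnrichmentProfile}.
#' @export
positionalProfile <- function(sites, features, genome,
                              bins = seq(-2000L, 2000L, 100L),
                              cfg = enrichmentConfig()) {
  if (!nrow(features)) stop("features must be nonempty")
  fsplit <- featureSplit(features)
  chrom <- as.character(seqnames(sites))
  mid <- siteMidpoints(sites)
  obs <- binCounts(signedDistCore(chrom, mid, fsplit), bins)

  lens <- seqlengths(genome)
  ci <- match(chrom, GenomeInfoDb::seqnames(genome))
  if (anyNA(ci)) stop("site on chromosome absent from genome")
  nb <- length(bins) - 1L
  nullMat <- withSeed(cfg$seed, {
    vapply(seq_len(cfg$nSim), function(i) {
      m2 <- runifInt(length(mid), lens[ci])
      binCounts(signedDistCore(chrom, m2, fsplit), bins)
    }, integer(nb))
  })
  nullMat <- matrix(nullMat, nrow = nb)

  rows <- lapply(seq_len(nb), function(b) {
    s <- nullSummary(obs[b], nullMat[b, ], cfg$ciLo, cfg$ciHi)
    data.frame(bin_lo = bins[b], bin_hi = bins[b + 1L],
               observed = s$observed, null_median = s$null_median,
               null_lo = s$null_lo, null_hi = s$null_hi,
               log2_enrichment = s$log2_enrichment,
               ci_lo = s$ci_lo, ci_hi = s$ci_hi,
               p_enriched = s$p_enriched, p_depleted = s$p_depleted)
  })
  new("EnrichmentProfile", table = do.call(rbind, rows),
      nSim = cfg$nSim)
}

#' Select promoter pairs by geometric class
#'
#' \describe{
#'   \item{adjacent}{consecutive distinct TSS, any strand, TSS-to-TSS
#'     distance in [1500, 20000] bp (inclusive), no intervening TSS.}
#'   \item{divergent}{consecutive TSS on opposite strands in divergent
#'     orientation (minus-strand TSS left of plus-strand TSS), distance
#'     in [500, 2500] bp (inclusive).}
#'   \item{alternative}{all pairs of distinct TSS of the same gene.}
#' }
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param mode one of "adjacent", "divergent", "alternative".
#' @return data.frame with \code{chrom}, \code{a}, \code{b} (0-based TSS
#'   positions, \code{a < b}), \code{a_id}, \code{b_id}.
#' @export
selectPromoterPairs <- function(genes,
                                mode = c("adjacent", "divergent",
                                         "alternative")) {
  mode <- match.arg(mode)
  tss <- tssPoints(genes)
  mkId <- function(i) paste0(tss$chrom[i], ":", tss$pos[i])
  if (mode == "alternative") {
    res <- NULL
    for (g in unique(tss$gene_id[duplicated(tss$gene_id)])) {
      i <- which(tss$gene_id == g)
      pos <- sort(unique(tss$pos[i]))
      if (length(pos) < 2L) next
      cmb <- utils::combn(length(pos), 2)
      res <- rbind(res, data.frame(
        chrom = tss$chrom[i[1]], a = pos[cmb[1, ]], b = pos[cmb[2, ]]))
    }
    if (is.null(res))
      return(data.frame(chrom = character(), a = integer(), b = integer(),
                        a_id = character(), b_id = character()))
    res$a_id <- paste0(res$chrom, ":", res$a)
    res$b_id <- paste0(res$chrom, ":", res$b)
    return(res)
  }
  # consecutive distinct TSS positions per chromosome
  res <- NULL
  for (cn in unique(tss$chrom)) {
    i <- which(tss$chrom == cn)
    i <- i[!duplicated(tss$pos[i])]
    i <- i[order(tss$pos[i])]
    if (length(i) < 2L) next
    a <- i[-length(i)]; b <- i[-1]
    gap <- tss$pos[b] - tss$pos[a]
    keep <- if (mode == "adjacent") {
      gap >= 1500L & gap <= 20000L
    } else {
      gap >= 500L & gap <= 2500L &
        tss$strand[a] == "-" & tss$strand[b] == "+"
    }
    if (any(keep))
      res <- rbind(res, data.frame(
        chrom = cn, a = tss$pos[a[keep]], b = tss$pos[b[keep]],
        a_id = mkId(a[keep]), b_id = mkId(b[keep])))
  }
  if (is.null(res))
    data.frame(chrom = character(), a = integer(), b = integer(),
               a_id = character(), b_id = character())
  else res
}

# Step function counting how many pairs strictly contain an integer
# position: +1 at a+1, -1 at b. Returns per-chromosome breakpoints and
# cumulative weights; evaluate with pairWeightAt().
pairWeightFun <- function(pairs) {
  lapply(split(pairs, pairs$chrom), function(pp) {
    ev <- c(pp$a + 1L, pp$b)
    dw <- c(rep(1L, nrow(pp)), rep(-1L, nrow(pp)))
    o <- order(ev)
    ev <- ev[o]; dw <- dw[o]
    cum <- cumsum(dw)
    keep <- !duplicated(ev, fromLast = TRUE)
    list(bp = ev[keep], w = cum[keep])
  })
}

pairWeightAt <- function(wf, chrom, pos) {
  out <- numeric(length(pos))
  for (cn in unique(chrom)) {
    f <- wf[[cn]]
    if (is.null(f)) next
    sel <- chrom == cn
    fi <- findInterval(pos[sel], f$bp)
    out[sel] <- c(0, f$w)[fi + 1L]
  }
  out
}

# Shared machinery: observed and null intervening counts for one or more
# pair strata against the same permuted site sets (stratum-matched
# nulls). Returns list(observed = vector, null = nSim x nStrata matrix).
interveningCounts <- function(sites, pairList, genome, cfg) {
  wfs <- lapply(pairList, pairWeightFun)
  chrom <- as.character(seqnames(sites))
  mid <- siteMidpoints(sites)
  observed <- vapply(wfs, function(wf) sum(pairWeightAt(wf, chrom, mid)),
                     0)
  lens <- seqlengths(genome)
  ci <- match(chrom, GenomeInfoDb::seqnames(genome))
  if (anyNA(ci)) stop("site on chromosome absent from genome")
  byChrom <- split(seq_along(mid), chrom)
  nullMat <- withSeed(cfg$seed, {
    out <- matrix(0, cfg$nSim, length(wfs))
    block <- 500L
    done <- 0L
    while (done < cfg$nSim) {
      nb <- min(block, cfg$nSim - done)
      # draw nb complete permutations at once, chromosome by chromosome
      for (cn in names(byChrom)) {
        nC <- length(byChrom[[cn]])
        len <- lens[ci[byChrom[[cn]][1]]]
        m2 <- runifInt(nC * nb, len)
        for (s in seq_along(wfs)) {
          f <- wfs[[s]][[cn]]
          if (is.null(f)) next
          w <- c(0, f$w)[findInterval(m2, f$bp) + 1L]
          out[done + seq_len(nb), s] <- out[done + seq_len(nb), s] +
            colSums(matrix(w, nrow = nC))
        }
      }
      done <- done + nb
    }
    out
  })
  list(observed = observed, null = nullMat)
}

pairEnrichmentFromCounts <- function(observed, null, label, nPairs, cfg) {
  s <- nullSummary(observed, null, cfg$ciLo, cfg$ciHi)
  new("PairEnrichment", label = label,
      observed = s$observed, nullMedian = s$null_median,
      nullLo = s$null_lo, nullHi = s$null_hi,
      log2Enrichment = s$log2_enrichment, ciLo = s$ci_lo, ciHi = s$ci_hi,
      pEnriched = s$p_enriched, pDepleted = s$p_depleted,
      nPairs = as.integer(nPairs), nSim = cfg$nSim,
      nullCounts = as.numeric(null))
}

#' @describeIn interveningEnrichment the stored permutation-null counts.
#' @param x a \code{PairEnrichment}.
#' @export
nullCounts <- function(x) x@nullCounts

#' Enrichment of sites intervening between paired features
#'
#' The observed statistic is the total number of site midpoints falling
#' strictly between the two members of each pair (endpoints excluded),
#' summed over pairs; the null re-places sites uniformly per chromosome.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param pairs data.frame with \code{chrom}, \code{a}, \code{b}
#'   (0-based points, \code{a < b}).
#' @param genome \code{Seqinfo}.
#' @param cfg an \code{\link{enrichmentConfig}}.
#' @param label label for the result.
#' @return a \linkS4class{PairEnrichment}.
#' @export
interveningEnrichment <- function(sites, pairs, genome,
                                  cfg = enrichmentConfig(),
                                  label = "pairs") {
  if (is.null(pairs) || !nrow(pairs)) stop("pairs must be nonempty")
  ic <- interveningCounts(sites, list(pairs), genome, cfg)
  pairEnrichmentFromCounts(ic$observed[1], ic$null[, 1], label,
                           nrow(pairs), cfg)
}

#' Call active promoters from H3K4me3, PolII and RNA evidence
#'
#' A transcript's promoter is active iff an H3K4me3 interval and a PolII
#' interval both overlap the window TSS +/- \code{window} bp and at
#' least one exon of the transcript overlaps an RNA interval. Distinct
#' TSS of a gene are labelled active if any of their transcripts is.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param h3k4me3,polII,rna evidence \linkS4class{SiteSet}s.
#' @param window half-width of the TSS evidence window (default 500 bp).
#' @return data.frame: one row per distinct TSS with \code{chrom},
#'   \code{pos}, \code{strand}, \code{gene_id}, \code{tx_id},
#'   \code{active}.
#' @export
callActivePromoters <- function(genes, h3k4me3, polII, rna, window = 500L) {
  tx <- genes@transcripts
  tss0 <- ifelse(as.character(strand(tx)) == "+", start(tx) - 1L,
                 end(tx) - 1L)
  win <- GRanges(as.character(seqnames(tx)),
                 IRanges(pmax(1L, tss0 + 1L - window), tss0 + 1L + window))
  hasH3 <- countOverlaps(win, h3k4me3, ignore.strand = TRUE) > 0
  hasPol <- countOverlaps(win, polII, ignore.strand = TRUE) > 0
  ex <- genes@exons
  exHit <- countOverlaps(ex, rna, ignore.strand = TRUE) > 0
  rnaByTx <- tapply(exHit, mcols(ex)$tx_id, any)
  hasRna <- unname(rnaByTx[mcols(tx)$tx_id]) %in% TRUE
  txActive <- hasH3 & hasPol & hasRna

  df <- data.frame(
    chrom = as.character(seqnames(tx)), pos = as.integer(tss0),
    strand = as.character(strand(tx)),
    gene_id = mcols(tx)$gene_id, tx_id = mcols(tx)$tx_id,
    active = txActive, stringsAsFactors = FALSE
  )
  agg <- tapply(df$active, paste0(df$chrom, ":", df$pos, ":", df$gene_id),
                any)
  key <- paste0(df$chrom, ":", df$pos, ":", df$gene_id)
  df$active <- unname(agg[key])
  df <- df[!duplicated(key), , drop = FALSE]
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Pair enrichment stratified by differential promoter activity
#'
#' Splits pairs into those whose endpoints differ in activity and those
#' that agree, then measures intervening enrichment per stratum against
#' the same permuted site sets (stratum-matched nulls).
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param pairs data.frame from \code{\link{selectPromoterPairs}} (needs
#'   \code{a_id}/\code{b_id} of the form "chrom:pos").
#' @param activity data.frame from \code{\link{callActivePromoters}}.
#' @param genome \code{Seqinfo}.
#' @param cfg an \code{\link{enrichmentConfig}}.
#' @return named list with \code{differential} and \code{non_differential}
#'   \linkS4class{PairEnrichment} entries (an empty stratum yields NULL).
#' @export
stratifiedPairEnrichment <- function(sites, pairs, activity, genome,
                                     cfg = enrichmentConfig()) {
  if (!nrow(pairs)) stop("pairs must be nonempty")
  if (is.null(activity) || !nrow(activity))
    stop("pair endpoint without an activity label")
  actKey <- paste0(activity$chrom, ":", activity$pos)
  # a TSS position may host several genes' transcripts; active if any is
  actByPos <- tapply(activity$active, actKey, any)
  aAct <- actByPos[pairs$a_id]
  bAct <- actByPos[pairs$b_id]
  if (anyNA(aAct) || anyNA(bAct))
    stop("pair endpoint without an activity label")
  diffSel <- as.vector(aAct != bAct)
  strata <- list(differential = pairs[diffSel, , drop = FALSE],
                 non_differential = pairs[!diffSel, , drop = FALSE])
  nonEmpty <- vapply(strata, nrow, 0L) > 0L
  res <- list(differential = NULL, non_differential = NULL)
  if (!any(nonEmpty)) return(res)
  ic <- interveningCounts(sites, strata[nonEmpty], genome, cfg)
  j <- 0L
  for (nm in names(strata)[nonEmpty]) {
    j <- j + 1L
    res[[nm]] <- pairEnrichmentFromCounts(
      ic$observed[j], ic$null[, j], nm, nrow(strata[[nm]]), cfg)
  }
  res
}

#' CRM / promoter partition enrichment
#'
#' Builds three pair classes and measures intervening-site enrichment
#' for each, with nulls drawn from the same permuted site sets:
#' (i) CRM midpoint to the nearest TSS of its annotated target gene,
#' (ii) CRM midpoint to the nearest TSS of any other gene (ties resolve
#' to the smaller coordinate), and (iii) adjacent CRM midpoints of the
#' same target gene.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param crms data.frame with \code{chrom}, \code{start0}, \code{end0},
#'   \code{target_gene}.
#' @param genes a \linkS4class{GeneModels}.
#' @param genome \code{Seqinfo}.
#' @param cfg an \code{\link{enrichmentConfig}}.
#' @return named list of \linkS4class{PairEnrichment} (\code{target},
#'   \code{non_target}, \code{crm_crm}); classes with no pairs are NULL.
#' @export
crmPartitionEnrichment <- function(sites, crms, genes, genome,
                                   cfg = enrichmentConfig()) {
  stopifnot(nrow(crms) > 0L)
  tss <- tssPoints(genes)
  mid <- as.integer((crms$start0 + crms$end0) %/% 2L)

  nearestTss <- function(chrom, pos, sel) {
    # nearest TSS among tss rows satisfying sel; ties -> smaller coord
    cand <- which(sel & tss$chrom == chrom)
    if (!length(cand)) return(NA_integer_)
    d <- abs(tss$pos[cand] - pos)
    cand <- cand[d == min(d)]
    min(tss$pos[cand])
  }

  tgt <- integer(nrow(crms)); ntgt <- integer(nrow(crms))
  for (i in seq_len(nrow(crms))) {
    g <- crms$target_gene[i]
    t1 <- nearestTss(crms$chrom[i], mid[i], tss$gene_id == g)
    if (is.na(t1)) stop("CRM target gene without a TSS: ", g)
    tgt[i] <- t1
    ntgt[i] <- nearestTss(crms$chrom[i], mid[i], tss$gene_id != g)
  }
  mkPairs <- function(x, y, chrom) {
    keep <- !is.na(x) & !is.na(y) & x != y
    data.frame(chrom = chrom[keep], a = pmin(x[keep], y[keep]),
               b = pmax(x[keep], y[keep]))
  }
  pT <- mkPairs(mid, tgt, crms$chrom)
  pN <- mkPairs(mid, ntgt, crms$chrom)
  pC <- NULL
  for (g in unique(crms$target_gene[duplicated(crms$target_gene)])) {
    i <- which(crms$target_gene == g)
    i <- i[order(mid[i])]
    if (length(i) < 2L) next
    pC <- rbind(pC, data.frame(chrom = crms$chrom[i[-length(i)]],
                               a = mid[i[-length(i)]], b = mid[i[-1]]))
  }
  classes <- list(target = pT, non_target = pN, crm_crm = pC)
  nonEmpty <- vapply(classes, function(x) !is.null(x) && nrow(x) > 0, TRUE)
  res <- list(target = NULL, non_target = NULL, crm_crm = NULL)
  if (!any(nonEmpty)) return(res)
  ic <- interveningCounts(sites, classes[nonEmpty], genome, cfg)
  j <- 0L
  for (nm in names(classes)[nonEmpty]) {
    j <- j + 1L
    res[[nm]] <- pairEnrichmentFromCounts(
      ic$observed[j], ic$null[, j], nm, nrow(classes[[nm]]), cfg)
  }
  res
}

#' Classify site midpoints into annotation categories
#'
#' Each site is assigned exactly one category by its midpoint with
#' precedence 5'UTR > 3'UTR > exon > intron > intergenic; the genomic
#' base-pair fraction of each category (same precedence) is reported for
#' normalisation.
#'
#' @param sites a \linkS4class{SiteSet}.
#' @param genes a \linkS4class{GeneModels}.
#' @param genome \code{Seqinfo} (for the intergenic fraction).
#' @return list with \code{counts} (named integer, sums to the number of
#'   sites), \code{category} (per-site factor) and \code{genome_fraction}
#'   (named numeric summing to 1).
#' @export
annotateSiteCategories <- function(sites, genes, genome) {
  pts <- GRanges(as.character(seqnames(sites)),
                 IRanges(siteMidpoints(sites) + 1L, width = 1L))
  u5 <- reduce(genes@utr5, ignore.strand = TRUE)
  u3 <- reduce(genes@utr3, ignore.strand = TRUE)
  ex <- reduce(genes@exons, ignore.strand = TRUE)
  tx <- reduce(genes@transcripts, ignore.strand = TRUE)

  inU5 <- countOverlaps(pts, u5, ignore.strand = TRUE) > 0
  inU3 <- countOverlaps(pts, u3, ignore.strand = TRUE) > 0
  inEx <- countOverlaps(pts, ex, ignore.strand = TRUE) > 0
  inTx <- countOverlaps(pts, tx, ignore.strand = TRUE) > 0
  lv <- c("utr5", "utr3", "exon", "intron", "intergenic")
  cat <- rep("intergenic", length(pts))
  cat[inTx] <- "intron"
  cat[inEx] <- "exon"
  cat[inU3] <- "utr3"
  cat[inU5] <- "utr5"
  cat <- factor(cat, levels = lv)

  total <- sum(as.numeric(seqlengths(genome)))
  bpU5 <- sum(as.numeric(width(u5)))
  u3x <- GenomicRanges::setdiff(u3, u5, ignore.strand = TRUE)
  bpU3 <- sum(as.numeric(width(u3x)))
  exx <- GenomicRanges::setdiff(ex, reduce(c(u5, u3)), ignore.strand = TRUE)
  bpEx <- sum(as.numeric(width(exx)))
  inx <- GenomicRanges::setdiff(tx, reduce(c(u5, u3, ex)),
                                ignore.strand = TRUE)
  bpIn <- sum(as.numeric(width(inx)))
  frac <- c(utr5 = bpU5, utr3 = bpU3, exon = bpEx, intron = bpIn,
            intergenic = total - bpU5 - bpU3 - bpEx - bpIn) / total
  list(counts = setNames(as.integer(table(cat)), lv),
       category = cat, genome_fraction = frac)
}
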