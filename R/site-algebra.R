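# Multi-factor binding-site overlap and clustering. The overlap criterion
# throughout is a midpoint-to-midpoint distance strictly below 250 bp;
# clusters are single-linkage connected components under that criterion,
# which in one dimension are runs of sorted midpoints with consecutive
# gaps below the threshold.

#' Midpoint-to-midpoint overlap criterion
#'
#' Two sites overlap iff they are on the same chromosome and their
#' midpoints are strictly less than \code{maxDist} bp apart.
#'
#' @param chromA,chromB chromosomes (vectors recycle).
#' @param midA,midB 0-based midpoints.
#' @param maxDist distance threshold in bp (default 250, strict \code{<}).
#' @return logical vector.
#' @export
midpointOverlap <- function(chromA, midA, chromB, midB, maxDist = 250L) {
  chromA == chromB & abs(as.numeric(midA) - as.numeric(midB)) < maxDist
}

# For each query midpoint, is there a subject midpoint on the same
# chromosome strictly within maxDist? Sorted-vector scan, O(n log m).
hasNeighbor <- function(qchrom, qmid, schrom, smid, maxDist) {
  out <- rep(FALSE, length(qmid))
  sSplit <- splitSorted(smid, schrom)
  for (cn in unique(qchrom)) {
    s <- sSplit[[cn]]
    if (is.null(s) || !length(s)) next
    sel <- qchrom == cn
    q <- qmid[sel]
    lo <- findInterval(q - maxDist, s)        # s <= q - maxDist
    hi <- findInterval(q + maxDist - 1L, s)   # s <= q + maxDist - 1
    out[sel] <- hi > lo
  }
  out
}

#' Pairwise overlap fraction matrix
#'
#' Entry (A, B) is the fraction of A's sites having at least one B site
#' with midpoint distance strictly below \code{maxDist}. The matrix is
#' generally asymmetric; rows for empty sets are \code{NA}.
#'
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param maxDist distance threshold (default 250 bp).
#' @return numeric matrix with factor names on both dimensions.
#' @export
pairwiseOverlapFraction <- function(siteSets, maxDist = 250L) {
  if (length(siteSets) < 2L) stop("need at least two site sets")
  nm <- vapply(siteSets, factorName, "")
  names(siteSets) <- nm
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (a in nm) {
    sa <- siteSets[[a]]
    if (!length(sa)) next
    ca <- as.character(seqnames(sa)); ma <- siteMidpoints(sa)
    for (b in nm) {
      sb <- siteSets[[b]]
      if (!length(sb)) { m[a, b] <- NA_real_; next }
      m[a, b] <- mean(hasNeighbor(ca, ma, as.character(seqnames(sb)),
                                  siteMidpoints(sb), maxDist))
    }
  }
  m
}

# Cluster pooled (chrom, midpoint, factor index) triples. Returns a list
# with per-site cluster ids and, per cluster, the signature bitmask.
# Sites are single-linkage chained: sorted within chromosome, a new
# cluster starts where the gap to the previous midpoint is >= maxDist.
clusterPooled <- function(chrom, mid, fidx, maxDist) {
  o <- order(chrom, mid)
  ch <- chrom[o]; m <- mid[o]; f <- fidx[o]
  n <- length(m)
  if (n == 0L)
    return(list(order = o, run = integer(), mask = integer(),
                size = integer()))
  newrun <- c(TRUE, ch[-1] != ch[-n] | (m[-1] - m[-n]) >= maxDist)
  run <- cumsum(newrun)
  key <- run * 64 + f
  first <- !duplicated(key)
  mask <- as.integer(rowsum(2^f[first], run[first]))
  size <- tabulate(run)
  list(order = o, run = run, mask = mask, size = size,
       chrom = ch, mid = m)
}

#' Single-linkage clustering of multi-factor binding sites
#'
#' Pools all factors' sites and forms the connected components of the
#' graph whose edges join sites with midpoint distance strictly below
#' \code{maxDist} (transitively chained). Every input site belongs to
#' exactly one cluster; a factor present more than once in a component
#' counts once in the signature.
#'
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param maxDist overlap threshold (default 250 bp, strict).
#' @return data.frame, one row per cluster: \code{chrom}, \code{start0},
#'   \code{end0} (span over member midpoints, half-open), \code{n_sites},
#'   \code{signature} (sorted factor names joined with "+"),
#'   \code{n_factors}.
#' @export
buildClusters <- function(siteSets, maxDist = 250L) {
  nm <- vapply(siteSets, factorName, "")
  chrom <- unlist(lapply(siteSets, function(s) as.character(seqnames(s))),
                  use.names = FALSE)
  mid <- unlist(lapply(siteSets, siteMidpoints), use.names = FALSE)
  fidx <- rep(seq_along(siteSets), vapply(siteSets, length, 0L))
  cl <- clusterPooled(chrom, mid, fidx, maxDist)
  if (!length(cl$run))
    return(data.frame(chrom = character(), start0 = integer(),
                      end0 = integer(), n_sites = integer(),
                      signature = character(), n_factors = integer()))
  firsts <- which(!duplicated(cl$run))
  lasts <- c(firsts[-1] - 1L, length(cl$run))
  data.frame(
    chrom = cl$chrom[firsts],
    start0 = cl$mid[firsts],
    end0 = cl$mid[lasts] + 1L,
    n_sites = cl$size,
    signature = maskToSignature(cl$mask, nm),
    n_factors = vapply(cl$mask, function(x) sum(bitwAnd(x, 2^(1:30)) > 0), 0L),
    stringsAsFactors = FALSE
  )
}

# Convert factor-presence bitmasks (bit i set = factor i present, i from
# 1) to "A+B" style sorted signature strings.
maskToSignature <- function(mask, factorNames) {
  k <- length(factorNames)
  o <- order(factorNames)
  vapply(mask, function(x) {
    present <- which(bitwAnd(x, 2^(1:k)) > 0)
    paste(sort(factorNames[present]), collapse = "+")
  }, "")
}

#' Combination-signature significance against uniform simulations
#'
#' Counts observed clusters per factor-combination signature, then
#' repeats the clustering on \code{nSim} simulated datasets in which each
#' factor's sites are independently re-placed uniformly per chromosome
#' (widths preserved). Empirical p-values per side use the +1
#' pseudo-count, so the minimal attainable p is \code{1/(1 + nSim)}.
#'
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param genome \code{Seqinfo}.
#' @param nSim number of simulations (>= 1; the spec-level default in the
#'   pipeline is 1000).
#' @param seed integer seed.
#' @param maxDist overlap threshold.
#' @return a \linkS4class{CombinationTable}; signatures observed 0 times
#'   but seen in simulation are included (depletion side).
#' @export
combinationSignificance <- function(siteSets, genome, nSim = 1000L,
                                    seed = NULL, maxDist = 250L) {
  if (nSim < 1L) stop("nSim must be >= 1")
  nm <- vapply(siteSets, factorName, "")
  k <- length(siteSets)
  chrom <- unlist(lapply(siteSets, function(s) as.character(seqnames(s))),
                  use.names = FALSE)
  mid <- unlist(lapply(siteSets, siteMidpoints), use.names = FALSE)
  fidx <- rep(seq_len(k), vapply(siteSets, length, 0L))

  countSignatures <- function(ch, m, f) {
    cl <- clusterPooled(ch, m, f, maxDist)
    tab <- table(cl$mask)
    setNames(as.integer(tab), names(tab))
  }
  obs <- countSignatures(chrom, mid, fidx)

  lens <- seqlengths(genome)
  chromIdx <- match(chrom, GenomeInfoDb::seqnames(genome))
  if (anyNA(chromIdx)) stop("site on chromosome absent from genome")

  simCounts <- withSeed(seed, {
    lapply(seq_len(nSim), function(i) {
      m2 <- runifInt(length(mid), lens[chromIdx])
      countSignatures(chromIdx, m2, fidx)
    })
  })

  allMasks <- sort(unique(c(names(obs),
                            unlist(lapply(simCounts, names)))))
  obsVec <- setNames(rep(0L, length(allMasks)), allMasks)
  obsVec[names(obs)] <- obs
  simMat <- matrix(0L, nSim, length(allMasks),
                   dimnames = list(NULL, allMasks))
  for (i in seq_len(nSim)) {
    sc <- simCounts[[i]]
    simMat[i, names(sc)] <- sc
  }
  pe <- (1 + colSums(simMat >= rep(obsVec, each = nSim))) / (1 + nSim)
  pd <- (1 + colSums(simMat <= rep(obsVec, each = nSim))) / (1 + nSim)
  tab <- data.frame(
    signature = maskToSignature(as.integer(allMasks), nm),
    observed = as.integer(obsVec),
    null_median = apply(simMat, 2, median),
    p_enriched = pe, p_depleted = pd,
    stringsAsFactors = FALSE, row.names = NULL
  )
  new("CombinationTable", table = tab[order(-tab$observed), ],
      nSim = as.integer(nSim))
}

#' Assign insulator class to a cluster signature
#'
#' Class I clusters involve the BEAF-32/CP190/CTCF trio without Su(Hw);
#' Class II clusters contain Su(Hw) without the trio; signatures with
#' members of both are \code{"both"}; anything else (e.g. GAF-only or
#' Mod(mdg4)-only) is \code{"other"}.
#'
#' @param signature character vector of "+"-joined signatures, or a list
#'   of character vectors of factor names.
#' @param classI,classII factor names defining each class.
#' @param known all recognised factor names; an unknown label errors.
#' @return character vector in \code{c("ClassI","ClassII","both","other")}.
#' @export
assignClass <- function(signature,
                        classI = c("BEAF-32", "CP190", "CTCF"),
                        classII = "Su(Hw)",
                        known = c(classI, classII, "GAF", "Mod(mdg4)")) {
  sigs <- if (is.list(signature)) signature else
    strsplit(as.character(signature), "+", fixed = TRUE)
  vapply(sigs, function(fs) {
    bad <- setdiff(fs, known)
    if (length(bad)) stop("unknown factor label: ", paste(bad, collapse = ", "))
    hasI <- length(intersect(fs, classI)) > 0
    hasII <- length(intersect(fs, classII)) > 0
    if (hasI && hasII) "both"
    else if (hasI) "ClassI"
    else if (hasII) "ClassII"
    else "other"
  }, "")
}
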