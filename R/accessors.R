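#' Construct a SiteSet
#'
#' @param chrom character chromosomes.
#' @param start0,end0 0-based half-open interval coordinates (BED
#'   convention); \code{start0 < end0} is required.
#' @param factorName factor label for the whole set.
#' @param score numeric scores (0 when absent).
#' @param genome optional \code{Seqinfo}; when given, intervals are
#'   validated against chromosome lengths.
#' @return a \linkS4class{SiteSet}, sorted by (chrom, start), with
#'   midpoints \code{floor((start0 + end0)/2)}.
#' @export
SiteSet <- function(chrom, start0, end0, factorName,
                    score = rep(0, length(chrom)), genome = NULL) {
  chrom <- as.character(chrom)
  start0 <- as.integer(start0)
  end0 <- as.integer(end0)
  if (any(start0 < 0L) || any(start0 >= end0))
    stop("invalid interval: need 0 <= start < end")
  if (!is.null(genome)) {
    len <- seqlengths(genome)[chrom]
    if (anyNA(len))
      stop("site on chromosome absent from genome: ",
           paste(unique(chrom[is.na(len)]), collapse = ", "))
    if (any(end0 > len))
      stop("site extends beyond chromosome end")
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0),
                score = as.numeric(score),
                midpoint = as.integer(floor((start0 + end0) / 2)))
  if (!is.null(genome))
    seqinfo(gr) <- genome[seqlevels(gr)]
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]
  new("SiteSet", gr, factorName = factorName)
}

#' @describeIn SiteSet factor label of a site set.
#' @param x a \code{SiteSet}.
#' @export
factorName <- function(x) x@factorName

#' Site midpoints in 0-based coordinates
#'
#' @param x a \code{SiteSet} (or any GRanges with a \code{midpoint} column).
#' @return integer vector of midpoints, \code{floor((start0 + end0)/2)}.
#' @export
siteMidpoints <- function(x) mcols(x)$midpoint

setMethod("show", "SiteSet", function(object) {
  cat("SiteSet '", object@factorName, "' with ", length(object),
      " sites on ", length(unique(as.character(seqnames(object)))),
      " chromosome(s)\n", sep = "")
  if (length(object)) callNextMethod()
})

#' Construct a genome from chromosome names and lengths
#'
#' The genome doubles as the analysis-chromosome whitelist: every
#' permutation samples only these chromosomes.
#'
#' @param chrom chromosome names (unique).
#' @param length chromosome lengths in bp (> 0).
#' @return a \code{Seqinfo}.
#' @export
makeGenome <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  Seqinfo(seqnames = chrom, seqlengths = as.integer(length))
}

#' GeneModels constructor
#'
#' @param genes,transcripts,exons,utr5,utr3 see
#'   \linkS4class{GeneModels}.
#' @export
GeneModels <- function(genes, transcripts, exons,
                       utr5 = GRanges(), utr3 = GRanges()) {
  new("GeneModels", genes = genes, transcripts = transcripts,
      exons = exons, utr5 = utr5, utr3 = utr3)
}

#' @describeIn GeneModels gene-level ranges.
#' @param x a \code{GeneModels}.
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GeneModels transcript-level ranges.
#' @export
transcriptRanges <- function(x) x@transcripts

#' @describeIn GeneModels exon ranges.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GeneModels 5' UTR ranges.
#' @export
utr5Ranges <- function(x) x@utr5

#' @describeIn GeneModels 3' UTR ranges.
#' @export
utr3Ranges <- function(x) x@utr3

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels:", length(object@genes), "genes,",
      length(object@transcripts), "transcripts,",
      length(object@exons), "exons\n")
  n_alt <- sum(mcols(object@genes)$alt_promoter %in% TRUE)
  cat("  genes flagged alternative-promoter:", n_alt, "\n")
})

#' Transcription start sites
#'
#' Strand-aware 5' ends of transcripts, as 0-based point coordinates.
#' For a + strand transcript at 1-based \code{[s, e]} the TSS is
#' \code{s - 1}; for a - strand transcript it is \code{e - 1}.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param distinct drop duplicate (gene, position) entries so each gene
#'   contributes its distinct TSS positions once (default TRUE).
#' @return data.frame with \code{chrom}, \code{pos} (0-based),
#'   \code{strand}, \code{gene_id}, \code{tx_id}.
#' @export
tssPoints <- function(genes, distinct = TRUE) {
  tx <- genes@transcripts
  pos <- ifelse(as.character(strand(tx)) == "+", start(tx) - 1L, end(tx) - 1L)
  df <- data.frame(
    chrom = as.character(seqnames(tx)),
    pos = as.integer(pos),
    strand = as.character(strand(tx)),
    gene_id = mcols(tx)$gene_id,
    tx_id = mcols(tx)$tx_id,
    stringsAsFactors = FALSE
  )
  if (distinct)
    df <- df[!duplicated(df[, c("chrom", "pos", "gene_id")]), , drop = FALSE]
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Transcription end sites (strand-aware 3' ends), 0-based points
#'
#' @inheritParams tssPoints
#' @export
tesPoints <- function(genes, distinct = TRUE) {
  tx <- genes@transcripts
  pos <- ifelse(as.character(strand(tx)) == "+", end(tx) - 1L, start(tx) - 1L)
  df <- data.frame(
    chrom = as.character(seqnames(tx)),
    pos = as.integer(pos),
    strand = as.character(strand(tx)),
    gene_id = mcols(tx)$gene_id,
    tx_id = mcols(tx)$tx_id,
    stringsAsFactors = FALSE
  )
  if (distinct)
    df <- df[!duplicated(df[, c("chrom", "pos", "gene_id")]), , drop = FALSE]
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' SignalTrack constructor
#'
#' @param chrom chromosome per probe.
#' @param pos 0-based probe positions, strictly increasing per chromosome.
#' @param value probe values.
#' @export
SignalTrack <- function(chrom, pos, value) {
  chrom <- rep_len(as.character(chrom), length(pos))
  o <- order(chrom, pos)
  new("SignalTrack", chroms = as.character(chrom)[o],
      positions = as.integer(pos)[o], values = as.numeric(value)[o])
}

#' @describeIn SignalTrack 0-based probe positions.
#' @param x a \code{SignalTrack}.
#' @export
trackPositions <- function(x) x@positions

#' @describeIn SignalTrack probe values.
#' @export
trackValues <- function(x) x@values

#' @describeIn SignalTrack probe chromosomes.
#' @export
trackChroms <- function(x) x@chroms

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack:", length(object@positions), "probes on",
      length(unique(object@chroms)), "chromosome(s)\n")
})

setMethod("length", "SignalTrack", function(x) length(x@positions))

#' @describeIn PairEnrichment result as a one-row data.frame.
#' @param x a \code{PairEnrichment}.
#' @export
asPairRow <- function(x) {
  data.frame(
    label = x@label, observed = x@observed, null_median = x@nullMedian,
    null_lo = x@nullLo, null_hi = x@nullHi,
    log2_enrichment = x@log2Enrichment, ci_lo = x@ciLo, ci_hi = x@ciHi,
    p_enriched = x@pEnriched, p_depleted = x@pDepleted,
    n_pairs = x@nPairs, n_sim = x@nSim, stringsAsFactors = FALSE
  )
}

setMethod("show", "PairEnrichment", function(object) {
  cat("PairEnrichment '", object@label, "': observed ", object@observed,
      ", null median ", object@nullMedian,
      ", log2 ", round(object@log2Enrichment, 3),
      " [", round(object@ciLo, 3), ", ", round(object@ciHi, 3), "]",
      ", p(enr) ", signif(object@pEnriched, 3),
      ", p(dep) ", signif(object@pDepleted, 3), "\n", sep = "")
})

#' @describeIn EnrichmentProfile the per-bin table.
#' @param x an \code{EnrichmentProfile}.
#' @export
profileTable <- function(x) x@table

setMethod("show", "EnrichmentProfile", function(object) {
  cat("EnrichmentProfile:", nrow(object@table), "bins,",
      object@nSim, "permutations\n")
  print(head(object@table, 4))
})

#' @describeIn CombinationTable the signature table.
#' @param x a \code{CombinationTable}.
#' @export
combinationTable <- function(x) x@table

setMethod("show", "CombinationTable", function(object) {
  cat("CombinationTable:", nrow(object@table), "signatures,",
      object@nSim, "simulations\n")
  print(head(object@table[order(-object@table$observed), ], 6))
})

#' @describeIn DomainSet the domain ranges.
#' @param x a \code{DomainSet}.
#' @export
domainRanges <- function(x) x@domains

#' @describeIn DomainSet the boundary points (left edges strand -, right
#'   edges strand +), with 0-based positions in the \code{pos} column.
#' @export
boundaryPoints <- function(x) x@boundaries

setMethod("show", "DomainSet", function(object) {
  cat("DomainSet from '", object@source, "': ", length(object@domains),
      " domains, ", length(object@boundaries), " boundaries\n", sep = "")
})

#' @describeIn HmmParams state means (increasing).
#' @param x an \code{HmmParams}.
#' @export
hmmMeans <- function(x) x@means

#' @describeIn HmmParams state variances.
#' @export
hmmVariances <- function(x) x@variances

#' @describeIn HmmParams transition matrix.
#' @export
hmmTransition <- function(x) x@transition

#' @describeIn HmmParams log-likelihood trace.
#' @export
hmmLogLik <- function(x) x@logLik

setMethod("show", "HmmParams", function(object) {
  cat("Gaussian HMM with", length(object@means), "states\n")
  cat("  means:", paste(signif(object@means, 4), collapse = ", "), "\n")
  cat("  sds:  ", paste(signif(sqrt(object@variances), 4), collapse = ", "),
      "\n")
  cat("  converged:", object@converged, "after", length(object@logLik),
      "iterations\n")
})

#' @describeIn MetaProfile profile as a data.frame.
#' @param x a \code{MetaProfile}.
#' @export
metaProfileTable <- function(x) {
  data.frame(offset = x@offsets, mean = x@means, n = x@counts)
}

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile: +/-", object@halfWidth, "bp in", object@binWidth,
      "bp bins;", sum(object@counts), "site-probe pairs\n")
})

#' @describeIn PWM motif width in bp.
#' @param x a \code{PWM}.
#' @export
pwmWidth <- function(x) ncol(x@probs)

#' @describeIn PWM 4 x width log2-odds score matrix (rows A,C,G,T).
#'   Zero-probability cells are floored with a small pseudo-probability
#'   (1e-4) before taking logs so scores stay finite.
#' @export
pwmLogOdds <- function(x) {
  p <- pmax(x@probs, 1e-4)
  p <- sweep(p, 2, colSums(p), "/")
  log2(p / x@background)
}

setMethod("show", "PWM", function(object) {
  cat("PWM '", object@name, "', width ", ncol(object@probs), "\n", sep = "")
})
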