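#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @importFrom stats rbinom rnorm runif kmeans setNames dnorm phyper
#'   ks.test
#' @importFrom utils read.table write.table packageVersion
NULL

#' SiteSet: binding sites for one factor
#'
#' A \code{SiteSet} holds the binding-site intervals of a single
#' DNA-binding factor (an insulator-associated protein, a histone mark, a
#' transcript signal, ...) as a \linkS4class{GRanges} with a factor label.
#' Each site carries a \code{score} and its \code{midpoint} (BED-style
#' 0-based coordinate, \code{floor((start0 + end0)/2)}), the unit on which
#' all overlap and enrichment statistics operate.
#'
#' @slot factorName single character, the factor the sites belong to.
#' @name SiteSet-class
#' @aliases SiteSet-class
#' @exportClass SiteSet
setClass("SiteSet",
  contains = "GRanges",
  representation(factorName = "character")
)

setValidity("SiteSet", function(object) {
  msg <- NULL
  if (length(object@factorName) != 1L || is.na(object@factorName) ||
      !nzchar(object@factorName))
    msg <- c(msg, "'factorName' must be a single non-empty string")
  if (!all(c("score", "midpoint") %in% colnames(mcols(object))))
    msg <- c(msg, "sites must carry 'score' and 'midpoint' metadata columns")
  if (length(object)) {
    mp <- mcols(object)$midpoint
    s0 <- start(object) - 1L
    e0 <- end(object)
    if (any(mp < s0 | mp >= e0))
      msg <- c(msg, "midpoints must lie within [start, end)")
    if (!identical(order(as.character(seqnames(object)), start(object)),
                   seq_along(object)))
      msg <- c(msg, "sites must be sorted by (chrom, start)")
  }
  if (is.null(msg)) TRUE else msg
})

#' GeneModels: gene annotation with transcripts, exons and UTRs
#'
#' Container for gene models: one gene owns one or more transcripts
#' (alternative promoters when their 5' ends differ), each transcript owns
#' exons, and UTR ranges are carried separately for positional
#' classification of binding sites.
#'
#' @slot genes \code{GRanges} with \code{gene_id} and logical
#'   \code{alt_promoter} metadata.
#' @slot transcripts \code{GRanges} with \code{tx_id}, \code{gene_id}.
#' @slot exons \code{GRanges} with \code{tx_id}, \code{gene_id}.
#' @slot utr5,utr3 \code{GRanges} of untranslated regions with \code{tx_id}.
#' @name GeneModels-class
#' @exportClass GeneModels
setClass("GeneModels",
  representation(
    genes = "GRanges",
    transcripts = "GRanges",
    exons = "GRanges",
    utr5 = "GRanges",
    utr3 = "GRanges"
  )
)

setValidity("GeneModels", function(object) {
  msg <- NULL
  if (!"gene_id" %in% colnames(mcols(object@genes)))
    msg <- c(msg, "genes need a 'gene_id' column")
  if (!all(c("tx_id", "gene_id") %in% colnames(mcols(object@transcripts))))
    msg <- c(msg, "transcripts need 'tx_id' and 'gene_id' columns")
  if (!"tx_id" %in% colnames(mcols(object@exons)))
    msg <- c(msg, "exons need a 'tx_id' column")
  if (length(object@transcripts) &&
      !all(mcols(object@transcripts)$gene_id %in% mcols(object@genes)$gene_id))
    msg <- c(msg, "every transcript must point to a known gene")
  if (any(!as.character(strand(object@transcripts)) %in% c("+", "-")))
    msg <- c(msg, "transcripts must be stranded (+ or -)")
  if (is.null(msg)) TRUE else msg
})

#' SignalTrack: ordered probe-level signal
#'
#' Probe-level signal (tiling-array log-ratios, conservation scores, ...)
#' as one value per probe position. Positions are stored 1-based
#' internally; \code{trackPositions()} returns the 0-based coordinates in
#' which bedGraph records are expressed.
#'
#' @slot positions integer vector of 0-based probe positions.
#' @slot values numeric vector of probe values.
#' @slot chroms character vector, chromosome of each probe.
#' @name SignalTrack-class
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(
    chroms = "character",
    positions = "integer",
    values = "numeric"
  )
)

setValidity("SignalTrack", function(object) {
  msg <- NULL
  n <- length(object@positions)
  if (length(object@values) != n || length(object@chroms) != n)
    msg <- c(msg, "chroms, positions and values must have equal length")
  if (n > 1L) {
    ok <- tapply(object@positions, object@chroms,
                 function(p) !is.unsorted(p, strictly = TRUE))
    if (!all(unlist(ok)))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (is.null(msg)) TRUE else msg
})

#' EnrichmentProfile: binned positional enrichment against a permutation null
#'
#' Result of tabulating distances from site midpoints to their nearest
#' genomic feature, binned, with per-bin permutation null summaries:
#' null median, percentile interval, log2 enrichment and two one-sided
#' empirical p-values.
#'
#' @slot table data.frame with columns \code{bin_lo}, \code{bin_hi},
#'   \code{observed}, \code{null_median}, \code{null_lo}, \code{null_hi},
#'   \code{log2_enrichment}, \code{ci_lo}, \code{ci_hi},
#'   \code{p_enriched}, \code{p_depleted}.
#' @slot nSim number of permutations behind the null.
#' @name EnrichmentProfile-class
#' @exportClass EnrichmentProfile
setClass("EnrichmentProfile",
  representation(table = "data.frame", nSim = "integer")
)

#' PairEnrichment: intervening-site enrichment for a class of feature pairs
#'
#' Count of site midpoints falling strictly between paired genomic
#' features (divergent promoters, CRM/target promoter, ...) compared to a
#' uniform permutation null.
#'
#' @slot label pair-class label.
#' @slot observed observed total intervening count.
#' @slot nullMedian,nullLo,nullHi permutation-null summaries.
#' @slot log2Enrichment \code{log2(observed / null median)}.
#' @slot ciLo,ciHi log2 interval from the null percentiles.
#' @slot pEnriched,pDepleted one-sided empirical p-values (+1 pseudo-count).
#' @slot nPairs number of feature pairs; \code{nSim} permutations used.
#' @slot nullCounts the full vector of permutation-null counts, kept for
#'   calibration diagnostics.
#' @name PairEnrichment-class
#' @exportClass PairEnrichment
setClass("PairEnrichment",
  representation(
    label = "character",
    observed = "numeric",
    nullMedian = "numeric",
    nullLo = "numeric",
    nullHi = "numeric",
    log2Enrichment = "numeric",
    ciLo = "numeric",
    ciHi = "numeric",
    pEnriched = "numeric",
    pDepleted = "numeric",
    nPairs = "integer",
    nSim = "integer",
    nullCounts = "numeric"
  )
)

#' CombinationTable: signature counts of multi-factor clusters vs simulation
#'
#' One row per binding-site combination signature (the set of factors
#' co-occurring in a cluster): observed cluster count, simulated null
#' median, and empirical enrichment/depletion p-values.
#'
#' @slot table data.frame with columns \code{signature}, \code{observed},
#'   \code{null_median}, \code{p_enriched}, \code{p_depleted}.
#' @slot nSim number of simulations.
#' @name CombinationTable-class
#' @exportClass CombinationTable
setClass("CombinationTable",
  representation(table = "data.frame", nSim = "integer")
)

#' HmmParams: Gaussian hidden Markov model parameters
#'
#' @slot means,variances per-state Gaussian emission parameters (states
#'   ordered by increasing mean).
#' @slot transition row-stochastic transition matrix.
#' @slot initial initial state distribution.
#' @slot logLik per-iteration log-likelihood trace of the Baum-Welch fit.
#' @slot converged whether the fit reached the tolerance before max_iter.
#' @name HmmParams-class
#' @exportClass HmmParams
setClass("HmmParams",
  representation(
    means = "numeric",
    variances = "numeric",
    transition = "matrix",
    initial = "numeric",
    logLik = "numeric",
    converged = "logical"
  )
)

setValidity("HmmParams", function(object) {
  msg <- NULL
  k <- length(object@means)
  if (length(object@variances) != k || any(object@variances <= 0))
    msg <- c(msg, "variances must be positive, one per state")
  if (!all(dim(object@transition) == c(k, k)) ||
      any(abs(rowSums(object@transition) - 1) > 1e-9))
    msg <- c(msg, "transition rows must sum to 1")
  if (length(object@initial) != k || abs(sum(object@initial) - 1) > 1e-9)
    msg <- c(msg, "initial distribution must sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' DomainSet: segmented chromatin domains and their boundaries
#'
#' @slot domains non-overlapping sorted \code{GRanges} of domains.
#' @slot boundaries \code{GRanges} points at the domain edges, with a
#'   \code{side} column (\code{"left"}/\code{"right"}); left edges carry
#'   strand \code{-} and right edges \code{+} so that signed distances are
#'   negative inside the domain.
#' @slot source id of the signal track the domains came from.
#' @name DomainSet-class
#' @exportClass DomainSet
setClass("DomainSet",
  representation(domains = "GRanges", boundaries = "GRanges",
                 source = "character")
)

setValidity("DomainSet", function(object) {
  msg <- NULL
  d <- object@domains
  if (length(d)) {
    if (is.unsorted(order(as.integer(seqnames(d)), start(d))) &&
        !identical(order(as.integer(seqnames(d)), start(d)), seq_along(d)))
      msg <- c(msg, "domains must be sorted")
    red <- reduce(d)
    if (sum(width(red)) != sum(width(d)))
      msg <- c(msg, "domains must not overlap")
  }
  if (length(object@boundaries) != 2L * length(d))
    msg <- c(msg, "there must be exactly two boundaries per domain")
  if (is.null(msg)) TRUE else msg
})

#' MetaProfile: average signal around aligned site midpoints
#'
#' @slot offsets bin-center offsets in bp, symmetric about 0.
#' @slot means per-bin mean signal over all (site, probe) pairs.
#' @slot counts per-bin number of contributing (site, probe) pairs.
#' @slot halfWidth,binWidth the aggregation window geometry.
#' @name MetaProfile-class
#' @exportClass MetaProfile
setClass("MetaProfile",
  representation(
    offsets = "numeric",
    means = "numeric",
    counts = "integer",
    halfWidth = "integer",
    binWidth = "integer"
  )
)

#' PWM: position weight matrix
#'
#' Letter probabilities per motif column plus the background from which
#' log-odds scores are derived.
#'
#' @slot probs 4 x width matrix of column probabilities (rows A,C,G,T).
#' @slot background length-4 background letter probabilities.
#' @slot name motif name.
#' @name PWM-class
#' @exportClass PWM
setClass("PWM",
  representation(probs = "matrix", background = "numeric", name = "character")
)

setValidity("PWM", function(object) {
  msg <- NULL
  if (nrow(object@probs) != 4L)
    msg <- c(msg, "probs must have 4 rows (A,C,G,T)")
  if (ncol(object@probs) < 1L)
    msg <- c(msg, "motif width must be >= 1")
  if (any(abs(colSums(object@probs) - 1) > 1e-9))
    msg <- c(msg, "each column of probs must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9 || any(object@background <= 0))
    msg <- c(msg, "background must be 4 positive probabilities summing to 1")
  if (is.null(msg)) TRUE else msg
})
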