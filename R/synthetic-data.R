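# Synthetic genomes with planted ground truth. The generator emulates the
# structures the analyses are designed to detect -- promoter-biased and
# co-bound site placement, divergent/adjacent/alternative promoter
# geometry, two-state domain signal, activity evidence and CRM links --
# so every downstream statistic can be checked against construction.

#' ScenarioConfig: parameters of a synthetic scenario
#'
#' @slot chromLengths named integer vector of chromosome lengths.
#' @slot nGenes number of genes.
#' @slot fracAltPromoter probability a gene carries a second distinct TSS.
#' @slot fracDivergent target fraction of genes arranged in divergent
#'   pairs (opposite strands, TSS gap uniform in [500, 2500] bp).
#' @slot factorSpecs data.frame with columns \code{factor}, \code{n_sites},
#'   \code{width}, \code{promoter_frac}, \code{pair_enrichment}.
#' @slot cobind named square matrix; entry (A, B) is the fraction of A's
#'   sites that receive a co-placed B site (midpoint jitter uniform in
#'   [-100, 100] bp).
#' @slot domainSpec list: \code{n_domains}, \code{mean_len}, \code{mu_in},
#'   \code{mu_out}, \code{sigma}, \code{probe_spacing}.
#' @slot pActive probability a promoter is active.
#' @slot activityNoise probability an activity label's evidence is flipped.
#' @slot nCrms number of CRM annotations.
#' @slot seed integer seed; same seed, same scenario, byte for byte.
#' @name ScenarioConfig-class
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(
    chromLengths = "integer", nGenes = "integer",
    fracAltPromoter = "numeric", fracDivergent = "numeric",
    factorSpecs = "data.frame", cobind = "matrix",
    domainSpec = "list", pActive = "numeric", activityNoise = "numeric",
    nCrms = "integer", seed = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- NULL
  probs <- c(object@fracAltPromoter, object@fracDivergent, object@pActive,
             object@activityNoise, object@factorSpecs$promoter_frac,
             as.vector(object@cobind))
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (any(object@factorSpecs$pair_enrichment < 0))
    msg <- c(msg, "pair_enrichment folds must be >= 0")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be > 0")
  if (object@nGenes < 2L)
    msg <- c(msg, "need at least 2 genes")
  if (is.null(msg)) TRUE else msg
})

#' Build a scenario configuration
#'
#' Defaults describe a compact but realistic testbed: three 2 Mb
#' chromosomes, 500 genes, four factors with 1,000 sites of 400 bp each
#' and no planted structure (uniform placement). Planted structure is
#' switched on by raising \code{promoter_frac}, \code{pair_enrichment},
#' or \code{cobind} entries.
#'
#' @param chromLengths chromosome lengths (named or not).
#' @param nGenes number of genes to place.
#' @param fracAltPromoter,fracDivergent promoter-geometry fractions.
#' @param factors factor names.
#' @param nSites sites per factor (recycled).
#' @param siteWidth site width in bp (recycled).
#' @param promoterFrac fraction of each factor's sites centred within
#'   500 bp upstream of a TSS (recycled).
#' @param pairEnrichment fold enrichment of each factor's sites between
#'   divergent promoter pairs, relative to uniform (recycled; 1 = none).
#' @param cobind named co-binding matrix (defaults to all zero).
#' @param nDomains,domainMeanLen,muIn,muOut,sigma,probeSpacing two-state
#'   domain track parameters.
#' @param pActive probability a promoter is active.
#' @param activityNoise evidence flip probability (default 0).
#' @param nCrms number of CRM annotations.
#' @param seed integer seed.
#' @return a \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(chromLengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                           nGenes = 500L,
                           fracAltPromoter = 0.2, fracDivergent = 0.25,
                           factors = c("A", "B", "C", "D"),
                           nSites = 1000L, siteWidth = 400L,
                           promoterFrac = 0, pairEnrichment = 1,
                           cobind = NULL,
                           nDomains = 20L, domainMeanLen = 5000L,
                           muIn = 2, muOut = 0, sigma = 0.5,
                           probeSpacing = 50L,
                           pActive = 0.6, activityNoise = 0,
                           nCrms = 100L, seed = 1L) {
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  fs <- data.frame(
    factor = factors,
    n_sites = as.integer(rep_len(nSites, length(factors))),
    width = as.integer(rep_len(siteWidth, length(factors))),
    promoter_frac = rep_len(promoterFrac, length(factors)),
    pair_enrichment = rep_len(pairEnrichment, length(factors)),
    stringsAsFactors = FALSE
  )
  if (is.null(cobind)) {
    cobind <- matrix(0, length(factors), length(factors),
                     dimnames = list(factors, factors))
  }
  new("ScenarioConfig",
      chromLengths = setNames(as.integer(chromLengths), names(chromLengths)),
      nGenes = as.integer(nGenes),
      fracAltPromoter = fracAltPromoter, fracDivergent = fracDivergent,
      factorSpecs = fs, cobind = cobind,
      domainSpec = list(n_domains = as.integer(nDomains),
                        mean_len = as.integer(domainMeanLen),
                        mu_in = muIn, mu_out = muOut, sigma = sigma,
                        probe_spacing = as.integer(probeSpacing)),
      pActive = pActive, activityNoise = activityNoise,
      nCrms = as.integer(nCrms), seed = as.integer(seed))
}

#' Generate a genome and gene set with planted promoter geometry
#'
#' Genes are placed without overlap, left to right per chromosome.
#' A binomially-drawn number of gene pairs are laid out divergently
#' (opposite strands, TSS gap uniform in [500, 2500] bp); remaining genes
#' are single with random strand and random inter-unit gaps, which
#' naturally yields adjacent TSS pairs in the 1.5-20 kb range. Each gene
#' independently gains a second, downstream-shifted TSS with probability
#' \code{fracAltPromoter}. CRMs are placed upstream of randomly chosen
#' target genes.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @return list with \code{genome} (Seqinfo), \code{genes}
#'   (\linkS4class{GeneModels}), \code{crms} (data.frame: chrom, start0,
#'   end0, crm_id, target_gene) and \code{truth} (divergent pairs,
#'   alternative-promoter gene ids, realized fractions).
#' @export
generateGenomeAndGenes <- function(config) {
  stopifnot(is(config, "ScenarioConfig"))
  withSeed(deriveSeed(config@seed, "genes"), {
    genome <- makeGenome(names(config@chromLengths), config@chromLengths)
    n <- config@nGenes
    nPairs <- rbinom(1L, n %/% 2L, config@fracDivergent)
    nSingles <- n - 2L * nPairs
    unit_type <- sample(c(rep("pair", nPairs), rep("single", nSingles)))
    chroms <- names(config@chromLengths)
    unit_chrom <- sample(chroms, length(unit_type), replace = TRUE,
                         prob = config@chromLengths)

    rows <- vector("list", length(chroms))
    div_pairs <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      cn <- chroms[ci]
      idx <- which(unit_chrom == cn)
      if (!length(idx)) next
      types <- unit_type[idx]
      k <- length(idx)
      gap <- runifInt(k, 6001L) + 2000L            # inter-unit gap 2-8 kb
      L1 <- runifInt(k, 2501L) + 1500L             # gene body 1.5-4 kb
      L2 <- runifInt(k, 2501L) + 1500L
      tg <- runifInt(k, 2001L) + 500L              # divergent TSS gap
      uw <- ifelse(types == "pair", L1 + tg + L2, L1)
      ends <- cumsum(as.numeric(gap) + as.numeric(uw))
      if (ends[k] > config@chromLengths[cn] - 1000)
        stop("capacity error: genes do not fit on chromosome ", cn)
      ustart <- as.integer(ends - uw)
      isp <- types == "pair"
      # pair geometry (0-based): gene1 on '-' occupies [u, u+L1),
      # TSS1 = u+L1-1; gene2 on '+' starts at TSS2 = TSS1 + tss_gap.
      p_u <- ustart[isp]; p_L1 <- L1[isp]; p_L2 <- L2[isp]; p_tg <- tg[isp]
      tss1 <- p_u + p_L1 - 1L
      tss2 <- tss1 + p_tg
      s_strand <- sample(c("+", "-"), sum(!isp), replace = TRUE)
      rows[[ci]] <- data.frame(
        chrom = cn,
        start0 = c(p_u, tss2, ustart[!isp]),
        len = c(p_L1, p_L2, L1[!isp]),
        strand = c(rep("-", sum(isp)), rep("+", sum(isp)), s_strand),
        stringsAsFactors = FALSE
      )
      if (any(isp))
        div_pairs[[ci]] <- data.frame(chrom = cn, tss1 = tss1, tss2 = tss2)
    }
    gdf <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    gdf <- gdf[order(gdf$chrom, gdf$start0), , drop = FALSE]
    ng <- nrow(gdf)
    gdf$gene_id <- sprintf("g%04d", seq_len(ng))
    gdf$alt <- runif(ng) < config@fracAltPromoter

    genes <- GRanges(gdf$chrom, IRanges(gdf$start0 + 1L, gdf$start0 + gdf$len),
                     strand = gdf$strand, gene_id = gdf$gene_id,
                     alt_promoter = gdf$alt, seqinfo = genome)

    # transcripts: primary = full gene body; alternative promoter = 5' end
    # shifted into the gene by 300-800 bp, same 3' end.
    shift <- runifInt(ng, 501L) + 300L
    tx_start <- c(gdf$start0,
                  ifelse(gdf$strand == "+", gdf$start0 + shift,
                         gdf$start0)[gdf$alt])
    tx_end <- c(gdf$start0 + gdf$len,
                ifelse(gdf$strand == "+", gdf$start0 + gdf$len,
                       gdf$start0 + gdf$len - shift)[gdf$alt])
    tx_chrom <- c(gdf$chrom, gdf$chrom[gdf$alt])
    tx_strand <- c(gdf$strand, gdf$strand[gdf$alt])
    tx_gene <- c(gdf$gene_id, gdf$gene_id[gdf$alt])
    tx_id <- c(paste0(gdf$gene_id, ".t1"),
               paste0(gdf$gene_id, ".t2")[gdf$alt])
    tx <- GRanges(tx_chrom, IRanges(tx_start + 1L, tx_end),
                  strand = tx_strand, tx_id = tx_id, gene_id = tx_gene,
                  seqinfo = genome)

    # two exons per transcript with a central intron; UTRs are the
    # terminal 150 bp at each transcript end, inside the terminal exons.
    tl <- width(tx)
    e1 <- pmax(300L, as.integer(round(tl * 0.35)))
    intr <- pmax(100L, as.integer(round(tl * 0.2)))
    e1 <- pmin(e1, tl - intr - 300L)
    ex_s <- c(start(tx), start(tx) + e1 + intr)
    ex_e <- c(start(tx) + e1 - 1L, end(tx))
    exons <- GRanges(rep(as.character(seqnames(tx)), 2),
                     IRanges(ex_s, ex_e),
                     strand = rep(as.character(strand(tx)), 2),
                     tx_id = rep(tx_id, 2), gene_id = rep(tx_gene, 2),
                     seqinfo = genome)
    plus <- as.character(strand(tx)) == "+"
    u5 <- GRanges(as.character(seqnames(tx)),
                  IRanges(ifelse(plus, start(tx), end(tx) - 149L),
                          ifelse(plus, start(tx) + 149L, end(tx))),
                  strand = as.character(strand(tx)), tx_id = tx_id,
                  seqinfo = genome)
    u3 <- GRanges(as.character(seqnames(tx)),
                  IRanges(ifelse(plus, end(tx) - 149L, start(tx)),
                          ifelse(plus, end(tx), start(tx) + 149L)),
                  strand = as.character(strand(tx)), tx_id = tx_id,
                  seqinfo = genome)
    gm <- GeneModels(genes, tx, exons, u5, u3)

    # CRMs: upstream of sampled target genes; sampling with replacement
    # gives some genes several CRMs (needed for CRM-CRM pair analyses).
    crms <- NULL
    if (config@nCrms > 0L) {
      tgt <- sample(gdf$gene_id, config@nCrms, replace = TRUE)
      ti <- match(tgt, gdf$gene_id)
      d <- runifInt(config@nCrms, 7001L) + 1000L
      tss0 <- ifelse(gdf$strand[ti] == "+", gdf$start0[ti],
                     gdf$start0[ti] + gdf$len[ti] - 1L)
      mid <- ifelse(gdf$strand[ti] == "+", tss0 - d, tss0 + d)
      len <- config@chromLengths[gdf$chrom[ti]]
      mid <- pmax(150L, pmin(as.integer(len) - 151L, as.integer(mid)))
      crms <- data.frame(chrom = gdf$chrom[ti], start0 = mid - 150L,
                         end0 = mid + 150L,
                         crm_id = sprintf("crm%04d", seq_len(config@nCrms)),
                         target_gene = tgt, stringsAsFactors = FALSE)
      crms <- crms[order(crms$chrom, crms$start0), , drop = FALSE]
    }

    dp <- do.call(rbind, div_pairs[!vapply(div_pairs, is.null, TRUE)])
    truth <- list(
      divergent_pairs = dp,
      alt_promoter_genes = gdf$gene_id[gdf$alt],
      frac_divergent_realized = if (ng) 2 * nPairs / ng else 0,
      frac_alt_realized = mean(gdf$alt)
    )
    list(genome = genome, genes = gm, crms = crms, truth = truth)
  })
}

#' Generate binding sites with planted promoter bias, pair enrichment and
#' co-binding
#'
#' Factors are processed in the order of \code{factorSpecs}. For factor B,
#' each earlier factor A donates \code{round(cobind[A,B] * nA)} co-placed
#' sites (A midpoints plus uniform jitter in [-100, 100] bp). Remaining
#' sites are each, independently: centred within 500 bp upstream of a
#' random TSS with probability \code{promoter_frac}; otherwise placed
#' between a random divergent promoter pair with probability
#' \code{min(1, fold * a)} (where \code{a} is the genomic fraction covered
#' by divergent gaps), so the expected fold enrichment of the intervening
#' count relative to uniform equals the configured \code{pair_enrichment};
#' otherwise uniform outside those gaps.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param genome \code{Seqinfo} from \code{generateGenomeAndGenes}.
#' @param genes \code{GeneModels} from the same call.
#' @param divergentPairs data.frame(chrom, tss1, tss2); defaults to the
#'   truth emitted by \code{generateGenomeAndGenes}.
#' @return list with \code{sites} (named list of \linkS4class{SiteSet})
#'   and \code{truth} (realized promoter fractions, achieved pair folds,
#'   co-binding donor counts).
#' @export
generateSites <- function(config, genome, genes, divergentPairs = NULL) {
  stopifnot(nrow(config@factorSpecs) > 0L)
  withSeed(deriveSeed(config@seed, "sites"), {
    fs <- config@factorSpecs
    chroms <- GenomeInfoDb::seqnames(genome)
    lens <- seqlengths(genome)
    total_bp <- sum(as.numeric(lens))
    tss <- tssPoints(genes)

    spans <- divergentPairs
    span_bp <- if (is.null(spans) || !nrow(spans)) 0 else
      sum(pmax(0, spans$tss2 - spans$tss1 - 1))
    a_frac <- span_bp / total_bp
    span_cum <- if (span_bp > 0)
      cumsum(as.numeric(pmax(0, spans$tss2 - spans$tss1 - 1))) else numeric()

    sites <- list()
    truth <- list(promoter_frac_realized = numeric(),
                  achieved_fold = numeric(), cobind_donated = list())

    uniformMid <- function(k) {
      # uniform over the genome: chromosome prob proportional to length
      ci <- sample(seq_along(lens), k, replace = TRUE, prob = lens)
      list(chrom = chroms[ci], mid = runifInt(k, lens[ci]))
    }
    drawInSpan <- function(k) {
      # uniform over the union of divergent gaps (interior, endpoints
      # excluded so planted sites are strictly intervening)
      u <- runif(k) * span_bp
      pi <- findInterval(u, c(0, span_cum), rightmost.closed = TRUE)
      off <- as.integer(floor(u - c(0, span_cum)[pi]))
      list(chrom = spans$chrom[pi], mid = spans$tss1[pi] + 1L + off)
    }

    for (i in seq_len(nrow(fs))) {
      fname <- fs$factor[i]
      n <- fs$n_sites[i]; w <- fs$width[i]
      fold <- fs$pair_enrichment[i]; pf <- fs$promoter_frac[i]

      cb_chrom <- character(); cb_mid <- integer(); donated <- integer()
      for (aname in names(sites)) {
        p <- config@cobind[aname, fname]
        if (is.na(p) || p <= 0) next
        amid <- siteMidpoints(sites[[aname]])
        achr <- as.character(seqnames(sites[[aname]]))
        kA <- round(p * length(amid))
        pick <- if (kA >= length(amid)) seq_along(amid) else
          sample(length(amid), kA)
        jit <- runifInt(length(pick), 201L) - 100L
        cb_chrom <- c(cb_chrom, achr[pick])
        cb_mid <- c(cb_mid, amid[pick] + jit)
        donated[aname] <- length(pick)
      }
      if (length(cb_mid) > n)
        stop("capacity error: co-binding copies exceed n_sites for ", fname)

      n_rem <- n - length(cb_mid)
      is_prom <- runif(n_rem) < pf
      n_prom <- sum(is_prom)
      pr_chrom <- character(); pr_mid <- integer()
      if (n_prom > 0L) {
        ti <- sample(nrow(tss), n_prom, replace = TRUE)
        off <- runifInt(n_prom, 501L)     # 0..500 bp upstream
        pr_mid <- ifelse(tss$strand[ti] == "+", tss$pos[ti] - off,
                         tss$pos[ti] + off)
        pr_chrom <- tss$chrom[ti]
      }
      n_bg <- n_rem - n_prom
      bg_chrom <- character(); bg_mid <- integer(); n_in <- 0L
      if (n_bg > 0L) {
        p_in <- if (fold == 1 || a_frac == 0) a_frac else
          min(1, fold * a_frac)
        inside <- runif(n_bg) < p_in
        n_in <- sum(inside)
        if (fold == 1 || a_frac == 0) {
          u <- uniformMid(n_bg)
          bg_chrom <- u$chrom; bg_mid <- u$mid
        } else {
          bg_chrom <- character(n_bg); bg_mid <- integer(n_bg)
          if (n_in > 0L) {
            s <- drawInSpan(n_in)
            bg_chrom[inside] <- s$chrom; bg_mid[inside] <- s$mid
          }
          n_out <- n_bg - n_in
          if (n_out > 0L) {
            # uniform outside the spans by rejection (spans cover a tiny
            # genomic fraction, so few redraws are needed)
            got <- 0L; oc <- character(n_out); om <- integer(n_out)
            while (got < n_out) {
              u <- uniformMid(2L * (n_out - got) + 10L)
              keep <- !insideSpans(u$chrom, u$mid, spans)
              kc <- u$chrom[keep]; km <- u$mid[keep]
              take <- min(length(km), n_out - got)
              if (take > 0L) {
                oc[got + seq_len(take)] <- kc[seq_len(take)]
                om[got + seq_len(take)] <- km[seq_len(take)]
                got <- got + take
              }
            }
            bg_chrom[!inside] <- oc; bg_mid[!inside] <- om
          }
        }
      }

      chrom <- c(cb_chrom, pr_chrom, bg_chrom)
      mid <- c(cb_mid, pr_mid, bg_mid)
      half <- w %/% 2L
      mid <- pmax(half, pmin(as.integer(lens[chrom]) - (w - half) - 1L,
                             as.integer(mid)))
      ss <- SiteSet(chrom, mid - half, mid - half + w, factorName = fname,
                    genome = genome)
      sites[[fname]] <- ss
      truth$promoter_frac_realized[fname] <-
        if (n_rem > 0) n_prom / n_rem else NA_real_
      truth$achieved_fold[fname] <-
        if (n_bg > 0 && a_frac > 0) (n_in / n_bg) / a_frac else NA_real_
      truth$cobind_donated[[fname]] <- donated
    }
    list(sites = sites, truth = truth)
  })
}

# TRUE for midpoints strictly inside a divergent gap (tss1, tss2).
insideSpans <- function(chrom, mid, spans) {
  if (is.null(spans) || !nrow(spans)) return(rep(FALSE, length(mid)))
  out <- rep(FALSE, length(mid))
  for (cn in unique(chrom)) {
    sp <- spans[spans$chrom == cn, , drop = FALSE]
    if (!nrow(sp)) next
    sel <- chrom == cn
    m <- mid[sel]
    o <- order(sp$tss1)
    fi <- findInterval(m, sp$tss1[o])
    hit <- fi > 0 & m > sp$tss1[o][pmax(fi, 1)] & m < sp$tss2[o][pmax(fi, 1)]
    out[sel] <- hit
  }
  out
}

#' Generate a two-state domain signal track
#'
#' Domains of length uniform in [0.5, 1.5] x \code{mean_len} are placed
#' without overlap (slack distributed uniformly between them); probes are
#' laid every \code{probe_spacing} bp and draw from
#' \code{Normal(mu_in, sigma)} inside a true domain and
#' \code{Normal(mu_out, sigma)} outside.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param genome \code{Seqinfo}.
#' @return list with \code{track} (\linkS4class{SignalTrack}) and
#'   \code{truth} (GRanges of true domains).
#' @export
generateDomainTrack <- function(config, genome) {
  ds <- config@domainSpec
  if (ds$probe_spacing <= 0L) stop("probe_spacing must be > 0")
  if (ds$mu_in <= ds$mu_out) stop("mu_in must exceed mu_out")
  withSeed(deriveSeed(config@seed, "domains"), {
    chroms <- GenomeInfoDb::seqnames(genome)
    lens <- seqlengths(genome)
    k <- ds$n_domains
    dchrom <- if (k > 0)
      sample(chroms, k, replace = TRUE, prob = lens) else character()
    doms <- NULL
    for (cn in unique(dchrom)) {
      kk <- sum(dchrom == cn)
      dl <- as.integer(round(runif(kk, 0.5, 1.5) * ds$mean_len))
      slack <- lens[cn] - sum(dl)
      if (slack < 0) stop("capacity error: domains do not fit on ", cn)
      cuts <- sort(runif(kk))
      gaps <- diff(c(0, cuts, 1)) * slack
      s0 <- as.integer(floor(cumsum(gaps[seq_len(kk)]) +
                               c(0, cumsum(dl))[seq_len(kk)]))
      doms <- rbind(doms, data.frame(chrom = cn, start0 = s0,
                                     end0 = s0 + dl))
    }
    truth <- if (is.null(doms)) GRanges(seqinfo = genome) else
      sort(GRanges(doms$chrom, IRanges(doms$start0 + 1L, doms$end0),
                   seqinfo = genome))

    pc <- character(); pp <- integer(); pv <- numeric()
    for (cn in chroms) {
      pos <- seq.int(0L, lens[cn] - 1L, by = ds$probe_spacing)
      inside <- rep(FALSE, length(pos))
      if (!is.null(doms)) {
        dd <- doms[doms$chrom == cn, , drop = FALSE]
        if (nrow(dd)) {
          o <- order(dd$start0)
          fi <- findInterval(pos, dd$start0[o])
          inside <- fi > 0 & pos < dd$end0[o][pmax(fi, 1)]
        }
      }
      mu <- ifelse(inside, ds$mu_in, ds$mu_out)
      val <- if (ds$sigma > 0) rnorm(length(pos), mu, ds$sigma) else mu
      pc <- c(pc, rep(cn, length(pos))); pp <- c(pp, pos); pv <- c(pv, val)
    }
    list(track = SignalTrack(pc, pp, pv), truth = truth)
  })
}

#' Generate promoter-activity evidence (H3K4me3, PolII, RNA)
#'
#' Activity is drawn per gene with probability \code{pActive}; all TSS
#' of a gene share the label (promoters a few hundred bp apart with
#' shared exons are not separable by overlap evidence, so per-gene
#' labels keep the ground truth recoverable). Every TSS of an active
#' gene emits an H3K4me3 interval and a PolII interval overlapping the
#' TSS, and the gene emits an RNA interval inside an exon; inactive
#' genes emit nothing. With probability \code{activityNoise} a gene's
#' evidence is flipped (an active gene emits nothing, an inactive one
#' emits everything), so caller accuracy degrades linearly in the noise.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param genes \code{GeneModels}.
#' @return list with \code{h3k4me3}, \code{polII}, \code{rna}
#'   (\linkS4class{SiteSet}s) and \code{truth} (data.frame of TSS labels).
#' @export
generateActivityEvidence <- function(config, genes) {
  withSeed(deriveSeed(config@seed, "activity"), {
    tss <- tssPoints(genes)
    gids <- unique(tss$gene_id)
    gActive <- setNames(runif(length(gids)) < config@pActive, gids)
    gFlip <- setNames(runif(length(gids)) < config@activityNoise, gids)
    gEmits <- xor(gActive, gFlip)
    active <- unname(gActive[tss$gene_id])
    emits <- unname(gEmits[tss$gene_id])

    ex <- genes@exons
    ex_by_tx <- split(seq_along(ex), mcols(ex)$tx_id)

    idx <- which(emits)
    mkset <- function(chrom, mid, w, name) {
      if (!length(mid))
        return(SiteSet(character(), integer(), integer(), factorName = name))
      SiteSet(chrom, as.integer(mid) - w %/% 2L,
              as.integer(mid) + (w - w %/% 2L), factorName = name)
    }
    h3 <- mkset(tss$chrom[idx], tss$pos[idx], 400L, "H3K4me3")
    jit <- if (length(idx)) runifInt(length(idx), 101L) - 50L else integer()
    pol <- mkset(tss$chrom[idx], tss$pos[idx] + jit, 400L, "PolII")
    # one RNA interval per emitting transcript, strictly inside an exon
    # of that transcript so it cannot overlap a neighbouring gene
    rna_mid <- integer(); rna_chrom <- character()
    for (i in idx) {
      eidx <- ex_by_tx[[tss$tx_id[i]]]
      if (is.null(eidx)) next
      e <- ex[eidx[length(eidx)]]
      rna_mid <- c(rna_mid, as.integer((start(e) - 1L + end(e)) %/% 2L))
      rna_chrom <- c(rna_chrom, as.character(seqnames(e)))
    }
    rna <- mkset(rna_chrom, rna_mid, 300L, "RNA")
    truth <- cbind(tss, active = active, emits = emits)
    list(h3k4me3 = h3, polII = pol, rna = rna, truth = truth)
  })
}

#' Generate a complete scenario
#'
#' Runs all generators under the configuration's seed.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @return list: \code{genome}, \code{genes}, \code{crms}, \code{sites},
#'   \code{track}, \code{activity}, \code{truth}.
#' @export
generateScenario <- function(config) {
  gg <- generateGenomeAndGenes(config)
  st <- generateSites(config, gg$genome, gg$genes, gg$truth$divergent_pairs)
  dt <- generateDomainTrack(config, gg$genome)
  act <- generateActivityEvidence(config, gg$genes)
  list(
    genome = gg$genome, genes = gg$genes, crms = gg$crms,
    sites = st$sites, track = dt$track,
    activity = act[c("h3k4me3", "polII", "rna")],
    truth = c(gg$truth, st$truth,
              list(domains = dt$truth, activity = act$truth))
  )
}

#' Write a scenario directory
#'
#' Emits genome.tsv, genes.gff3, sites_<factor>.bed, track_domain.bedGraph,
#' activity evidence BEDs, crms.tsv and flat truth TSVs.
#'
#' @param scenario result of \code{generateScenario}.
#' @param dir output directory (created).
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenome(scenario$genome, file.path(dir, "genome.tsv"))
  writeGenes(scenario$genes, file.path(dir, "genes.gff3"))
  for (fn in names(scenario$sites))
    writeSites(scenario$sites[[fn]],
               file.path(dir, paste0("sites_", fn, ".bed")))
  writeTrack(scenario$track, file.path(dir, "track_domain.bedGraph"))
  for (nm in names(scenario$activity))
    writeSites(scenario$activity[[nm]],
               file.path(dir, paste0("evidence_", nm, ".bed")))
  if (!is.null(scenario$crms))
    write.table(scenario$crms, file.path(dir, "crms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  dom <- scenario$truth$domains
  if (length(dom))
    write.table(
      data.frame(chrom = as.character(seqnames(dom)),
                 start = start(dom) - 1L, end = end(dom)),
      file.path(dir, "truth_domains.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  write.table(scenario$truth$activity, file.path(dir, "truth_activity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
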