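# PWM instance statistics: exact p-value -> score threshold conversion
# by dynamic programming over the discrete score distribution, two-strand
# scanning, uniquely-bound window construction, exact hypergeometric
# enrichment and the conservative Wilson-ratio ranking statistic.

#' Construct a PWM from column probabilities
#'
#' @param probs 4 x width matrix (rows A, C, G, T) of column
#'   probabilities, or a matrix of counts (normalised internally).
#' @param name motif name.
#' @param background length-4 background probabilities (default uniform).
#' @return a \linkS4class{PWM}.
#' @export
makePWM <- function(probs, name = "motif",
                    background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A,C,G,T)")
  probs <- sweep(probs, 2, colSums(probs), "/")
  rownames(probs) <- c("A", "C", "G", "T")
  new("PWM", probs = probs, background = background, name = name)
}

#' Read PWMs from MEME minimal text format
#'
#' Parses \code{MOTIF} blocks with letter-probability matrices.
#'
#' @param path MEME minimal format file.
#' @return named list of \linkS4class{PWM}.
#' @export
readMemePwms <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi) && bgi[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    v <- v[!is.na(v)]
    if (length(v) == 4L) bg <- v / sum(v)
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    j <- s + 1L
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) next
    rows <- list()
    j <- j + 1L
    while (j <= length(lines)) {
      tok <- suppressWarnings(as.numeric(
        strsplit(trimws(lines[j]), "\\s+")[[1]]))
      if (length(tok) != 4L || anyNA(tok)) break
      rows[[length(rows) + 1L]] <- tok
      j <- j + 1L
    }
    if (length(rows))
      out[[name]] <- makePWM(t(do.call(rbind, rows)), name = name,
                             background = bg)
  }
  out
}

#' Score threshold for a target p-value, by exact DP
#'
#' Computes the full distribution of the PWM log-odds score of a random
#' background sequence by column-wise convolution on a discrete score
#' grid, and returns the smallest threshold \code{t} such that
#' \code{P(score >= t) <= p}. When \code{p} is below the attainable
#' granularity the maximal score is returned with a warning.
#'
#' @param pwm a \linkS4class{PWM}.
#' @param p target p-value in (0, 1); the conventional scanning
#'   stringency is \code{4^-8}.
#' @param background background probabilities (default the PWM's).
#' @param resolution score grid resolution (default 1e-3 score units).
#' @return numeric threshold in log2-odds units.
#' @export
pwmThresholdFromPvalue <- function(pwm, p, background = pwm@background,
                                   resolution = 1e-3) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  M <- round(pwmLogOdds(pwm) / resolution)
  w <- ncol(M)
  # dist over integer score offsets: start at 0
  off0 <- 0L
  dist <- 1
  for (j in seq_len(w)) {
    mj <- min(M[, j])
    shifted <- M[, j] - mj
    span <- max(shifted)
    nd <- numeric(length(dist) + span)
    for (l in 1:4) {
      idx <- seq_along(dist) + shifted[l]
      nd[idx] <- nd[idx] + dist * background[l]
    }
    dist <- nd
    off0 <- off0 + mj
  }
  tail <- rev(cumsum(rev(dist)))
  # restrict to attainable scores (grid points with positive mass)
  ok <- which(tail <= p & dist > 0)
  if (!length(ok)) {
    warning("p below attainable granularity; returning maximal score")
    return((off0 + max(which(dist > 0)) - 1L) * resolution)
  }
  (off0 + ok[1] - 1L) * resolution
}

#' Scan a sequence for PWM instances on both strands
#'
#' Windows containing N are skipped; overlapping instances are all
#' reported. An instance is reported when its log2-odds score is greater
#' than or equal to \code{threshold}; the threshold is applied per
#' strand-position.
#'
#' @param sequence a \code{DNAString}, character string, or named list /
#'   \code{DNAStringSet} (scanned per sequence).
#' @param pwm a \linkS4class{PWM}.
#' @param threshold minimum log2-odds score.
#' @return data.frame: \code{seqname}, \code{start0}, \code{end0}
#'   (0-based half-open), \code{strand}, \code{score}.
#' @export
scanInstances <- function(sequence, pwm, threshold) {
  if (is(sequence, "DNAStringSet") || is.list(sequence)) {
    nms <- if (is.null(names(sequence)))
      as.character(seq_along(sequence)) else names(sequence)
    out <- lapply(seq_along(sequence), function(i) {
      r <- scanInstances(sequence[[i]], pwm, threshold)
      if (nrow(r)) r$seqname <- nms[i]
      r
    })
    return(do.call(rbind, out))
  }
  s <- toupper(as.character(sequence))
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  w <- pwmWidth(pwm)
  L <- length(code)
  empty <- data.frame(seqname = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (L < w) return(empty)
  M <- pwmLogOdds(pwm)
  Mrc <- M[4:1, w:1]   # reverse-complement PWM
  nW <- L - w + 1L
  fwd <- numeric(nW); rev <- numeric(nW); valid <- rep(TRUE, nW)
  for (j in seq_len(w)) {
    cj <- code[j:(j + nW - 1L)]
    bad <- is.na(cj)
    valid <- valid & !bad
    cj[bad] <- 1L
    fwd <- fwd + M[cbind(cj, j)]
    rev <- rev + Mrc[cbind(cj, j)]
  }
  hitF <- which(valid & fwd >= threshold)
  hitR <- which(valid & rev >= threshold)
  out <- data.frame(
    seqname = rep("seq", length(hitF) + length(hitR)),
    start0 = c(hitF, hitR) - 1L,
    end0 = c(hitF, hitR) - 1L + w,
    strand = c(rep("+", length(hitF)), rep("-", length(hitR))),
    score = c(fwd[hitF], rev[hitR]),
    stringsAsFactors = FALSE
  )
  out[order(out$start0, out$strand), , drop = FALSE]
}

#' Uniquely-bound windows around focal peak centres
#'
#' Focal sites whose centre is at least \code{minSep} bp from every
#' other factor's centre yield windows centre +/- \code{flank} bp;
#' overlap with excluded regions is removed (windows are clipped and
#' dropped when fully excluded).
#'
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param focal name of the focal factor.
#' @param minSep minimum centre-to-centre separation (default 1000 bp;
#'   separation exactly equal to \code{minSep} is allowed).
#' @param flank window half-width (default 100 bp).
#' @param exclusions optional \code{GRanges} of excluded regions (coding
#'   exons, repeats, transposons, 3' UTRs, ...).
#' @return \code{GRanges} of windows.
#' @export
uniqueBoundWindows <- function(siteSets, focal, minSep = 1000L,
                               flank = 100L, exclusions = NULL) {
  if (!focal %in% names(siteSets)) stop("focal factor not supplied")
  fs <- siteSets[[focal]]
  others <- siteSets[setdiff(names(siteSets), focal)]
  eligible <- rep(TRUE, length(fs))
  if (length(others)) {
    ochrom <- unlist(lapply(others, function(s)
      as.character(seqnames(s))), use.names = FALSE)
    omid <- unlist(lapply(others, siteMidpoints), use.names = FALSE)
    # a neighbour strictly closer than minSep disqualifies the site
    eligible <- !hasNeighbor(as.character(seqnames(fs)), siteMidpoints(fs),
                             ochrom, omid, minSep)
  }
  mid <- siteMidpoints(fs)[eligible]
  chrom <- as.character(seqnames(fs))[eligible]
  if (!length(mid)) return(GRanges())
  win <- GRanges(chrom, IRanges(mid + 1L - flank, mid + 1L + flank))
  if (!is.null(exclusions) && length(exclusions))
    win <- GenomicRanges::setdiff(win, exclusions, ignore.strand = TRUE)
  reduce(win)
}

#' Exact hypergeometric enrichment of motif instances in regions
#'
#' Models instance placement as drawing \code{K} base pairs from the
#' \code{N} searchable base pairs, of which \code{n} lie in the regions
#' of interest: the enrichment p-value is the exact upper tail
#' \code{P(X >= k)} and the depletion p-value the lower tail
#' \code{P(X <= k)}.
#'
#' @param k instances observed in the regions.
#' @param K total instances.
#' @param n region size in bp.
#' @param N searchable size in bp.
#' @return named numeric: \code{p_enriched}, \code{p_depleted},
#'   \code{expected}.
#' @export
hypergeometricEnrichment <- function(k, K, n, N) {
  if (k > K) stop("k must not exceed K")
  if (n > N) stop("n must not exceed N")
  if (k > n) stop("k must not exceed n")
  c(p_enriched = phyper(k - 1, n, N - n, K, lower.tail = FALSE),
    p_depleted = phyper(k, n, N - n, K),
    expected = K * n / N)
}

#' Wilson-bound conservative enrichment ratio
#'
#' The ratio of the bound-region instance fraction to the control
#' instance fraction, made conservative by taking the Wilson score
#' interval lower bound of the numerator fraction and upper bound of the
#' denominator fraction at \code{z} (default 1.5).
#'
#' @param kBound,nBound instance count and total for the bound regions.
#' @param kCtrl,nCtrl instance count and total for the shuffled controls.
#' @param z Wilson z (default 1.5).
#' @return list: \code{ratio}, \code{lower_bound}, \code{upper_ctrl},
#'   \code{infinite} (TRUE when the control upper bound is 0).
#' @export
wilsonRatioEnrichment <- function(kBound, nBound, kCtrl, nCtrl, z = 1.5) {
  if (nBound <= 0 || nCtrl <= 0) stop("totals must be positive")
  lb <- wilsonBound(kBound / nBound, nBound, z, lower = TRUE)
  ub <- wilsonBound(kCtrl / nCtrl, nCtrl, z, lower = FALSE)
  if (ub == 0)
    return(list(ratio = Inf, lower_bound = lb, upper_ctrl = ub,
                infinite = TRUE))
  list(ratio = lb / ub, lower_bound = lb, upper_ctrl = ub,
       infinite = FALSE)
}

#' Wilson score interval bound for a binomial proportion
#'
#' @param phat observed proportion.
#' @param n number of trials.
#' @param z the z multiplier.
#' @param lower TRUE for the lower bound, FALSE for the upper.
#' @return the bound, clipped to [0, 1].
#' @export
wilsonBound <- function(phat, n, z, lower = TRUE) {
  s <- if (lower) -1 else 1
  b <- (phat + z^2 / (2 * n) +
          s * z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  min(max(b, 0), 1)
}

#' Shuffled control PWMs by column permutation
#'
#' Generates \code{n} column-order permutations of the PWM (never the
#' identity when the width permits a non-identity permutation), so the
#' per-column information content multiset is preserved exactly.
#'
#' @param pwm a \linkS4class{PWM}.
#' @param n number of shuffles.
#' @param seed integer seed.
#' @return list of \linkS4class{PWM}.
#' @export
shuffledControlPwms <- function(pwm, n, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  w <- pwmWidth(pwm)
  if (w < 2L) stop("cannot shuffle a PWM of width < 2")
  withSeed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        perm <- sample(w)
        if (!identical(perm, seq_len(w))) break
      }
      out[[i]] <- makePWM(pwm@probs[, perm, drop = FALSE],
                          name = paste0(pwm@name, "_shuf", i),
                          background = pwm@background)
    }
    out
  })
}
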