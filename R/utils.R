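# Shared statistical helpers: empirical p-values, null summaries, seeds.

#' Two one-sided empirical p-values with a +1 pseudo-count
#'
#' \code{p = (1 + #{null as or more extreme}) / (1 + n_sim)}; the minimal
#' attainable p is therefore \code{1/(1 + n_sim)} and no p can be 0.
#'
#' @param observed observed statistic (scalar).
#' @param null numeric vector of null statistics.
#' @return named numeric: \code{p_enriched} (fraction of null >= observed)
#'   and \code{p_depleted} (fraction <= observed), both pseudo-counted.
#' @export
empiricalP <- function(observed, null) {
  n <- length(null)
  if (n < 1L) stop("need at least one null replicate")
  c(p_enriched = (1 + sum(null >= observed)) / (1 + n),
    p_depleted = (1 + sum(null <= observed)) / (1 + n))
}

# Summarise an observed count against its permutation null: median,
# percentile interval, log2 enrichment and the log2 interval implied by
# normalising the observation with the null percentiles. log2 values are
# NA where the normaliser is 0.
nullSummary <- function(observed, null, ciLo = 2.5, ciHi = 97.5) {
  med <- median(null)
  qs <- quantile(null, c(ciLo, ciHi) / 100, names = FALSE, type = 7)
  p <- empiricalP(observed, null)
  log2ratio <- function(num, den) {
    if (is.na(den) || den == 0 || num == 0) NA_real_ else log2(num / den)
  }
  list(
    observed = observed, null_median = med,
    null_lo = qs[1], null_hi = qs[2],
    log2_enrichment = log2ratio(observed, med),
    ci_lo = log2ratio(observed, qs[2]),
    ci_hi = log2ratio(observed, qs[1]),
    p_enriched = unname(p["p_enriched"]),
    p_depleted = unname(p["p_depleted"])
  )
}

#' Derive a per-stage seed from a master seed
#'
#' Stable string hash (polynomial rolling hash mod a Mersenne prime) mixed
#' with the master seed, so pipeline stages get independent but
#' reproducible streams.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(master, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(master) * 7919) %% 2147483647)
}

# Run expr with a locally-set RNG seed (or untouched RNG if seed is NULL).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Integer uniform on [0, n) of length k (vectorised, no modulo bias worth
# worrying about at genomic scales).
runifInt <- function(k, n) {
  pmin(as.integer(floor(runif(k) * n)), as.integer(n - 1L))
}

# Split a vector of 0-based positions by chromosome, sorted.
splitSorted <- function(pos, chrom) {
  lapply(split(pos, chrom), sort.int, method = "quick")
}
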