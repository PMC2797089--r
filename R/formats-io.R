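# I/O for the standard genomic formats the pipeline touches. Coordinate
# conventions are fixed here once: BED and bedGraph are 0-based half-open,
# GFF3 is 1-based closed; internally ranges are standard Bioconductor
# 1-based GRanges and *points* (midpoints, TSS, boundaries) are reported
# 0-based, matching BED arithmetic.

#' Read binding sites from a BED file
#'
#' @param path BED file (>= 3 columns; column 5 is taken as score when
#'   present, otherwise score is 0).
#' @param factor factor label to attach to the set.
#' @param genome optional \code{Seqinfo} to validate against.
#' @return a \linkS4class{SiteSet}, sorted.
#' @export
readSites <- function(path, factor, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(SiteSet(character(), integer(), integer(), factorName = factor))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s0) | is.na(e0))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-integer coordinates")
  bad <- which(s0 >= e0)
  if (length(bad))
    stop("invalid BED line ", bad[1], ": start >= end")
  score <- rep(0, length(lines))
  has5 <- nf >= 5L
  if (any(has5)) {
    sc <- suppressWarnings(as.numeric(
      vapply(fields[has5], `[`, "", 5L)))
    score[has5][!is.na(sc)] <- sc[!is.na(sc)]
  }
  SiteSet(chrom, s0, e0, factorName = factor, score = score, genome = genome)
}

#' Write a SiteSet as BED (0-based half-open)
#'
#' @param sites a \code{SiteSet}.
#' @param path output path.
#' @param header optional comment lines to prepend (each gets a "#").
#' @export
writeSites <- function(sites, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  if (length(sites)) {
    df <- data.frame(
      chrom = as.character(seqnames(sites)),
      start = start(sites) - 1L,
      end = end(sites),
      name = paste0(factorName(sites), "_", seq_along(sites)),
      score = mcols(sites)$score
    )
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene / mRNA (or transcript) / exon features with ID/Parent
#' links; five_prime_UTR and three_prime_UTR features are used when
#' present. Genes whose transcripts have more than one distinct 5' end
#' are flagged \code{alt_promoter}.
#'
#' @param path GFF3 file.
#' @return a \linkS4class{GeneModels}.
#' @export
readGenes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  tx <- gff[type %in% c("mRNA", "transcript")]
  exons <- gff[type == "exon"]
  utr5 <- gff[type == "five_prime_UTR"]
  utr3 <- gff[type == "three_prime_UTR"]
  if (!length(genes)) stop("no gene features in ", path)
  if (any(!as.character(strand(tx)) %in% c("+", "-")))
    stop("transcript with unknown strand")
  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("gene with unknown strand")
  firstParent <- function(x) {
    p <- x$Parent
    ifelse(lengths(p) > 0L, vapply(p, function(v) v[1], ""), NA_character_)
  }
  tx_parent <- firstParent(tx)
  if (anyNA(tx_parent) || !all(tx_parent %in% genes$ID))
    stop("mRNA without parent gene")
  ex_parent <- firstParent(exons)
  if (anyNA(ex_parent) || !all(ex_parent %in% tx$ID))
    stop("exon without parent transcript")

  g <- granges(genes)
  mcols(g)$gene_id <- genes$ID
  t <- granges(tx)
  mcols(t)$tx_id <- tx$ID
  mcols(t)$gene_id <- tx_parent
  e <- granges(exons)
  mcols(e)$tx_id <- ex_parent
  mcols(e)$gene_id <- mcols(t)$gene_id[match(ex_parent, tx$ID)]
  u5 <- granges(utr5); u3 <- granges(utr3)
  if (length(u5)) mcols(u5)$tx_id <- firstParent(utr5)
  if (length(u3)) mcols(u3)$tx_id <- firstParent(utr3)

  tss <- ifelse(as.character(strand(t)) == "+", start(t) - 1L, end(t) - 1L)
  n_tss <- tapply(tss, mcols(t)$gene_id, function(p) length(unique(p)))
  mcols(g)$alt_promoter <- unname(n_tss[mcols(g)$gene_id] > 1L)
  GeneModels(g, t, e, u5, u3)
}

#' Write gene models as GFF3
#'
#' @param genes a \code{GeneModels}.
#' @param path output path.
#' @export
writeGenes <- function(genes, path) {
  fmt <- function(gr, type, id, parent = NULL) {
    attr <- if (is.null(parent)) sprintf("ID=%s", id) else
      sprintf("ID=%s;Parent=%s", id, parent)
    data.frame(
      seqid = as.character(seqnames(gr)), source = "insulatR",
      type = type, start = start(gr), end = end(gr), score = ".",
      strand = as.character(strand(gr)), phase = ".", attr = attr
    )
  }
  g <- genes@genes; t <- genes@transcripts; e <- genes@exons
  rows <- rbind(
    fmt(g, "gene", mcols(g)$gene_id),
    fmt(t, "mRNA", mcols(t)$tx_id, mcols(t)$gene_id),
    fmt(e, "exon", paste0(mcols(e)$tx_id, ":exon:", seq_along(e)),
        mcols(e)$tx_id)
  )
  if (length(genes@utr5))
    rows <- rbind(rows, fmt(genes@utr5, "five_prime_UTR",
                            paste0("u5:", seq_along(genes@utr5)),
                            mcols(genes@utr5)$tx_id))
  if (length(genes@utr3))
    rows <- rbind(rows, fmt(genes@utr3, "three_prime_UTR",
                            paste0("u3:", seq_along(genes@utr3)),
                            mcols(genes@utr3)$tx_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(rows, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe-level signal track from bedGraph
#'
#' Each record contributes one probe at its interval midpoint. Records
#' must not overlap within a chromosome.
#'
#' @param path 4-column bedGraph file.
#' @return a \linkS4class{SignalTrack}.
#' @export
readTrack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(SignalTrack(character(), integer(), numeric()))
  fields <- strsplit(lines, "[\t ]+")
  if (any(lengths(fields) < 4L))
    stop("malformed bedGraph line ", which(lengths(fields) < 4L)[1])
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- as.integer(vapply(fields, `[`, "", 2L))
  e0 <- as.integer(vapply(fields, `[`, "", 3L))
  val <- as.numeric(vapply(fields, `[`, "", 4L))
  if (anyNA(s0) || anyNA(e0) || anyNA(val))
    stop("malformed bedGraph record")
  if (any(s0 >= e0)) stop("bedGraph record with start >= end")
  o <- order(chrom, s0)
  chrom <- chrom[o]; s0 <- s0[o]; e0 <- e0[o]; val <- val[o]
  same <- chrom[-1] == chrom[-length(chrom)]
  if (length(s0) > 1L && any(same & s0[-1] < e0[-length(e0)]))
    stop("overlapping bedGraph records on the same chromosome")
  SignalTrack(chrom, floor((s0 + e0) / 2), val)
}

#' Write a SignalTrack as bedGraph
#'
#' Probes are written as 1 bp records at their positions, so a
#' write/read round trip preserves positions and values exactly.
#'
#' @param track a \code{SignalTrack}.
#' @param path output path.
#' @param header optional comment lines.
#' @export
writeTrack <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (length(track)) {
    df <- data.frame(track@chroms, track@positions, track@positions + 1L,
                     track@values)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a genome (chromosome sizes) from a two-column TSV
#'
#' @param path TSV with columns chrom, length (no header).
#' @return a \code{Seqinfo}.
#' @export
readGenome <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  makeGenome(df$chrom, df$length)
}

#' Write a genome as a chromosome-sizes TSV
#'
#' @param genome a \code{Seqinfo}.
#' @param path output path.
#' @export
writeGenome <- function(genome, path) {
  write.table(
    data.frame(GenomeInfoDb::seqnames(genome), seqlengths(genome)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
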