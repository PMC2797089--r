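# End-to-end orchestration: scenario generation (or loading a scenario
# directory) followed by the analysis stages in their natural order --
# clusters, positional profiles, promoter pairs, activity stratification,
# CRM partition, domain segmentation, meta-profiles -- with one master
# seed, per-stage derived seeds, and a manifest of everything that ran.

#' Run the full analysis pipeline on a scenario
#'
#' Either generates a synthetic scenario from \code{config} or loads one
#' from \code{inputDir} (a directory written by
#' \code{\link{writeScenario}}). Every output file carries a header with
#' the master seed and stage parameters; a run manifest records inputs,
#' parameters, per-stage seeds and failures. A failing stage does not
#' corrupt the outputs of completed stages; the pipeline errors at the
#' end if any stage failed.
#'
#' @param outDir output directory (created).
#' @param config a \linkS4class{ScenarioConfig} (ignored when
#'   \code{inputDir} is given).
#' @param inputDir optional scenario directory to load instead of
#'   simulating.
#' @param nSim permutations per enrichment statistic (default 1000).
#' @param seed master seed; per-stage seeds are derived by stable
#'   hashing of (master, stage name).
#' @param stages character vector of stages to run (default all):
#'   "cluster", "positional", "pairs", "activity", "crm", "domains",
#'   "profiles".
#' @return invisibly, the manifest list.
#' @export
runFullPipeline <- function(outDir, config = scenarioConfig(),
                            inputDir = NULL, nSim = 1000L, seed = 1L,
                            stages = c("cluster", "positional", "pairs",
                                       "activity", "crm", "domains",
                                       "profiles")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, n_sim = nSim, stages = stages,
                   package_version = as.character(packageVersion("insulatR")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stage_seeds = list(), failures = list())

  if (!is.null(inputDir)) {
    need <- file.path(inputDir, c("genome.tsv", "genes.gff3"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("missing required input: ", paste(miss, collapse = ", "))
    genome <- readGenome(file.path(inputDir, "genome.tsv"))
    genes <- readGenes(file.path(inputDir, "genes.gff3"))
    bedFiles <- list.files(inputDir, "^sites_.*\\.bed$", full.names = TRUE)
    sites <- lapply(bedFiles, function(f)
      readSites(f, sub("^sites_(.*)\\.bed$", "\\1", basename(f)), genome))
    names(sites) <- vapply(sites, factorName, "")
    trackFile <- file.path(inputDir, "track_domain.bedGraph")
    track <- if (file.exists(trackFile)) readTrack(trackFile) else NULL
    crmFile <- file.path(inputDir, "crms.tsv")
    crms <- if (file.exists(crmFile))
      read.table(crmFile, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else NULL
    activity_evidence <- NULL
    ev <- file.path(inputDir, paste0("evidence_",
                                     c("h3k4me3", "polII", "rna"), ".bed"))
    if (all(file.exists(ev)))
      activity_evidence <- list(h3k4me3 = readSites(ev[1], "H3K4me3"),
                                polII = readSites(ev[2], "PolII"),
                                rna = readSites(ev[3], "RNA"))
    scen <- list(genome = genome, genes = genes, sites = sites,
                 track = track, crms = crms,
                 activity = activity_evidence)
    manifest$input_dir <- inputDir
  } else {
    scen <- generateScenario(config)
    manifest$scenario_seed <- config@seed
  }

  hdr <- function(stage, sd)
    sprintf("insulatR %s | master seed %d | stage seed %d | n_sim %d",
            stage, seed, sd, nSim)
  writeTsv <- function(df, file, stage, sd) {
    con <- file(file.path(outDir, file), "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr(stage, sd)), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  runStage <- function(stage, fun) {
    if (!stage %in% stages) return()
    sd <- deriveSeed(seed, stage)
    manifest$stage_seeds[[stage]] <<- sd
    res <- tryCatch({ fun(sd); "ok" },
                    error = function(e) conditionMessage(e))
    if (!identical(res, "ok")) manifest$failures[[stage]] <<- res
  }
  cfgFor <- function(sd) enrichmentConfig(nSim = nSim, seed = sd)

  runStage("cluster", function(sd) {
    cl <- buildClusters(scen$sites)
    writeTsv(cl, "clusters.tsv", "cluster", sd)
    ct <- combinationSignificance(scen$sites, scen$genome, nSim = nSim,
                                  seed = sd)
    writeTsv(combinationTable(ct), "combinations.tsv", "cluster", sd)
  })

  runStage("positional", function(sd) {
    tss <- tssPoints(scen$genes)
    tes <- tesPoints(scen$genes)
    for (fn in names(scen$sites)) {
      pr <- positionalProfile(scen$sites[[fn]],
                              tss[, c("chrom", "pos", "strand")],
                              scen$genome, cfg = cfgFor(sd))
      writeTsv(profileTable(pr), paste0("tss_profile_", fn, ".tsv"),
               "positional", sd)
      pr2 <- positionalProfile(scen$sites[[fn]],
                               tes[, c("chrom", "pos", "strand")],
                               scen$genome, cfg = cfgFor(sd))
      writeTsv(profileTable(pr2), paste0("tes_profile_", fn, ".tsv"),
               "positional", sd)
      cat_res <- annotateSiteCategories(scen$sites[[fn]], scen$genes,
                                        scen$genome)
      writeTsv(data.frame(category = names(cat_res$counts),
                          count = cat_res$counts,
                          genome_fraction = cat_res$genome_fraction),
               paste0("categories_", fn, ".tsv"), "positional", sd)
    }
  })

  runStage("pairs", function(sd) {
    rows <- NULL
    for (mode in c("adjacent", "divergent", "alternative")) {
      pp <- selectPromoterPairs(scen$genes, mode)
      if (!nrow(pp)) next
      for (fn in names(scen$sites)) {
        pe <- interveningEnrichment(scen$sites[[fn]], pp, scen$genome,
                                    cfgFor(sd), label = mode)
        r <- asPairRow(pe); r$factor <- fn
        rows <- rbind(rows, r)
      }
    }
    writeTsv(rows, "pair_enrichment.tsv", "pairs", sd)
  })

  runStage("activity", function(sd) {
    if (is.null(scen$activity)) stop("no activity evidence available")
    act <- callActivePromoters(scen$genes, scen$activity$h3k4me3,
                               scen$activity$polII, scen$activity$rna)
    writeTsv(act, "promoter_activity.tsv", "activity", sd)
    rows <- NULL
    for (mode in c("adjacent", "divergent", "alternative")) {
      pp <- selectPromoterPairs(scen$genes, mode)
      if (!nrow(pp)) next
      for (fn in names(scen$sites)) {
        st <- stratifiedPairEnrichment(scen$sites[[fn]], pp, act,
                                       scen$genome, cfgFor(sd))
        for (nm in names(st)) {
          if (is.null(st[[nm]])) next
          r <- asPairRow(st[[nm]])
          r$factor <- fn; r$mode <- mode; r$stratum <- nm
          rows <- rbind(rows, r)
        }
      }
    }
    writeTsv(rows, "stratified_pair_enrichment.tsv", "activity", sd)
  })

  runStage("crm", function(sd) {
    if (is.null(scen$crms) || !nrow(scen$crms)) stop("no CRM annotations")
    rows <- NULL
    for (fn in names(scen$sites)) {
      ce <- crmPartitionEnrichment(scen$sites[[fn]], scen$crms,
                                   scen$genes, scen$genome, cfgFor(sd))
      for (nm in names(ce)) {
        if (is.null(ce[[nm]])) next
        r <- asPairRow(ce[[nm]]); r$factor <- fn; r$class <- nm
        rows <- rbind(rows, r)
      }
    }
    writeTsv(rows, "crm_enrichment.tsv", "crm", sd)
  })

  runStage("domains", function(sd) {
    if (is.null(scen$track)) stop("no domain track available")
    params <- fitDomainHmm(scen$track, seed = sd)
    ds <- decodeDomains(scen$track, params, source = "domain_track")
    dgr <- domainRanges(ds)
    writeTsv(data.frame(chrom = as.character(seqnames(dgr)),
                        start = start(dgr) - 1L, end = end(dgr)),
             "domains.bed.tsv", "domains", sd)
    tss <- tssPoints(scen$genes)
    rows <- NULL
    for (fn in names(scen$sites)) {
      io <- insideOutsideEnrichment(scen$sites[[fn]], ds, scen$genome,
                                    cfgFor(sd))
      rows <- rbind(rows,
                    cbind(asPairRow(io$inside), factor = fn),
                    cbind(asPairRow(io$outside), factor = fn))
      chi <- boundaryTssIndependence(scen$sites[[fn]],
                                     tss[, c("chrom", "pos")], ds)
      if (isTRUE(chi$computable))
        rows$chisq_p[rows$factor == fn] <- chi$p_value
    }
    writeTsv(rows, "domain_enrichment.tsv", "domains", sd)
  })

  runStage("profiles", function(sd) {
    if (is.null(scen$track)) stop("no track available")
    for (fn in names(scen$sites)) {
      mp <- aggregateTrack(scen$sites[[fn]], scen$track)
      writeTsv(metaProfileTable(mp), paste0("meta_profile_", fn, ".tsv"),
               "profiles", sd)
    }
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(manifest$failures))
    stop("pipeline stages failed: ",
         paste(names(manifest$failures), collapse = ", "),
         " (see manifest.json)")
  invisible(manifest)
}
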