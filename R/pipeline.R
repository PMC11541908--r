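# Config-driven end-to-end pipeline with logging and provenance.

#' Default pipeline configuration
#'
#' @return nested list of every stage's parameters with their defaults
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1,
    outDir = "kelpfold-run",
    simulate = list(enabled = TRUE, depth = 1e6),
    inputs = list(pairs = NULL, coo = NULL, chromSizes = NULL,
                  binSize = 1e4, gcTrack = NULL, fasta = NULL,
                  repeats = NULL, peaks = NULL, genes = NULL),
    mask = list(minFrac = 0.02),
    balance = list(tol = 1e-5, maxIter = 200),
    decay = list(sMin = 1e4, sMax = 5e5, logBinsPerDecade = 8),
    compartments = list(mode = "trans", signTol = 0.05),
    aggregate = list(nPseudo = 100, window = 5, tauC = 1.5, tauR = 1.5),
    insulation = list(window = 1e5, minStrength = 0.5,
                      densityThreshold = 1),
    centromeres = list(coarseBinSize = 5e4, windowHalfWidth = 2e5,
                       minSpecificity = 0.9, minChromFraction = 1),
    telomeres = list(motif = "TTAGGG", minCopies = 5, maxOffset = 2000),
    integrate = list(padjMax = 0.01, lfcMin = 1))
}

# recursive defaults merge: user values win
mergeConfig <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) {
      user[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      user[[nm]] <- mergeConfig(user[[nm]], defaults[[nm]])
    }
  }
  user
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing keys take their defaults
#'   (see [defaultRunConfig()])
#' @return merged configuration list
#' @export
readRunConfig <- function(path) {
  mergeConfig(yaml::read_yaml(path), defaultRunConfig())
}

# stable hash of the effective configuration
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

# per-stage seed derivation: global seed fanned out deterministically
stageSeed <- function(seed, stageIndex) {
  (as.numeric(seed) * 1009 + 97 * stageIndex) %% 2147483647
}

#' Run the full analysis pipeline
#'
#' Executes bin -> mask -> balance -> decay -> compartments -> aggregate ->
#' insulation -> centromeres/telomeres -> integrate in dependency order,
#' writing per-stage text outputs plus a JSON summary carrying the config
#' hash and seed.  A stage failure aborts with the stage name; that stage's
#' outputs are retained with a `.partial` suffix.
#'
#' @param config configuration list (see [defaultRunConfig()]) or a YAML
#'   path
#' @param outDir output directory (default from the config)
#' @return (invisibly) the summary list, also written as `summary.json`
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- mergeConfig(config, defaultRunConfig())
  if (is.null(outDir)) outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  logPath <- file.path(outDir, "run.log")
  logLines <- character(0)
  logMsg <- function(...) {
    logLines <<- c(logLines, paste0(...))
    writeLines(logLines, logPath)
  }
  summary <- list(configHash = hash, seed = config$seed, stages = list())
  stageFiles <- character(0)
  runStage <- function(name, index, fn) {
    stageFiles <<- character(0)
    logMsg("stage ", name, ": seed ", stageSeed(config$seed, index))
    tryCatch(fn(), error = function(e) {
      for (f in stageFiles) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(name) {
    f <- file.path(outDir, name)
    stageFiles <<- c(stageFiles, f)
    f
  }
  tracks <- NULL
  truth <- NULL

  # ---- input / simulate ----
  m <- runStage("input", 1L, function() {
    if (isTRUE(config$simulate$enabled)) {
      truth <<- do.call(syntheticTruth, c(
        config$simulate$truth,
        list(seed = stageSeed(config$seed, 1L))))
      tracks <<- simulateFeatureTracks(truth)
      mm <- simulateContactMap(truth, depth = config$simulate$depth)
      mm@genome <- setGC(mm@genome, tracks$gc)
      summary$stages$input <<- list(source = "simulated",
                                    depth = config$simulate$depth)
      mm
    } else {
      cs <- config$inputs$chromSizes
      if (is.null(cs)) stop("missing input: chromSizes")
      genome <- GenomeSpec(readChromSizes(cs), config$inputs$binSize)
      mm <- if (!is.null(config$inputs$pairs)) {
        binPairs(readPairsFile(config$inputs$pairs), genome)
      } else if (!is.null(config$inputs$coo)) {
        readCOO(config$inputs$coo, genome)
      } else {
        stop("missing input: pairs or coo")
      }
      if (!is.null(config$inputs$gcTrack)) {
        mm@genome <- setGC(genome, readBedGraphTrack(config$inputs$gcTrack,
                                                     genome))
      } else if (!is.null(config$inputs$fasta)) {
        seqs <- Biostrings::readDNAStringSet(config$inputs$fasta)
        names(seqs) <- sub("\\s.*", "", names(seqs))
        mm@genome <- setGC(genome, gcFromSequences(seqs, genome))
      }
      summary$stages$input <<- list(source = "files")
      mm
    }
  })
  writeBinsBED(m@genome, out("bins.bed"))
  writeCOO(m, out("matrix.coo.tsv"))

  # ---- mask + balance ----
  m <- runStage("balance", 2L, function() {
    mm <- maskLowCoverage(m, config$mask$minFrac)
    mm <- iceBalance(mm, tol = config$balance$tol,
                     maxIter = config$balance$maxIter)
    summary$stages$balance <<- c(config$mask, config$balance,
                                 list(nMasked = sum(binMask(mm))))
    mm
  })
  writeBedGraphTrack(balancingWeights(m), m@genome,
                     out("weights.bedGraph"))
  oe <- observedOverExpected(m)

  # ---- decay ----
  decayTab <- runStage("decay", 3L, function() {
    rows <- lapply(chromNames(m), function(ch) {
      fit <- fitIDERegion(m, ch, sMin = config$decay$sMin,
                          sMax = config$decay$sMax,
                          logBinsPerDecade = config$decay$logBinsPerDecade)
      data.frame(region = ch, exponent = fit@exponent,
                 intercept = fit@intercept, r2 = fit@r2,
                 nBands = fit@nBands)
    })
    tab <- do.call(rbind, rows)
    summary$stages$decay <<- c(config$decay,
                               list(meanExponent = mean(tab$exponent)))
    tab
  })
  data.table::fwrite(decayTab, out("decay.tsv"), sep = "\t")

  # ---- compartments ----
  track <- runStage("compartments", 4L, function() {
    if (is.null(gcContent(m))) {
      stop("missing input: per-bin GC track (required for mode '",
           config$compartments$mode, "')")
    }
    tr <- callCompartments(m, mode = config$compartments$mode,
                           signTol = config$compartments$signTol, oe = oe)
    summary$stages$compartments <<- list(
      mode = tr@mode,
      nA = sum(compartmentLabels(tr) == "A"),
      nB = sum(compartmentLabels(tr) == "B"),
      nBorders = nrow(compartmentBorders(tr)))
    tr
  })
  writeBedGraphTrack(e1Values(track), m@genome, out("e1.bedGraph"))
  if (nrow(compartmentBorders(track))) {
    data.table::fwrite(compartmentBorders(track), out("borders.tsv"),
                       sep = "\t")
  }

  # ---- centromeres (needed by the aggregate stage) ----
  cenCalls <- runStage("centromeres", 5L, function() {
    cc <- config$centromeres
    mc <- coarsen(m, cc$coarseBinSize)
    mc <- iceBalance(maskLowCoverage(mc), tol = 1e-4)
    calls <- locateCentromeresHiC(mc)
    summary$stages$centromeres <<- list(coarseBinSize = cc$coarseBinSize,
                                        calls = nrow(calls))
    calls
  })
  data.table::fwrite(cenCalls, out("centromeres_hic.tsv"), sep = "\t")

  # ---- aggregate ----
  scores <- runStage("aggregate", 6L, function() {
    cens <- setNames(cenCalls$pos, cenCalls$chrom)
    ag <- aca(m, cens, nPseudo = config$aggregate$nPseudo, oe = oe)
    sc <- clusterScores(ag$inter, window = config$aggregate$window,
                        tauC = config$aggregate$tauC,
                        tauR = config$aggregate$tauR)
    utils::write.table(ag$intra$map, out("aca_intra.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(ag$inter$map, out("aca_inter.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    pair <- transEnrichmentByPair(m)
    utils::write.table(pair, out("trans_enrichment.tsv"), sep = "\t",
                       quote = FALSE)
    summary$stages$aggregate <<- list(ccScore = sc$ccScore,
                                      ttScore = sc$ttScore,
                                      armAlignmentScore = sc$armAlignmentScore,
                                      configuration = sc$call)
    sc
  })

  # ---- insulation ----
  insTrack <- runStage("insulation", 7L, function() {
    tr <- insulationTrack(m, window = config$insulation$window)
    tr <- detectBoundaries(tr, minStrength = config$insulation$minStrength)
    tad <- assessTadPresence(tr,
                             strengthThreshold = config$insulation$minStrength,
                             densityThreshold = config$insulation$densityThreshold)
    summary$stages$insulation <<- list(
      nBoundaries = nrow(boundaries(tr)),
      densityPerMb = tad$densityPerMb, verdict = tad$verdict)
    tr
  })
  writeBedGraphTrack(insulationScores(insTrack), m@genome,
                     out("insulation.bedGraph"))
  if (nrow(boundaries(insTrack))) {
    data.table::fwrite(boundaries(insTrack), out("boundaries.tsv"),
                       sep = "\t")
  }

  # ---- repeats / telomeres ----
  runStage("features", 8L, function() {
    repeats <- if (!is.null(tracks)) {
      tracks$repeats
    } else if (!is.null(config$inputs$repeats)) {
      readRepeatTable(config$inputs$repeats)
    } else NULL
    if (!is.null(repeats)) {
      wins <- centromereWindows(cenCalls, m@genome,
                                config$centromeres$windowHalfWidth)
      fams <- scanCentromericFamilies(
        repeats, wins,
        minSpecificity = config$centromeres$minSpecificity,
        minChromFraction = config$centromeres$minChromFraction)
      data.table::fwrite(fams, out("centromeric_families.tsv"), sep = "\t")
      if (nrow(fams)) {
        spans <- defineCentromereSpans(repeats, fams$family)
        data.table::fwrite(spans, out("centromere_spans.tsv"), sep = "\t")
        summary$stages$features <<- list(families = fams$family,
                                         spans = nrow(spans))
      }
    }
    seqs <- if (!is.null(tracks)) {
      tracks$sequences
    } else if (!is.null(config$inputs$fasta)) {
      s <- Biostrings::readDNAStringSet(config$inputs$fasta)
      names(s) <- sub("\\s.*", "", names(s))
      s
    } else NULL
    if (!is.null(seqs)) {
      tel <- detectTelomericTracts(seqs, motif = config$telomeres$motif,
                                   minCopies = config$telomeres$minCopies,
                                   maxOffset = config$telomeres$maxOffset)
      data.table::fwrite(tel$perEnd, out("telomeres.tsv"), sep = "\t")
      summary$stages$telomeres <<- tel$summary
    }
    invisible(NULL)
  })

  # ---- integrate ----
  runStage("integrate", 9L, function() {
    genes <- if (!is.null(tracks)) {
      tracks$genes
    } else if (!is.null(config$inputs$genes)) {
      readGeneTable(config$inputs$genes)
    } else NULL
    peaks <- if (!is.null(tracks)) {
      tracks$peaks
    } else if (!is.null(config$inputs$peaks)) {
      readPeakTable(config$inputs$peaks)
    } else NULL
    res <- list()
    if (!is.null(peaks)) {
      me <- markEnrichmentByCompartment(peaks, track)
      res$marks <- lapply(me, function(x) x[c("W", "p", "nA", "nB")])
    }
    if (!is.null(genes)) {
      ex <- expressionByCompartment(genes, track)
      res$expression <- ex[c("W", "p", "nA", "nB")]
      genes <- classifySBG(genes, padjMax = config$integrate$padjMax,
                           lfcMin = config$integrate$lfcMin)
      res$sbgCounts <- as.list(table(genes$sbg_label))
    }
    if (length(res)) {
      jsonlite::write_json(res, out("integrate.json"), auto_unbox = TRUE,
                           digits = NA)
      summary$stages$integrate <<- res["sbgCounts"]
    }
    invisible(NULL)
  })

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logMsg("pipeline complete")
  invisible(summary)
}
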