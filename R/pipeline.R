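#' Configuration of a full delimitation-and-diversity run
#'
#' Either a \code{\link{simParams}} object (synthetic mode) or paths to real
#' inputs (aligned FASTA, rooted newick tree with substitution branch
#' lengths, metadata TSV with a \code{morphospecies} column) must be given.
#'
#' @param sim A \code{SimParams} object, or \code{NULL} for real inputs.
#' @param fasta,tree,metadata Paths to real inputs (ignored in synthetic
#'   mode).
#' @param methods Delimitation methods to run, a subset of
#'   \code{c("networks", "distance", "gmyc", "ptp")}.
#' @param threshold Distance-clustering threshold (default 0.03; presets
#'   0.03 / 0.05 / 0.075).
#' @param confidence Parsimony-network connection confidence (default 0.95).
#' @param maxSteps Optional fixed connection-limit override.
#' @param standardMethods Collection methods retained for richness
#'   estimation.
#' @param richnessLevels Elevational levels retained for richness estimation
#'   (the undersampled top level is excluded by default).
#' @param accumulationPerms Permutations of the random accumulation curve.
#' @param standardizationReps Draws of the sampling standardization.
#' @param seed Master seed governing every stochastic stage.
#' @param outDir Optional directory for the report files.
#' @return A list of class \code{RunConfig}.
#' @export
pipelineConfig <- function(sim = NULL, fasta = NULL, tree = NULL,
                           metadata = NULL,
                           methods = c("networks", "distance", "gmyc", "ptp"),
                           threshold = 0.03, confidence = 0.95,
                           maxSteps = NULL,
                           standardMethods = c("sweep", "beating", "hand"),
                           richnessLevels = c(1000L, 2000L),
                           accumulationPerms = 1000L,
                           standardizationReps = 10000L,
                           seed = 1L, outDir = NULL) {
  real <- !is.null(fasta) || !is.null(tree) || !is.null(metadata)
  if (is.null(sim) && !real)
    stop("config needs either simulation parameters or real input paths")
  if (!is.null(sim) && real)
    stop("give either simulation parameters or real input paths, not both")
  methods <- match.arg(methods, c("networks", "distance", "gmyc", "ptp"),
                       several.ok = TRUE)
  structure(list(sim = sim, fasta = fasta, tree = tree, metadata = metadata,
                 methods = methods, threshold = threshold,
                 confidence = confidence, maxSteps = maxSteps,
                 standardMethods = standardMethods,
                 richnessLevels = richnessLevels,
                 accumulationPerms = as.integer(accumulationPerms),
                 standardizationReps = as.integer(standardizationReps),
                 seed = as.integer(seed), outDir = outDir),
            class = "RunConfig")
}

#' Run the full delimitation and diversity pipeline
#'
#' Executes the stages in dependency order: (synthetic mode) community,
#' genealogy, sequences and perturbed morphospecies labels; haplotype
#' collapsing and pairwise distances; the requested delimitation methods
#' (statistical-parsimony networks, distance threshold clustering,
#' single-threshold GMYC on the ultrametric tree, PTP on the substitution
#' tree); congruence of every MOTU set against the morphospecies reference
#' plus the full pairwise perfect-match matrix; and per-method richness
#' estimation, accumulation, standardization and elevational occupancy.  A
#' single master seed drives all stochastic stages, so a rerun with the same
#' configuration reproduces the report exactly.  A method that fails is
#' recorded in \code{report$failures} and the run continues.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return A list of class \code{RunReport}; see Details.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- Sys.time()
  log <- character(0)
  note <- function(...) {
    log <<- c(log, paste0(...))
    invisible(NULL)
  }

  if (!is.null(config$sim)) {
    params <- config$sim
    params$seed <- config$seed
    truth <- simulateCommunity(params)
    genealogy <- simulateGenealogy(truth, params)
    aln <- simulateSequences(genealogy, params)
    morpho <- corruptMorphospecies(truth, params$splitRate, params$lumpRate,
                                   params$seed,
                                   attr(genealogy, "speciesTipOrder"))
    meta <- specimenTable(truth, morpho)
    timeTree <- genealogy
    subsTree <- substitutionTree(genealogy, params)
    note("simulated ", sum(truth@abundances), " specimens / ",
         truth@speciesCount, " species")
  } else {
    truth <- NULL
    aln <- readAlignment(config$fasta)
    meta <- readMetadata(config$metadata)
    morpho <- Partition(stats::setNames(meta$morphospecies, meta$specimen_id))
    subsTree <- if (is.null(config$tree)) NULL else readTimeTree(config$tree)
    timeTree <- if (is.null(subsTree)) NULL else ultrametricizeMPL(subsTree)
    note("loaded ", length(aln), " specimens")
  }
  if (any(c("gmyc", "ptp") %in% config$methods) && is.null(subsTree))
    stop("tree-based methods requested but no tree available")

  hs <- haplotypeSteps(aln)
  d <- pDistanceMatrix(aln)
  note(length(aln), " specimens -> ", hs$haplotypes$nHaplotypes, " haplotypes")

  partitions <- list(morphospecies = morpho)
  fits <- list()
  failures <- list()
  runStage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[name]] <<- conditionMessage(res)
      note(name, " FAILED: ", conditionMessage(res))
      NULL
    } else res
  }

  if ("networks" %in% config$methods) {
    lim <- connectionLimit(unique(Biostrings::width(aln))[1L],
                           config$confidence, config$maxSteps)
    p <- runStage("networks",
                  parsimonyNetworks(hs$haplotypes, hs$steps, lim))
    if (!is.null(p)) {
      partitions$networks <- p
      fits$connectionLimit <- lim
      note("networks: ", nGroups(p), " (limit ", lim@maxSteps, " steps)")
    }
  }
  if ("distance" %in% config$methods) {
    p <- runStage("distance", clusterByThreshold(d, config$threshold))
    if (!is.null(p)) {
      partitions$distance <- p
      note("distance clusters at ", config$threshold, ": ", nGroups(p))
    }
  }
  if ("gmyc" %in% config$methods) {
    fit <- runStage("gmyc", {
      tr <- if (isUltrametricTree(timeTree)) timeTree else
        ultrametricizeMPL(timeTree)
      fitGmyc(tr)
    })
    if (!is.null(fit)) {
      partitions$gmyc <- gmycPartition(fit)
      fits$gmyc <- fit
      note("GMYC entities: ", fit@nEntities)
    }
  }
  if ("ptp" %in% config$methods) {
    fit <- runStage("ptp",
                    fitPtp(subsTree, nSites = unique(Biostrings::width(aln))[1L],
                           seed = config$seed))
    if (!is.null(fit)) {
      partitions$ptp <- ptpPartition(fit)
      fits$ptp <- fit
      note("PTP entities: ", fit@nEntities)
    }
  }
  partitions$haplotypes <- haplotypePartition(hs$haplotypes)

  congruence <- lapply(partitions[setdiff(names(partitions), "morphospecies")],
                       function(p) comparePartitions(morpho, p))
  matchMatrix <- pairwiseMatchMatrix(partitions)
  summaries <- lapply(partitions, motuSummary)

  richness <- list()
  occupancy <- list()
  accumulation <- list()
  standardization <- list()
  for (nm in names(partitions)) {
    p <- partitions[[nm]]
    inc <- tryCatch(suppressMessages(
      buildIncidence(p, meta, methods = config$standardMethods,
                     levels = config$richnessLevels)),
      error = function(e) NULL)
    if (is.null(inc)) next
    richness[[nm]] <- rbind(chao2(inc),
                            jackknifeRichness(inc, 1L),
                            jackknifeRichness(inc, 2L))
    accumulation[[nm]] <- accumulationCurve(
      inc, method = "random", nPerm = config$accumulationPerms,
      seed = config$seed)
    occupancy[[nm]] <- list(
      all = levelOccupancy(p, meta),
      noRare = tryCatch(levelOccupancy(p, meta, excludeRare = TRUE),
                        error = function(e) NULL))
    # standardize the larger pool down to the smaller one
    keep <- meta$method %in% config$standardMethods &
      meta$level %in% config$richnessLevels
    poolSizes <- table(meta$level[keep])
    if (length(poolSizes) >= 2L) {
      nDraw <- min(poolSizes)
      big <- as.integer(names(poolSizes)[which.max(poolSizes)])
      standardization[[nm]] <- c(
        standardizedRichness(p, meta, big, nDraw,
                             reps = config$standardizationReps,
                             seed = config$seed,
                             methods = config$standardMethods),
        list(level = big))
    }
  }

  report <- structure(list(
    partitions = partitions,
    fits = fits,
    congruence = congruence,
    matchMatrix = matchMatrix,
    summaries = summaries,
    richness = richness,
    accumulation = accumulation,
    standardization = standardization,
    occupancy = occupancy,
    failures = failures,
    log = log,
    meta = meta,
    truth = truth,
    provenance = list(
      seed = config$seed,
      package = as.character(utils::packageVersion("barcodeMOTU")),
      configHash = .contentHash(config[setdiff(names(config), "outDir")]),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))
  ), class = "RunReport")

  if (!is.null(config$outDir)) writeRunReport(report, config$outDir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed ", x$provenance$seed, ", config ",
      x$provenance$configHash, ")\n", sep = "")
  for (nm in names(x$partitions))
    cat(sprintf("  %-14s %d groups\n", nm, nGroups(x$partitions[[nm]])))
  if (length(x$failures))
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits partition TSVs, congruence JSON/TSV, the perfect-match matrix,
#' richness and occupancy tables, accumulation curves and a provenance
#' block.
#'
#' @param report A \code{RunReport} from \code{\link{runPipeline}}.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$partitions))
    writePartition(report$partitions[[nm]], nm,
                   file.path(dir, paste0("partition_", nm, ".tsv")))
  for (nm in names(report$congruence))
    writeCongruenceReport(report$congruence[[nm]],
                          file.path(dir, paste0("congruence_", nm, ".json")),
                          file.path(dir, paste0("congruence_", nm, ".tsv")))
  utils::write.table(report$matchMatrix, file.path(dir, "match_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  for (nm in names(report$richness))
    utils::write.table(report$richness[[nm]],
                       file.path(dir, paste0("richness_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$accumulation))
    utils::write.table(report$accumulation[[nm]],
                       file.path(dir, paste0("accumulation_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$occupancy)) {
    utils::write.table(report$occupancy[[nm]]$all,
                       file.path(dir, paste0("occupancy_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}
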