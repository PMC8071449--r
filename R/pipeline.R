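#' Pipeline configuration
#'
#' Collects every input and setting for [runPipeline()]. Inputs may be
#' file paths (read with the package readers) or in-memory objects
#' (matrices / SummarizedExperiments, a `signaturePair`, a gene-set list).
#' The lineage stage runs only when a single-cell reference is supplied.
#'
#' @param counts bulk counts (path or matrix/SummarizedExperiment).
#' @param conditions sample-condition map (path or named vector; optional
#'   when `counts` is a SummarizedExperiment with a `condition` column).
#' @param refGroup reference (parental) group label.
#' @param signatures a `signaturePair`, or `list(adrn = path, mes = path)`.
#' @param geneSets GMT path or named list of gene sets (optional).
#' @param reference single-cell reference counts (path or object; optional).
#' @param cellAnnotations cell annotation table (path or data.frame;
#'   optional when `reference` carries colData).
#' @param orthologs ortholog map (path or data.frame; NULL = case-identity
#'   fallback).
#' @param exclusivityPairs list of 2-vectors of gene symbols to test.
#' @param intersectClones clone labels whose DE calls are intersected
#'   (default: every non-reference clone). Use this to restrict the
#'   common-DE intersection to the knockout clones when an overexpressing
#'   clone with the opposite response is present.
#' @param deConfig see [deConfig()].
#' @param gseaTransform,nPerm,minSize,maxSize GSEA settings.
#' @param useLog,linkage lineage settings.
#' @param seed global seed; all stage sub-streams derive from it.
#' @param outDir output directory (created; must not contain a previous
#'   manifest).
#' @return a list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(counts, conditions = NULL, refGroup,
                           signatures = demoSignaturePair(), geneSets = NULL,
                           reference = NULL, cellAnnotations = NULL,
                           orthologs = NULL,
                           exclusivityPairs = list(c("RETL", "AXLL"),
                                                   c("RETL", "YAP1L")),
                           intersectClones = NULL,
                           deConfig = cellstate::deConfig(),
                           gseaTransform = "absolute", nPerm = 1000L,
                           minSize = 5L, maxSize = 500L, useLog = TRUE,
                           linkage = "complete", seed = 1L, outDir) {
  cfg <- list(counts = counts, conditions = conditions, refGroup = refGroup,
              signatures = signatures, geneSets = geneSets,
              reference = reference, cellAnnotations = cellAnnotations,
              orthologs = orthologs, exclusivityPairs = exclusivityPairs,
              intersectClones = intersectClones,
              deConfig = deConfig, gseaTransform = gseaTransform,
              nPerm = as.integer(nPerm), minSize = as.integer(minSize),
              maxSize = as.integer(maxSize), useLog = useLog,
              linkage = linkage, seed = as.integer(seed), outDir = outDir)
  for (p in Filter(.isPath, cfg[c("counts", "conditions", "geneSets",
                                  "reference", "cellAnnotations",
                                  "orthologs")])) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  class(cfg) <- "pipelineConfig"
  cfg
}

.isPath <- function(x) is.character(x) && length(x) == 1L && is.null(names(x))

.loadInput <- function(x, reader) if (.isPath(x)) reader(x) else x

#' Run the full cell-state analysis pipeline
#'
#' Executes, in order: normalization, differential expression of every
#' clone against the reference group, intersection of the DE calls across
#' clones, pre-ranked GSEA per clone, ADRN/MES signature scoring, and (when
#' a single-cell reference is configured) ortholog mapping, the cell-clone
#' correlation map with per-type means, mutual-exclusivity tests and
#' hierarchical clustering of both axes of the correlation map. Every
#' result is written as TSV (dendrograms as Newick) under `outDir`
#' together with a JSON run manifest recording the settings, seed, input
#' checksums, package version, per-stage row counts and warnings. A stage
#' failure aborts with the stage name and removes this run's partial
#' outputs. Outputs are write-once: an existing manifest in `outDir` is an
#' error. Reruns with the same config and seed are identical.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  out <- config$outDir
  if (file.exists(file.path(out, "manifest.json")))
    stop("output directory already holds a run manifest; refusing to overwrite")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  warningsLog <- character()
  counts <- stages <- list()

  emit <- function(df, name) {
    p <- file.path(out, name)
    write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warningsLog <<- c(warningsLog, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  res <- list()

  stage("load", {
    m <- .loadInput(config$counts, readCountMatrix)
    condition <- .conditionOf(m, .loadInput(config$conditions,
                                            readConditionTable))
    res$counts <- .asCountsMatrix(m)
    res$condition <- condition
    stages$load <- list(nGenes = nrow(res$counts),
                         nSamples = ncol(res$counts))
  })

  stage("normalize", {
    res$sizeFactors <- estimateSizeFactorsMOR(res$counts)
    res$normalized <- normalizeCounts(res$counts, res$sizeFactors)
    sf <- data.frame(sample = names(res$sizeFactors),
                     sizeFactor = unname(res$sizeFactors))
    emit(sf, "size_factors.tsv")
    stages$normalize <- list(nSamples = length(res$sizeFactors))
  })

  clones <- setdiff(unique(res$condition), config$refGroup)
  stage("de", {
    res$de <- lapply(setNames(clones, clones), function(cl) {
      runDE(res$counts, res$condition, ref = config$refGroup, alt = cl,
            config = config$deConfig)
    })
    for (cl in clones) {
      emit(as.data.frame(res$de[[cl]]), sprintf("de_%s_vs_%s.tsv", cl,
                                                config$refGroup))
    }
    stages$de <- list(nComparisons = length(clones),
                       nTested = vapply(res$de, nrow, integer(1)))
  })

  stage("intersect", {
    use <- if (is.null(config$intersectClones)) clones else
      intersect(clones, config$intersectClones)
    calls <- lapply(res$de[use], callDEGenes, config = config$deConfig)
    res$common <- intersectDEAcrossClones(calls)
    emit(res$common$regions, "de_intersection_regions.tsv")
    emit(data.frame(direction = rep(c("up", "down"),
                                    c(length(res$common$up),
                                      length(res$common$down))),
                    gene = c(res$common$up, res$common$down)),
         "de_common_genes.tsv")
    stages$intersect <- list(nUp = length(res$common$up),
                              nDown = length(res$common$down))
  })

  stage("gsea", {
    sets <- .loadInput(config$geneSets, readGMT)
    if (is.null(sets)) {
      pair <- config$signatures
      if (is.list(pair) && !inherits(pair, "signaturePair")) {
        pair <- signaturePair(readSignature(pair$adrn),
                              readSignature(pair$mes))
      }
      sets <- list(MES_SIGNATURE = pair$mes, ADRN_SIGNATURE = pair$adrn)
    }
    res$gsea <- lapply(setNames(clones, clones), function(cl) {
      ranked <- makeRankedList(res$de[[cl]], transform = config$gseaTransform)
      gseaPreranked(ranked, sets, nPerm = config$nPerm,
                    seed = subSeed(config$seed, paste0("gsea-", cl)),
                    minSize = config$minSize, maxSize = config$maxSize)
    })
    for (cl in clones) emit(as.data.frame(res$gsea[[cl]]),
                            sprintf("gsea_%s.tsv", cl))
    stages$gsea <- list(nSets = length(sets))
  })

  stage("signatures", {
    pair <- config$signatures
    if (is.list(pair) && !inherits(pair, "signaturePair")) {
      pair <- signaturePair(readSignature(pair$adrn), readSignature(pair$mes))
    }
    res$scores <- scoreClones(res$normalized, pair, res$condition)
    emit(as.data.frame(res$scores), "signature_scores.tsv")
    emit(S4Vectors::metadata(res$scores)$groupMedians,
         "signature_score_medians.tsv")
    stages$signatures <- list(nSamples = nrow(res$scores))
  })

  if (is.null(config$reference)) {
    stages$lineage <- "skipped"
  } else {
    stage("lineage", {
      ref <- .loadInput(config$reference, readCountMatrix)
      ann <- .loadInput(config$cellAnnotations, read.delim)
      if (is.null(ann) && methods::is(ref, "SummarizedExperiment")) {
        ann <- as.data.frame(SummarizedExperiment::colData(ref))
      }
      refM <- .asCountsMatrix(ref)
      omap <- .loadInput(config$orthologs, readOrthologMap)
      mapped <- mapOrthologs(refM, omap)
      res$cmap <- correlateClonesToCells(
        res$counts, mapped$matrix, res$condition, ann,
        useLog = config$useLog, fallbackPositiveGeomean = TRUE)
      r <- corMatrix(res$cmap)
      emit(data.frame(cell = rownames(r), as.data.frame(r),
                      check.names = FALSE), "correlation_map.tsv")
      res$typeMeans <- meanCorrelationByType(res$cmap)
      emit(res$typeMeans, "correlation_by_type.tsv")

      bin <- binarizeExpression(mapped$matrix)
      exc <- lapply(config$exclusivityPairs, function(pr) {
        e <- exclusivityTest(bin, pr[1], pr[2])
        data.frame(geneA = e$geneA, geneB = e$geneB,
                   a = e$table[1, 1], b = e$table[1, 2],
                   c = e$table[2, 1], d = e$table[2, 2],
                   odds_ratio = e$oddsRatio, pvalue = e$pvalue,
                   direction = e$direction, flag = e$flag)
      })
      res$exclusivity <- do.call(rbind, exc)
      emit(res$exclusivity, "exclusivity.tsv")

      nTypes <- length(unique(ann$cell_type))
      res$cellClustering <- hierarchicalCluster(r, axis = "rows",
                                                 linkage = config$linkage,
                                                 k = nTypes)
      res$cloneClustering <- hierarchicalCluster(r, axis = "cols",
                                                  linkage = config$linkage,
                                                  k = 2)
      writeDendrogramNewick(res$cellClustering,
                            file.path(out, "cells_dendrogram.nwk"))
      writeDendrogramNewick(res$cloneClustering,
                            file.path(out, "clones_dendrogram.nwk"))
      written <- c(written, file.path(out, c("cells_dendrogram.nwk",
                                              "clones_dendrogram.nwk")))
      stages$lineage <- list(nCells = nrow(r), nClones = ncol(r),
                              nSharedGenes = res$cmap@nGenesUsed)
    })
  }

  fileInputs <- Filter(.isPath, config[c("counts", "conditions",
                                         "geneSets", "reference",
                                         "cellAnnotations", "orthologs")])
  manifest <- list(
    package = "cellstate",
    version = as.character(packageVersion("cellstate")),
    seed = config$seed,
    refGroup = config$refGroup,
    settings = list(de = config$deConfig, gseaTransform = config$gseaTransform,
                    nPerm = config$nPerm, useLog = config$useLog,
                    linkage = config$linkage),
    inputChecksums = if (length(fileInputs)) {
      as.list(tools::md5sum(unlist(fileInputs)))
    } else {
      list()
    },
    stages = stages,
    warnings = warningsLog)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
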