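#' Planted expression program for the bulk simulator
#'
#' A named group of genes that receive a common planted log2 fold change in
#' selected groups of a simulated knockout-clone experiment, relative to the
#' reference group (implicit log2 fold change 0). A value of `-Inf` marks a
#' knockout: the gene's expected count is exactly 0 in that group.
#'
#' @slot name program label, e.g. `"MES-up"` or `"KO-gene"`.
#' @slot genes character vector of member gene symbols (unique).
#' @slot log2fcByGroup named numeric; planted log2 fold change per group
#'   label (`-Inf` = knockout).
#' @export
setClass("PlantedProgram",
  representation(name = "character", genes = "character",
                 log2fcByGroup = "numeric"))

setValidity("PlantedProgram", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(object@genes) == 0L) msg <- c(msg, "genes must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene ids within a program must be disjoint")
  if (is.null(names(object@log2fcByGroup)) ||
      any(!nzchar(names(object@log2fcByGroup))))
    msg <- c(msg, "log2fcByGroup must be named by group label")
  if (any(is.nan(object@log2fcByGroup)))
    msg <- c(msg, "log2fcByGroup must not contain NaN")
  if (length(msg)) msg else TRUE
})

#' @param name,genes,log2fcByGroup see slots.
#' @param knockoutGroups group labels in which the genes are knocked out
#'   (expected count 0); encoded as `-Inf` in `log2fcByGroup`.
#' @return A [PlantedProgram-class] object.
#' @rdname PlantedProgram-class
#' @export
plantedProgram <- function(name, genes, log2fcByGroup = numeric(),
                           knockoutGroups = character()) {
  if (length(knockoutGroups)) {
    ko <- setNames(rep(-Inf, length(knockoutGroups)), knockoutGroups)
    overlap <- intersect(names(log2fcByGroup), knockoutGroups)
    if (length(overlap))
      stop("groups both planted and knocked out: ",
           paste(overlap, collapse = ", "))
    log2fcByGroup <- c(log2fcByGroup, ko)
  }
  new("PlantedProgram", name = name, genes = unique(as.character(genes)),
      log2fcByGroup = log2fcByGroup)
}

#' Scenario for the bulk knockout-clone count simulator
#'
#' Describes a bulk RNA-seq study design: groups (clones) with replicate
#' counts, a reference group, per-gene baseline log2 means drawn uniformly
#' over a range, a shared negative-binomial dispersion (var = mu + alpha
#' mu^2), planted expression programs, and library size factors.
#'
#' @slot nGenes number of genes (>= 100).
#' @slot groups data.frame with columns `label` and `n` (replicates).
#' @slot refGroup label of the reference (parental) group.
#' @slot baselineLog2Range range for uniform baseline log2 mean draws.
#' @slot dispersion shared NB dispersion alpha (> 0).
#' @slot programs list of [PlantedProgram-class].
#' @slot libSizeFactors per-sample positive library size factors.
#' @slot geneIds gene symbols; program genes are placed first.
#' @slot seed integer seed; all randomness derives from it.
#' @export
setClass("BulkScenario",
  representation(nGenes = "integer", groups = "data.frame",
                 refGroup = "character", baselineLog2Range = "numeric",
                 dispersion = "numeric", programs = "list",
                 libSizeFactors = "numeric", geneIds = "character",
                 seed = "integer"))

setValidity("BulkScenario", function(object) {
  msg <- character()
  if (object@nGenes < 100L) msg <- c(msg, "nGenes must be >= 100")
  if (!all(c("label", "n") %in% colnames(object@groups)))
    msg <- c(msg, "groups needs 'label' and 'n' columns")
  else {
    if (anyDuplicated(object@groups$label))
      msg <- c(msg, "group labels must be unique")
    if (!(object@refGroup %in% object@groups$label))
      msg <- c(msg, "refGroup must be one of the group labels")
    if (sum(object@groups$n) != length(object@libSizeFactors))
      msg <- c(msg, "libSizeFactors length must equal total sample count")
  }
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (any(object@libSizeFactors <= 0))
    msg <- c(msg, "library size factors must be > 0")
  if (length(object@geneIds) != object@nGenes)
    msg <- c(msg, "geneIds length must equal nGenes")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "geneIds must be unique")
  for (p in object@programs) {
    if (!methods::is(p, "PlantedProgram"))
      msg <- c(msg, "programs must be PlantedProgram objects")
    else {
      if (!all(p@genes %in% object@geneIds))
        msg <- c(msg, sprintf("program '%s' names genes outside the universe",
                              p@name))
      bad <- setdiff(names(p@log2fcByGroup),
                     setdiff(object@groups$label, object@refGroup))
      if (length(bad))
        msg <- c(msg, sprintf("program '%s' targets unknown/reference group: %s",
                              p@name, paste(bad, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param nGenes,groups,refGroup,baselineLog2Range,dispersion,programs,libSizeFactors,seed
#'   see slots. `groups` may be a named integer vector (label -> replicates).
#' @param geneIds optional explicit gene universe; by default program genes
#'   followed by filler symbols `G00001`, `G00002`, ...
#' @return A [BulkScenario-class] object.
#' @rdname BulkScenario-class
#' @export
bulkScenario <- function(nGenes = 2000L, groups, refGroup,
                         baselineLog2Range = c(3, 10), dispersion = 0.05,
                         programs = list(), libSizeFactors = NULL,
                         geneIds = NULL, seed = 1L) {
  if (!is.data.frame(groups)) {
    groups <- data.frame(label = names(groups), n = as.integer(groups),
                         stringsAsFactors = FALSE)
  }
  if (is.null(libSizeFactors)) libSizeFactors <- rep(1, sum(groups$n))
  if (is.null(geneIds)) {
    progGenes <- unique(unlist(lapply(programs, function(p) p@genes)))
    if (length(progGenes) > nGenes)
      stop("more program genes than nGenes")
    filler <- sprintf("G%05d", seq_len(nGenes))
    filler <- setdiff(filler, progGenes)
    geneIds <- c(progGenes, filler)[seq_len(nGenes)]
  }
  new("BulkScenario", nGenes = as.integer(nGenes), groups = groups,
      refGroup = refGroup, baselineLog2Range = as.numeric(baselineLog2Range),
      dispersion = as.numeric(dispersion), programs = programs,
      libSizeFactors = as.numeric(libSizeFactors),
      geneIds = as.character(geneIds), seed = as.integer(seed))
}

.scTypes <- c("SCP", "bridge", "chromaffin", "sympathoblast")

#' Scenario for the labeled single-cell reference simulator
#'
#' Emulates a four-population sympathoadrenal developmental reference
#' (Schwann cell precursors, bridge cells, chromaffin cells and
#' sympathoblasts): per-population marker programs with elevated means on a
#' shared negative-binomial baseline, plus designated "exclusivity" genes
#' that are switched on/off per cell by population-specific Bernoulli
#' probabilities before positive counts are drawn (zero-inflated NB for
#' those genes only), and optional extra dropout.
#'
#' @slot nGenes number of genes.
#' @slot populations data.frame with columns `label` (one of SCP, bridge,
#'   chromaffin, sympathoblast), `nCells` (>= 20) and `devOrder`.
#' @slot markerPrograms named list; each element is
#'   `list(genes = <character>, elevationByType = <named numeric>)` giving
#'   log2 mean elevations per population.
#' @slot exclusivityPairs list of `list(geneA, geneB, pOnA, pOnB)` where
#'   `pOnA`/`pOnB` are named per-type Bernoulli "on" probabilities.
#' @slot onLog2Mean log2 NB mean used for exclusivity genes when "on".
#' @slot dropout named per-type extra zero-inflation probability.
#' @slot baselineLog2Range,dispersion,geneIds,seed as in
#'   [BulkScenario-class].
#' @export
setClass("ScRefScenario",
  representation(nGenes = "integer", populations = "data.frame",
                 markerPrograms = "list", exclusivityPairs = "list",
                 onLog2Mean = "numeric", dropout = "numeric",
                 baselineLog2Range = "numeric", dispersion = "numeric",
                 geneIds = "character", seed = "integer"))

setValidity("ScRefScenario", function(object) {
  msg <- character()
  pop <- object@populations
  if (!all(c("label", "nCells", "devOrder") %in% colnames(pop)))
    return("populations needs 'label', 'nCells', 'devOrder' columns")
  if (!all(pop$label %in% .scTypes))
    msg <- c(msg, paste("unknown cell-type label:",
                        paste(setdiff(pop$label, .scTypes), collapse = ", ")))
  if (any(pop$nCells < 20L)) msg <- c(msg, "each population needs >= 20 cells")
  ord <- setNames(pop$devOrder, pop$label)
  chain <- c("SCP", "bridge", "chromaffin")
  present <- chain[chain %in% names(ord)]
  if (length(present) > 1 && any(diff(ord[present]) <= 0))
    msg <- c(msg, "devOrder must strictly increase SCP < bridge < chromaffin")
  for (pr in object@exclusivityPairs) {
    p <- c(pr$pOnA, pr$pOnB)
    if (any(p < 0 | p > 1)) msg <- c(msg, "on/off probabilities must be in [0,1]")
    if (!all(names(pr$pOnA) %in% .scTypes) || !all(names(pr$pOnB) %in% .scTypes))
      msg <- c(msg, "exclusivity probabilities named by unknown cell type")
  }
  if (any(object@dropout < 0 | object@dropout >= 1))
    msg <- c(msg, "dropout must be in [0,1)")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (length(object@geneIds) != object@nGenes)
    msg <- c(msg, "geneIds length must equal nGenes")
  if (length(msg)) msg else TRUE
})

#' @param nGenes,populations,markerPrograms,exclusivityPairs,onLog2Mean,dropout,baselineLog2Range,dispersion,geneIds,seed
#'   see slots.
#' @return A [ScRefScenario-class] object.
#' @rdname ScRefScenario-class
#' @export
scRefScenario <- function(nGenes = 2000L, populations, markerPrograms = list(),
                          exclusivityPairs = list(), onLog2Mean = 6,
                          dropout = setNames(rep(0, 4), .scTypes),
                          baselineLog2Range = c(3, 10), dispersion = 0.05,
                          geneIds = NULL, seed = 1L) {
  if (is.null(geneIds)) {
    special <- unique(c(
      unlist(lapply(markerPrograms, `[[`, "genes")),
      unlist(lapply(exclusivityPairs, function(p) c(p$geneA, p$geneB)))))
    filler <- setdiff(sprintf("G%05d", seq_len(nGenes)), special)
    geneIds <- c(special, filler)[seq_len(nGenes)]
  }
  new("ScRefScenario", nGenes = as.integer(nGenes), populations = populations,
      markerPrograms = markerPrograms, exclusivityPairs = exclusivityPairs,
      onLog2Mean = as.numeric(onLog2Mean), dropout = dropout,
      baselineLog2Range = as.numeric(baselineLog2Range),
      dispersion = as.numeric(dispersion), geneIds = as.character(geneIds),
      seed = as.integer(seed))
}

#' Cell-by-clone Pearson correlation map
#'
#' Pearson correlation coefficients between each single cell of a labeled
#' developmental reference and each bulk clone profile, with the cell
#' annotations needed for per-type summaries and clustering.
#'
#' @slot r numeric matrix, cells in rows, clones in columns, entries in
#'   \[-1, 1\] (NA where a pair was undefined).
#' @slot cellAnnotations data.frame with `cell_id`, `cell_type`, `dev_order`
#'   aligned to the rows of `r`.
#' @slot nGenesUsed number of shared genes the correlations are computed on.
#' @slot droppedPairs data.frame of (cell, clone) pairs with undefined r.
#' @export
setClass("CorrelationMap",
  representation(r = "matrix", cellAnnotations = "data.frame",
                 nGenesUsed = "integer", droppedPairs = "data.frame"))

setValidity("CorrelationMap", function(object) {
  msg <- character()
  if (nrow(object@r) != nrow(object@cellAnnotations))
    msg <- c(msg, "every cell must be annotated")
  else if (!identical(rownames(object@r),
                      as.character(object@cellAnnotations$cell_id)))
    msg <- c(msg, "cellAnnotations$cell_id must match rownames(r)")
  rr <- object@r[is.finite(object@r)]
  if (length(rr) && (max(rr) > 1 + 1e-12 || min(rr) < -1 - 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (!all(c("cell_id", "cell_type", "dev_order") %in%
           colnames(object@cellAnnotations)))
    msg <- c(msg, "cellAnnotations needs cell_id, cell_type, dev_order")
  if (length(msg)) msg else TRUE
})

#' @param object a `CorrelationMap`.
#' @rdname CorrelationMap-class
#' @export
setMethod("show", "CorrelationMap", function(object) {
  cat("CorrelationMap:", nrow(object@r), "cells x", ncol(object@r),
      "clones over", object@nGenesUsed, "shared genes\n")
  cat("cell types:",
      paste(sprintf("%s (%d)", names(table(object@cellAnnotations$cell_type)),
                    table(object@cellAnnotations$cell_type)), collapse = ", "),
      "\n")
  if (nrow(object@droppedPairs))
    cat(nrow(object@droppedPairs), "pairs with undefined correlation\n")
})

#' @rdname CorrelationMap-class
#' @param x a `CorrelationMap`.
#' @return `corMatrix` returns the cells-by-clones correlation matrix;
#'   `cellAnnotations` the annotation data.frame.
#' @export
corMatrix <- function(x) {
  stopifnot(methods::is(x, "CorrelationMap"))
  x@r
}

#' @rdname CorrelationMap-class
#' @export
cellAnnotations <- function(x) {
  stopifnot(methods::is(x, "CorrelationMap"))
  x@cellAnnotations
}

setMethod("show", "BulkScenario", function(object) {
  cat("BulkScenario:", object@nGenes, "genes;",
      nrow(object@groups), "groups (ref:", object@refGroup, ");",
      sum(object@groups$n), "samples;",
      length(object@programs), "planted programs; seed", object@seed, "\n")
})

setMethod("show", "ScRefScenario", function(object) {
  cat("ScRefScenario:", object@nGenes, "genes;",
      paste(sprintf("%s=%d", object@populations$label,
                    object@populations$nCells), collapse = ", "),
      "; seed", object@seed, "\n")
})
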