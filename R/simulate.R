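#' Simulate a bulk knockout-clone count matrix
#'
#' Draws gene-by-sample counts from a negative binomial with mean
#' `s_j * 2^(b_g + delta_{g, group(j)})` and variance `mu + alpha * mu^2`,
#' where `b_g` is a uniform baseline log2 mean, `delta` collects the planted
#' program fold changes (`-Inf` forces a zero mean, i.e. a knockout) and
#' `s_j` are the library size factors. Deterministic given the scenario
#' seed; the RNG sub-stream is derived from it so bulk and single-cell
#' matrices can be regenerated independently.
#'
#' @param scenario a [BulkScenario-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"`, `colData` columns `sample` and `condition`, `rowData`
#'   column `baselineLog2`, and `metadata(se)$truth`, an exhaustive
#'   data.frame of every planted non-zero log2 fold change
#'   (gene, group, log2fc; knockouts as `-Inf`).
#' @export
simulateBulkCounts <- function(scenario) {
  stopifnot(methods::is(scenario, "BulkScenario"))
  validObject(scenario)
  set.seed(subSeed(scenario@seed, "bulk"))

  genes <- scenario@geneIds
  grp <- scenario@groups
  groupOfSample <- rep(grp$label, grp$n)
  sampleIds <- unlist(lapply(seq_len(nrow(grp)), function(i) {
    sprintf("%s_R%d", grp$label[i], seq_len(grp$n[i]))
  }))
  nG <- scenario@nGenes
  nS <- length(sampleIds)

  b <- runif(nG, scenario@baselineLog2Range[1], scenario@baselineLog2Range[2])

  delta <- matrix(0, nG, nrow(grp), dimnames = list(genes, grp$label))
  assigned <- matrix(FALSE, nG, nrow(grp))
  for (p in scenario@programs) {
    gi <- match(p@genes, genes)
    for (g in names(p@log2fcByGroup)) {
      ci <- match(g, grp$label)
      clash <- assigned[gi, ci] & delta[gi, ci] != p@log2fcByGroup[[g]]
      if (any(clash)) {
        stop(sprintf(
          "overlapping programs assign conflicting log2 fold changes to gene '%s' in group '%s'",
          p@genes[which(clash)[1]], g))
      }
      delta[gi, ci] <- p@log2fcByGroup[[g]]
      assigned[gi, ci] <- TRUE
    }
  }

  sf <- scenario@libSizeFactors
  counts <- matrix(0L, nG, nS, dimnames = list(genes, sampleIds))
  size <- 1 / scenario@dispersion
  for (j in seq_len(nS)) {
    mu <- sf[j] * 2^(b + delta[, match(groupOfSample[j], grp$label)])
    counts[, j] <- rnbinom(nG, mu = mu, size = size)
  }

  nz <- which(delta != 0, arr.ind = TRUE)
  truth <- data.frame(gene = genes[nz[, 1]], group = grp$label[nz[, 2]],
                      log2fc = delta[nz], stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene, truth$group), , drop = FALSE]
  rownames(truth) <- NULL

  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sample = sampleIds,
                                   condition = groupOfSample,
                                   row.names = sampleIds),
    rowData = S4Vectors::DataFrame(baselineLog2 = b, row.names = genes),
    metadata = list(truth = truth, scenario = scenario))
}

#' Simulate a labeled single-cell developmental reference
#'
#' Per cell, counts are negative binomial on a shared baseline with
#' population-specific log2 elevations for marker-program genes.
#' Exclusivity genes are first switched on/off by the per-type Bernoulli
#' probabilities; "on" cells then receive a positive (zero-truncated) NB
#' count at the configured "on" mean, "off" cells receive 0. Optional extra
#' dropout zeroes non-exclusivity genes per cell type. Deterministic given
#' the scenario seed.
#'
#' @param scenario a [ScRefScenario-class].
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `"counts"` and `colData` columns `cell_id`, `cell_type`, `dev_order`.
#' @export
simulateScReference <- function(scenario) {
  stopifnot(methods::is(scenario, "ScRefScenario"))
  validObject(scenario)
  set.seed(subSeed(scenario@seed, "sc"))

  genes <- scenario@geneIds
  pop <- scenario@populations
  nG <- scenario@nGenes
  size <- 1 / scenario@dispersion

  b <- runif(nG, scenario@baselineLog2Range[1], scenario@baselineLog2Range[2])

  exGenes <- unique(unlist(lapply(scenario@exclusivityPairs,
                                  function(p) c(p$geneA, p$geneB))))
  pOn <- list()  # gene -> named per-type probability
  for (pr in scenario@exclusivityPairs) {
    for (side in list(list(g = pr$geneA, p = pr$pOnA),
                      list(g = pr$geneB, p = pr$pOnB))) {
      if (!is.null(pOn[[side$g]]) &&
          !isTRUE(all.equal(pOn[[side$g]][names(side$p)], side$p))) {
        stop("conflicting on-probabilities for gene ", side$g)
      }
      pOn[[side$g]] <- side$p
    }
  }

  cellType <- rep(pop$label, pop$nCells)
  devOrder <- rep(pop$devOrder, pop$nCells)
  cellIds <- unlist(lapply(seq_len(nrow(pop)), function(i) {
    sprintf("%s_c%03d", pop$label[i], seq_len(pop$nCells[i]))
  }))
  nC <- length(cellIds)

  # per-type log2 elevation matrix from the marker programs
  elev <- matrix(0, nG, nrow(pop), dimnames = list(genes, pop$label))
  for (mp in scenario@markerPrograms) {
    gi <- match(mp$genes, genes)
    for (ty in names(mp$elevationByType)) {
      if (ty %in% pop$label) elev[gi, ty] <- elev[gi, ty] + mp$elevationByType[[ty]]
    }
  }

  exIdx <- match(exGenes, genes)
  counts <- matrix(0L, nG, nC, dimnames = list(genes, cellIds))
  muOn <- 2^scenario@onLog2Mean
  p0 <- pnbinom(0, mu = muOn, size = size)  # for zero-truncated draws

  for (j in seq_len(nC)) {
    ty <- cellType[j]
    mu <- 2^(b + elev[, ty])
    k <- rnbinom(nG, mu = mu, size = size)
    drop <- scenario@dropout[ty]
    if (!is.na(drop) && drop > 0) {
      k[rbinom(nG, 1, drop) == 1] <- 0L
    }
    if (length(exIdx)) {
      for (i in seq_along(exIdx)) {
        g <- exGenes[i]
        p <- pOn[[g]][ty]
        if (is.na(p)) p <- 0
        if (rbinom(1, 1, p) == 1) {
          u <- runif(1, p0, 1)  # inverse-CDF truncated NB, count >= 1
          k[exIdx[i]] <- qnbinom(u, mu = muOn, size = size)
        } else {
          k[exIdx[i]] <- 0L
        }
      }
    }
    counts[, j] <- k
  }

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_id = cellIds, cell_type = cellType,
                                   dev_order = devOrder,
                                   row.names = cellIds),
    metadata = list(scenario = scenario))
}

.defaultMesGenes <- function() sprintf("MES%03d", 1:50)
.defaultAdrnGenes <- function() sprintf("ADRN%03d", 1:50)
.koGroups <- c("C2", "C5", "C9", "C17", "C19")

#' Default synthetic study scenarios
#'
#' `defaultBulkScenario()` emulates the knockout-clone study design: one
#' parental line, five knockout clones (C2, C5, C9, C17, C19), one
#' overexpressing clone (C1), two biological replicates each. A 50-gene
#' mesenchymal program is planted up (+3 log2) and a 50-gene adrenergic
#' program down (-3) in all knockout clones, with both signs reversed (at
#' the smaller magnitude 2, an opposite but milder shift than the
#' knockouts') in the overexpressing clone; the knocked-out receptor gene
#' `RETL` has mean zero in the knockout groups and is overexpressed in C1;
#' its partner genes `AXLL` and `YAP1L` move with the mesenchymal program.
#'
#' `defaultScScenario()` emulates a four-population E13.5 sympathoadrenal
#' reference (100 cells per type by default). The mesenchymal program genes
#' are most elevated in Schwann cell precursors and the adrenergic program
#' genes in chromaffin cells, with bridge cells and sympathoblasts graded
#' between, so a mesenchymally reprogrammed clone correlates best with SCPs
#' and least with chromaffin cells. The exclusivity genes follow the
#' SCP on-fractions 0.85 (`AXLL`), 0.17 (`RETL`) and 0.79 (`YAP1L`),
#' mirror-reversed in the other populations.
#'
#' @param seed integer seed.
#' @param nGenes gene-universe size.
#' @return A [BulkScenario-class] or [ScRefScenario-class].
#' @export
defaultBulkScenario <- function(seed = 1L, nGenes = 2000L) {
  mes <- .defaultMesGenes()
  adrn <- .defaultAdrnGenes()
  ko <- .koGroups
  up <- setNames(rep(3, length(ko)), ko)
  programs <- list(
    plantedProgram("MES-up", mes, c(up, C1 = -2)),
    plantedProgram("ADRN-down", adrn, c(-up, C1 = 2)),
    plantedProgram("KO-gene", "RETL", c(C1 = 3), knockoutGroups = ko),
    plantedProgram("AXL-up", "AXLL", c(up, C1 = -2)),
    plantedProgram("YAP1-up", "YAP1L", c(up * 2 / 3, C1 = -1.5)))
  bulkScenario(
    nGenes = nGenes,
    groups = c(parental = 2L, C1 = 2L, C2 = 2L, C5 = 2L, C9 = 2L,
               C17 = 2L, C19 = 2L),
    refGroup = "parental", programs = programs, seed = seed)
}

#' @param nCellsPerType cells per population (>= 20).
#' @rdname defaultBulkScenario
#' @export
defaultScScenario <- function(seed = 1L, nGenes = 2000L,
                              nCellsPerType = 100L) {
  mes <- .defaultMesGenes()
  adrn <- .defaultAdrnGenes()
  populations <- data.frame(
    label = c("SCP", "bridge", "chromaffin", "sympathoblast"),
    nCells = rep(as.integer(nCellsPerType), 4),
    devOrder = c(1L, 2L, 3L, 4L), stringsAsFactors = FALSE)
  markerPrograms <- list(
    MES = list(genes = mes,
               elevationByType = c(SCP = 4, bridge = 2.33,
                                   sympathoblast = 1, chromaffin = 0)),
    ADRN = list(genes = adrn,
                elevationByType = c(SCP = 0, bridge = 1,
                                    sympathoblast = 2.33, chromaffin = 4)))
  mirrored <- function(pSCP) {
    c(SCP = pSCP, bridge = 1 - pSCP, chromaffin = 1 - pSCP,
      sympathoblast = 1 - pSCP)
  }
  exclusivityPairs <- list(
    list(geneA = "RETL", geneB = "AXLL",
         pOnA = mirrored(0.17), pOnB = mirrored(0.85)),
    list(geneA = "RETL", geneB = "YAP1L",
         pOnA = mirrored(0.17), pOnB = mirrored(0.79)))
  scRefScenario(nGenes = nGenes, populations = populations,
                markerPrograms = markerPrograms,
                exclusivityPairs = exclusivityPairs, seed = seed)
}
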