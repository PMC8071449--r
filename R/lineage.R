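#' Map reference gene symbols onto the analysis species
#'
#' Renames the rows of a reference (e.g. mouse single-cell) matrix to the
#' analysis-species symbols using a two-column ortholog map. Many-to-one
#' and one-to-many mappings are dropped and counted; rows without a
#' mapping are dropped and listed. Without a map, the fallback is
#' case-normalized symbol identity (rownames are upper-cased), which
#' handles the common mouse-to-human convention (Yap1 -> YAP1).
#'
#' @param mat gene-by-cell matrix.
#' @param map data.frame with columns `ref_symbol`, `target_symbol`
#'   (extra columns ignored), or NULL for the case fallback.
#' @return list with `matrix` (renamed), `unmapped` (dropped reference
#'   symbols) and `nDroppedAmbiguous` (many-to-one + one-to-many pairs).
#' @export
mapOrthologs <- function(mat, map = NULL) {
  mat <- as.matrix(mat)
  if (is.null(map)) {
    renamed <- mat
    rownames(renamed) <- toupper(rownames(mat))
    if (anyDuplicated(rownames(renamed))) {
      dup <- duplicated(rownames(renamed)) |
        duplicated(rownames(renamed), fromLast = TRUE)
      renamed <- renamed[!dup, , drop = FALSE]
    }
    return(list(matrix = renamed, unmapped = character(),
                nDroppedAmbiguous = 0L))
  }
  stopifnot(all(c("ref_symbol", "target_symbol") %in% colnames(map)))
  ambiguous <- duplicated(map$ref_symbol) |
    duplicated(map$ref_symbol, fromLast = TRUE) |
    duplicated(map$target_symbol) |
    duplicated(map$target_symbol, fromLast = TRUE)
  nAmb <- sum(ambiguous)
  map <- map[!ambiguous, , drop = FALSE]
  hit <- rownames(mat) %in% map$ref_symbol
  unmapped <- rownames(mat)[!hit]
  out <- mat[hit, , drop = FALSE]
  if (nrow(out) == 0) stop("no reference gene maps onto the analysis symbols")
  rownames(out) <- map$target_symbol[match(rownames(out), map$ref_symbol)]
  list(matrix = out, unmapped = unmapped, nDroppedAmbiguous = nAmb)
}

#' Correlate bulk clone profiles with single cells
#'
#' Normalizes both matrices by median-of-ratios size factors, transforms to
#' `log2(normalized + 1)` (unless `useLog = FALSE`), averages clone
#' replicates into one profile per clone, and computes the Pearson
#' correlation between every (cell, clone) pair over the shared genes.
#' Pairs where either profile is constant across the shared genes get an
#' undefined (NA) correlation and are recorded.
#'
#' @param cloneCounts gene-by-sample bulk counts (matrix or
#'   SummarizedExperiment).
#' @param cellCounts gene-by-cell reference counts (matrix or
#'   SingleCellExperiment), already mapped to the analysis symbols (see
#'   [mapOrthologs()]).
#' @param cloneCondition named sample -> clone map (or from `colData`).
#' @param cellInfo data.frame with `cell_id`, `cell_type`, `dev_order`
#'   (or from `colData`).
#' @param useLog correlate on log2(normalized + 1) values (default TRUE);
#'   `FALSE` correlates normalized values directly.
#' @param minSharedGenes minimum size of the shared gene universe.
#' @param fallbackPositiveGeomean passed to [estimateSizeFactorsMOR()] for
#'   the cell matrix (sparse matrices may need it).
#' @return a [CorrelationMap-class].
#' @export
correlateClonesToCells <- function(cloneCounts, cellCounts,
                                   cloneCondition = NULL, cellInfo = NULL,
                                   useLog = TRUE, minSharedGenes = 100L,
                                   fallbackPositiveGeomean = FALSE) {
  cloneCondition <- .conditionOf(cloneCounts, cloneCondition)
  if (is.null(cellInfo)) {
    if (!methods::is(cellCounts, "SummarizedExperiment"))
      stop("cellInfo annotations are required")
    cellInfo <- as.data.frame(SummarizedExperiment::colData(cellCounts))
  }
  stopifnot(all(c("cell_id", "cell_type", "dev_order") %in% colnames(cellInfo)))

  cloneM <- .asCountsMatrix(cloneCounts)
  cellM <- .asCountsMatrix(cellCounts)
  shared <- intersect(rownames(cloneM), rownames(cellM))
  if (length(shared) < minSharedGenes)
    stop(sprintf("only %d shared genes (need >= %d)", length(shared),
                 minSharedGenes))

  cloneN <- normalizeCounts(cloneM)[shared, , drop = FALSE]
  cellN <- normalizeCounts(
    cellM, estimateSizeFactorsMOR(cellM, fallbackPositiveGeomean)
  )[shared, , drop = FALSE]
  if (useLog) {
    cloneN <- log2(cloneN + 1)
    cellN <- log2(cellN + 1)
  }

  cloneCondition <- cloneCondition[colnames(cloneN)]
  clones <- unique(cloneCondition)
  profile <- vapply(clones, function(cl) {
    rowMeans(cloneN[, cloneCondition == cl, drop = FALSE])
  }, numeric(length(shared)))

  r <- suppressWarnings(cor(cellN, profile))  # cells x clones
  dropped <- which(!is.finite(r), arr.ind = TRUE)
  droppedPairs <- data.frame(
    cell = rownames(r)[dropped[, 1]],
    clone = colnames(r)[dropped[, 2]], stringsAsFactors = FALSE)
  r[!is.finite(r)] <- NA_real_

  ann <- cellInfo[match(colnames(cellN), cellInfo$cell_id), , drop = FALSE]
  rownames(ann) <- NULL
  new("CorrelationMap", r = r, cellAnnotations = ann,
      nGenesUsed = length(shared), droppedPairs = droppedPairs)
}

#' Mean correlation per (clone, cell type)
#'
#' Arithmetic mean of the Pearson coefficients within each annotated
#' cell-type group, the summary behind "mean r per developmental
#' population".
#'
#' @param cmap a [CorrelationMap-class].
#' @return data.frame with columns `clone`, `cellType`, `meanR`, `nCells`,
#'   ordered by developmental order then clone.
#' @export
meanCorrelationByType <- function(cmap) {
  stopifnot(methods::is(cmap, "CorrelationMap"))
  r <- cmap@r
  ann <- cmap@cellAnnotations
  out <- do.call(rbind, lapply(split(seq_len(nrow(r)), ann$cell_type),
    function(i) {
      data.frame(clone = colnames(r),
                 cellType = ann$cell_type[i[1]],
                 devOrder = ann$dev_order[i[1]],
                 meanR = colMeans(r[i, , drop = FALSE], na.rm = TRUE),
                 nCells = length(i), stringsAsFactors = FALSE)
    }))
  out <- out[order(out$devOrder, out$clone), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binarize expression at zero
#'
#' A gene is "expressed" in a cell iff its count is greater than zero.
#' Because median-of-ratios normalization preserves zero-sets, raw and
#' normalized inputs give identical output.
#'
#' @param mat gene-by-cell counts (raw or normalized); negative entries
#'   are rejected.
#' @return logical gene-by-cell matrix.
#' @export
binarizeExpression <- function(mat) {
  m <- as.matrix(mat)
  if (any(m < 0)) stop("negative entries cannot be binarized")
  m > 0
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric test: with margins fixed, the two-sided
#' p-value sums the probabilities of all tables at most as probable as the
#' one observed. The reported odds ratio is the sample odds ratio
#' `(a d) / (b c)`, with 0.5 added to every cell (for the odds ratio only,
#' never the p-value) when any cell is zero, flagged `"0-cell"`. A table
#' with a zero margin carries no information: p = 1 and the odds ratio is
#' flagged undefined.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return list with `oddsRatio`, `pvalue`, `flag` (`"ok"`, `"0-cell"` or
#'   `"zero-margin"`) and the input `table`.
#' @export
fisherExact2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
    stop("table entries must be non-negative integers")
  tab <- round(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(oddsRatio = NA_real_, pvalue = 1, flag = "zero-margin",
                table = tab))
  }
  p <- fisher.test(tab)$p.value
  if (any(tab == 0)) {
    or <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    flag <- "0-cell"
  } else {
    or <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
    flag <- "ok"
  }
  list(oddsRatio = or, pvalue = min(p, 1), flag = flag, table = tab)
}

#' Mutual-exclusivity test for a gene pair
#'
#' Cross-tabulates expressed/non-expressed (count > 0) status of two genes
#' over all cells and applies the two-sided Fisher's exact test. An odds
#' ratio below 1 indicates a mutually exclusive pattern, above 1
#' co-occurrence.
#'
#' @param mat gene-by-cell count matrix (raw or normalized) or logical
#'   binarized matrix from [binarizeExpression()].
#' @param geneA,geneB gene symbols; an absent gene is an error naming it.
#' @return list with `geneA`, `geneB`, `table` (A on/off rows by B on/off
#'   columns), `oddsRatio`, `pvalue`, `flag` and `direction`
#'   (`"exclusive"`, `"co-occurring"` or `"none"`).
#' @export
exclusivityTest <- function(mat, geneA, geneB) {
  b <- if (is.logical(mat)) mat else binarizeExpression(mat)
  for (g in c(geneA, geneB)) {
    if (!g %in% rownames(b)) stop("gene not present in the matrix: ", g)
  }
  A <- b[geneA, ]
  B <- b[geneB, ]
  tab <- matrix(c(sum(A & B), sum(!A & B), sum(A & !B), sum(!A & !B)), 2, 2,
                dimnames = list(c("A_on", "A_off"), c("B_on", "B_off")))
  ft <- fisherExact2x2(tab)
  direction <- if (is.na(ft$oddsRatio) || ft$oddsRatio == 1) "none"
  else if (ft$oddsRatio < 1) "exclusive" else "co-occurring"
  list(geneA = geneA, geneB = geneB, table = tab, oddsRatio = ft$oddsRatio,
       pvalue = ft$pvalue, flag = ft$flag, direction = direction)
}

#' Expression-by-cell-type contingency test
#'
#' The alternative contingency construction: expressed/non-expressed
#' status of one gene against membership in a chosen cell type, with the
#' same two-sided Fisher's exact test. Also reports the fraction of cells
#' of the chosen type expressing the gene.
#'
#' @param mat count or binarized gene-by-cell matrix.
#' @param gene gene symbol.
#' @param cellTypes per-cell type labels aligned to columns.
#' @param type the cell type tested against (default `"SCP"`).
#' @return list with `table`, `oddsRatio`, `pvalue`, `flag` and
#'   `fractionOnInType`.
#' @export
typeEnrichmentTest <- function(mat, gene, cellTypes, type = "SCP") {
  b <- if (is.logical(mat)) mat else binarizeExpression(mat)
  if (!gene %in% rownames(b)) stop("gene not present in the matrix: ", gene)
  stopifnot(length(cellTypes) == ncol(b))
  on <- b[gene, ]
  inType <- cellTypes == type
  tab <- matrix(c(sum(on & inType), sum(!on & inType),
                  sum(on & !inType), sum(!on & !inType)), 2, 2,
                dimnames = list(c("on", "off"), c(type, paste0("not_", type))))
  ft <- fisherExact2x2(tab)
  c(ft[c("oddsRatio", "pvalue", "flag")],
    list(table = tab, fractionOnInType = mean(on[inType])))
}

#' Agglomerative hierarchical clustering with Manhattan distance
#'
#' Clusters the rows or columns of a matrix by agglomerative hierarchical
#' clustering on Manhattan (L1) distances. Complete linkage by default
#' (monotone merge heights); average and single linkage are available.
#'
#' @param mat numeric matrix; non-finite entries are rejected with their
#'   locations.
#' @param axis cluster `"rows"` (default) or `"cols"`.
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @param k optional number of flat clusters to cut.
#' @return list of class `"clusteringResult"` with the `hclust` object,
#'   `leafOrder` (labels in dendrogram order), `heights` and (if `k`
#'   given) `labels`, the flat cluster assignment.
#' @export
hierarchicalCluster <- function(mat, axis = c("rows", "cols"),
                                linkage = c("complete", "average", "single"),
                                k = NULL) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  m <- as.matrix(mat)
  if (axis == "cols") m <- t(m)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite entries at: ",
         paste(sprintf("(%s, %s)", rownames(m)[bad[, 1]],
                       colnames(m)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = ", "))
  }
  if (nrow(m) < 2) stop("need >= 2 items on the clustered axis")
  hc <- hclust(dist(m, method = "manhattan"), method = linkage)
  out <- list(hclust = hc, leafOrder = hc$labels[hc$order],
              heights = hc$height, linkage = linkage, axis = axis)
  if (!is.null(k)) out$labels <- cutree(hc, k = k)
  class(out) <- "clusteringResult"
  out
}

#' @export
print.clusteringResult <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, " linkage, Manhattan, ",
      x$axis, "): ", length(x$leafOrder), " leaves\n", sep = "")
  if (!is.null(x$labels))
    cat("flat clusters:", paste(table(x$labels), collapse = "/"), "\n")
  invisible(x)
}

#' Write a dendrogram as Newick text
#'
#' @param clustering a result of [hierarchicalCluster()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDendrogramNewick <- function(clustering, path) {
  stopifnot(inherits(clustering, "clusteringResult"))
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
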