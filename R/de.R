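#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over eligible genes of
#' `count[g, j] / geomean(count[g, ])`, where the geometric mean is taken
#' across samples and eligible genes are those with a positive count in
#' every sample. This is the median-of-ratios normalization used for
#' negative-binomial RNA-seq counts.
#'
#' @param counts gene-by-sample count matrix (or SummarizedExperiment with
#'   a `"counts"` assay).
#' @param fallbackPositiveGeomean if no gene is positive in every sample
#'   (common in sparse single-cell matrices), compute each gene's geometric
#'   mean over its positive entries only and take the median of ratios over
#'   a sample's positive counts. Off by default; an informative error asks
#'   for it when needed.
#' @return named numeric vector of per-sample size factors (all > 0).
#' @export
estimateSizeFactorsMOR <- function(counts, fallbackPositiveGeomean = FALSE) {
  m <- .asCountsMatrix(counts)
  eligible <- rowSums(m > 0) == ncol(m)
  if (!any(eligible)) {
    if (!fallbackPositiveGeomean) {
      stop("no gene has positive counts in every sample; ",
           "re-run with fallbackPositiveGeomean = TRUE")
    }
    geo <- apply(m, 1, function(x) {
      x <- x[x > 0]
      if (length(x)) exp(mean(log(x))) else NA_real_
    })
    use <- is.finite(geo)
    sf <- vapply(seq_len(ncol(m)), function(j) {
      r <- m[use, j] / geo[use]
      median(r[m[use, j] > 0])
    }, numeric(1))
  } else {
    sub <- m[eligible, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- vapply(seq_len(ncol(sub)), function(j) median(sub[, j] / geo),
                 numeric(1))
  }
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factor estimated")
  setNames(sf, colnames(m))
}

#' Normalize counts by size factors
#'
#' Divides each sample's column by its size factor (estimated by
#' [estimateSizeFactorsMOR()] when not supplied). Gene and sample names are
#' preserved.
#'
#' @inheritParams estimateSizeFactorsMOR
#' @param sizeFactors optional named per-sample size factors.
#' @return real-valued gene-by-sample matrix.
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
  m <- .asCountsMatrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactorsMOR(m)
  if (length(sizeFactors) != ncol(m))
    stop("size factor / sample count mismatch")
  if (!is.null(names(sizeFactors))) {
    if (!setequal(names(sizeFactors), colnames(m)))
      stop("size factor names do not match sample ids")
    sizeFactors <- sizeFactors[colnames(m)]
  }
  sweep(m, 2, sizeFactors, "/")
}

#' Differential-expression test configuration
#'
#' @param lfcThreshold absolute log2 fold-change threshold for calling a
#'   gene differentially expressed (strict inequality). Default 2.
#' @param alpha BH-adjusted p-value threshold (strict). Default 0.01.
#' @param minTotalCount genes with a smaller total raw count across the
#'   tested samples are removed before testing.
#' @param pseudoFraction small positive fraction used to stabilize fold
#'   changes: `eps = pseudoFraction * (muA + muB + 1)` is added to both
#'   group means, so an all-zero knockout gene yields a large finite
#'   |log2fc| rather than +/-Inf.
#' @param dispersionFloor,dispersionCap bounds on the per-gene dispersion.
#' @return a list of validated settings.
#' @export
deConfig <- function(lfcThreshold = 2, alpha = 0.01, minTotalCount = 10L,
                     pseudoFraction = 1e-3, dispersionFloor = 1e-8,
                     dispersionCap = 10) {
  stopifnot(alpha > 0, alpha < 1, lfcThreshold >= 0, pseudoFraction > 0,
            dispersionFloor > 0, dispersionCap > dispersionFloor)
  list(lfcThreshold = lfcThreshold, alpha = alpha,
       minTotalCount = as.integer(minTotalCount),
       pseudoFraction = pseudoFraction, dispersionFloor = dispersionFloor,
       dispersionCap = dispersionCap)
}

#' Negative-binomial Wald test between two groups
#'
#' A deliberately simple two-group differential-expression test for
#' NB-distributed counts: median-of-ratios normalization, per-group means
#' of normalized counts, per-gene method-of-moments dispersion
#' (`alpha = (var - mean) / mean^2`) pooled across the two groups and
#' floored at a dataset-level common dispersion (the median of the finite
#' per-gene estimates), a delta-method standard error for the log2 ratio of
#' group means, a Wald z statistic and a two-sided normal p-value with BH
#' adjustment. No dispersion or fold-change shrinkage, no outlier handling
#' and no independent filtering are applied, so results are statistically
#' comparable to, but not numerically identical with, full NB-GLM
#' differential-expression tools.
#'
#' The common-dispersion floor is what keeps the plug-in Wald test honest
#' with tiny group sizes: with n = 2-3 replicates the raw per-gene moment
#' estimate has so few degrees of freedom that normal p-values are badly
#' anti-conservative, while bounding it below by the dataset-level estimate
#' (a good estimate of the single shared dispersion the simulator and the
#' test both assume) restores near-nominal type-I error without sacrificing
#' power.
#'
#' @param counts count matrix or SummarizedExperiment (condition taken from
#'   `colData(counts)$condition` when not supplied).
#' @param condition named character vector mapping sample id to group.
#' @param ref,alt group labels; fold changes are `alt` over `ref`.
#' @param config see [deConfig()].
#' @param geneUniverse optional character vector restricting the tested
#'   genes (e.g. a coding-gene list) before filtering.
#' @return a [S4Vectors::DataFrame] with one row per tested gene and
#'   columns `gene`, `baseMean`, `log2fc`, `se`, `stat`, `pvalue`, `padj`,
#'   `deCall` (`"up"`, `"down"`, `"none"`) and `zeroInGroup`; metadata
#'   records the groups, config and common dispersion.
#' @export
runDE <- function(counts, condition = NULL, ref, alt, config = deConfig(),
                  geneUniverse = NULL) {
  condition <- .conditionOf(counts, condition)
  m <- .asCountsMatrix(counts)
  .checkWholeCounts(m)
  condition <- condition[colnames(m)]
  keep <- colnames(m)[condition %in% c(ref, alt)]
  if (!all(c(ref, alt) %in% condition)) stop("ref/alt group not found")
  m <- m[, keep, drop = FALSE]
  condition <- condition[keep]
  nA <- sum(condition == ref)
  nB <- sum(condition == alt)
  if (nA < 2 || nB < 2)
    stop("each group needs >= 2 samples (dispersion inestimable otherwise)")

  if (!is.null(geneUniverse)) m <- m[rownames(m) %in% geneUniverse, , drop = FALSE]
  m <- m[rowSums(m) >= config$minTotalCount, , drop = FALSE]
  if (nrow(m) == 0) stop("no gene passes the count filter")

  sf <- estimateSizeFactorsMOR(m)
  nc <- normalizeCounts(m, sf)
  A <- nc[, condition == ref, drop = FALSE]
  B <- nc[, condition == alt, drop = FALSE]
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  vA <- apply(A, 1, var)
  vB <- apply(B, 1, var)

  momA <- (vA - mA) / pmax(mA, 1e-12)^2
  momB <- (vB - mB) / pmax(mB, 1e-12)^2
  mom <- ((nA - 1) * momA + (nB - 1) * momB) / (nA + nB - 2)
  finite <- is.finite(mom) & mA > 0 & mB > 0
  commonDisp <- if (any(finite)) max(median(mom[finite]), 0) else 0
  disp <- pmin(pmax(mom, commonDisp, config$dispersionFloor,
                    na.rm = TRUE), config$dispersionCap)

  eps <- config$pseudoFraction * (mA + mB + 1)
  mAe <- mA + eps
  mBe <- mB + eps
  log2fc <- log2(mBe / mAe)
  se <- sqrt((mAe + disp * mAe^2) / (nA * mAe^2) +
             (mBe + disp * mBe^2) / (nB * mBe^2)) / log(2)
  stat <- log2fc / se
  pvalue <- 2 * pnorm(-abs(stat))
  padj <- benjaminiHochberg(pvalue)

  deCall <- rep("none", nrow(m))
  deCall[log2fc > config$lfcThreshold & padj < config$alpha] <- "up"
  deCall[log2fc < -config$lfcThreshold & padj < config$alpha] <- "down"

  res <- S4Vectors::DataFrame(
    gene = rownames(m), baseMean = rowMeans(nc), log2fc = log2fc, se = se,
    stat = stat, pvalue = pvalue, padj = padj, deCall = deCall,
    zeroInGroup = (mA == 0) | (mB == 0), row.names = rownames(m))
  S4Vectors::metadata(res) <- list(ref = ref, alt = alt, config = config,
                                   commonDispersion = commonDisp,
                                   sizeFactors = sf)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with monotonicity enforcement, order-preserving
#' with the input. Inputs outside \[0, 1\] are rejected.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
benjaminiHochberg <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes at thresholds
#'
#' Strict inequalities on both thresholds: a gene with log2fc exactly at
#' the threshold is not called.
#'
#' @param table a result table from [runDE()].
#' @param config see [deConfig()].
#' @return list with character vectors `up` and `down`.
#' @export
callDEGenes <- function(table, config = deConfig()) {
  if (nrow(table) == 0) return(list(up = character(), down = character()))
  sig <- table$padj < config$alpha
  list(up = table$gene[sig & table$log2fc > config$lfcThreshold],
       down = table$gene[sig & table$log2fc < -config$lfcThreshold])
}

#' Intersect DE calls across clone comparisons
#'
#' Computes the genes called in a common direction by every clone-vs-
#' reference comparison, plus Venn-style region counts (one row per
#' observed membership pattern and direction).
#'
#' @param deLists named list (one element per clone comparison) of
#'   `list(up = , down = )` gene vectors, as returned by [callDEGenes()].
#' @return list with `up` and `down` common gene vectors and `regions`, a
#'   data.frame with columns `direction`, `pattern` (clone labels joined by
#'   `&`) and `count`.
#' @export
intersectDEAcrossClones <- function(deLists) {
  if (length(deLists) < 2) stop("need >= 2 clone comparisons")
  if (is.null(names(deLists)) || any(!nzchar(names(deLists))))
    stop("deLists must be named by clone")
  regionsOf <- function(direction) {
    sets <- lapply(deLists, `[[`, direction)
    union <- unique(unlist(sets))
    if (!length(union)) {
      return(data.frame(direction = character(), pattern = character(),
                        count = integer(), stringsAsFactors = FALSE))
    }
    member <- vapply(sets, function(s) union %in% s, logical(length(union)))
    member <- matrix(member, nrow = length(union),
                     dimnames = list(union, names(deLists)))
    pattern <- apply(member, 1, function(r) {
      paste(names(deLists)[r], collapse = "&")
    })
    tab <- table(pattern)
    data.frame(direction = direction, pattern = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }
  list(up = Reduce(intersect, lapply(deLists, `[[`, "up")),
       down = Reduce(intersect, lapply(deLists, `[[`, "down")),
       regions = rbind(regionsOf("up"), regionsOf("down")))
}
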