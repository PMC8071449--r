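#' ADRN/MES signature gene pair
#'
#' A pair of disjoint gene lists defining the adrenergic (ADRN) and
#' mesenchymal (MES) neuroblastoma cell-state signatures. Lists are
#' de-duplicated and must be non-empty and disjoint.
#'
#' @param adrnGenes,mesGenes character vectors of gene symbols.
#' @param note free-text provenance note.
#' @return a list of class `"signaturePair"`.
#' @export
signaturePair <- function(adrnGenes, mesGenes, note = "") {
  adrnGenes <- unique(as.character(adrnGenes))
  mesGenes <- unique(as.character(mesGenes))
  if (!length(adrnGenes) || !length(mesGenes))
    stop("both signature lists must be non-empty")
  if (length(intersect(adrnGenes, mesGenes)))
    stop("signature lists must be disjoint")
  structure(list(adrn = adrnGenes, mes = mesGenes, note = note),
            class = "signaturePair")
}

#' Built-in demonstration signature pair
#'
#' The signature lists planted by [defaultBulkScenario()]: 50 mesenchymal
#' and 50 adrenergic program genes. Intended for tests and examples; real
#' analyses should load published signature lists with [readSignature()].
#'
#' @return a `"signaturePair"`.
#' @export
demoSignaturePair <- function() {
  signaturePair(.defaultAdrnGenes(), .defaultMesGenes(),
                note = "synthetic demo signatures (planted programs)")
}

#' Read a signature gene list
#'
#' Plain text, one symbol per line; `#` starts a comment; blank lines are
#' ignored.
#'
#' @param path file path.
#' @return character vector of symbols.
#' @export
readSignature <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Rank percentiles of an expression column
#'
#' Ascending average ranks divided by the number of genes: the
#' highest-expressed gene scores 1, and percentiles are invariant under
#' any strictly increasing transform of the column. An all-identical
#' column yields `(N + 1) / (2N)` everywhere, with a warning.
#'
#' @param values per-gene numeric expression values (length >= 2, finite).
#' @return per-gene percentiles in (0, 1\].
#' @export
geneRankPercentiles <- function(values) {
  if (length(values) < 2) stop("need >= 2 genes")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L)
    warning("all expression values identical; percentiles are all (N+1)/(2N)")
  rank(values, ties.method = "average") / length(values)
}

#' Signature score of each sample
#'
#' A sample's score for a signature is the mean rank percentile of the
#' signature genes present in the matrix, the percentile being computed
#' within the sample over the full gene universe of the matrix. Scores
#' depend only on within-sample ranks, so any per-sample positive scaling
#' (library size, normalization choice) leaves them unchanged.
#'
#' @param mat gene-by-sample expression matrix (raw or normalized counts).
#' @param signature character vector of signature genes.
#' @param minFraction minimum fraction of signature genes that must be
#'   present in the matrix (default 0.5).
#' @return list with `score` (named per-sample numeric in \[0, 1\]) and
#'   `nGenesUsed`.
#' @export
signatureScore <- function(mat, signature, minFraction = 0.5) {
  mat <- as.matrix(mat)
  signature <- unique(signature)
  present <- intersect(signature, rownames(mat))
  frac <- length(present) / length(signature)
  if (frac < minFraction) {
    stop(sprintf("only %.0f%% of signature genes present (%d of %d); need >= %.0f%%",
                 100 * frac, length(present), length(signature),
                 100 * minFraction))
  }
  pct <- apply(mat, 2, geneRankPercentiles)
  score <- colMeans(pct[present, , drop = FALSE])
  list(score = score, nGenesUsed = length(present))
}

#' MES and ADRN signature scores per sample
#'
#' Computes both cell-state scores for every sample plus per-clone medians
#' (the summary drawn as horizontal lines in per-clone score plots).
#'
#' @param mat gene-by-sample matrix, or a SummarizedExperiment.
#' @param pair a [signaturePair()].
#' @param condition named sample -> clone map (taken from `colData` when
#'   `mat` is a SummarizedExperiment).
#' @param minFraction see [signatureScore()].
#' @return [S4Vectors::DataFrame] with columns `sample`, `clone`,
#'   `mesScore`, `adrnScore`, `nMesUsed`, `nAdrnUsed`;
#'   `metadata(x)$groupMedians` holds the per-clone medians.
#' @export
scoreClones <- function(mat, pair, condition = NULL, minFraction = 0.5) {
  stopifnot(inherits(pair, "signaturePair"))
  condition <- tryCatch(.conditionOf(mat, condition), error = function(e) NULL)
  m <- if (methods::is(mat, "SummarizedExperiment")) {
    SummarizedExperiment::assay(mat, "counts")
  } else {
    as.matrix(mat)
  }
  mes <- signatureScore(m, pair$mes, minFraction)
  adrn <- signatureScore(m, pair$adrn, minFraction)
  clone <- if (is.null(condition)) rep(NA_character_, ncol(m)) else
    as.character(condition[colnames(m)])
  res <- S4Vectors::DataFrame(
    sample = colnames(m), clone = clone,
    mesScore = mes$score, adrnScore = adrn$score,
    nMesUsed = mes$nGenesUsed, nAdrnUsed = adrn$nGenesUsed,
    row.names = colnames(m))
  med <- NULL
  if (!all(is.na(clone))) {
    med <- do.call(rbind, lapply(split(seq_len(ncol(m)), clone), function(i) {
      data.frame(clone = clone[i[1]], mesMedian = median(res$mesScore[i]),
                 adrnMedian = median(res$adrnScore[i]),
                 stringsAsFactors = FALSE)
    }))
    rownames(med) <- NULL
  }
  S4Vectors::metadata(res) <- list(groupMedians = med)
  res
}
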