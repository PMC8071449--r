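#' @importFrom methods new validObject is slot
#' @importFrom stats median rnbinom runif rbinom qnbinom pnbinom cor cutree
#'   dist hclust p.adjust pnorm quantile rank setNames var fisher.test
#' @importFrom utils read.delim write.table packageVersion head
NULL

# Derive a named RNG sub-stream seed from a global seed. Polynomial string
# hash mod the Mersenne prime 2^31 - 1 keeps everything in integer range.
subSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m + h) %% m)
}

# Extract a plain counts matrix from a matrix-like or SummarizedExperiment.
.asCountsMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, "counts")
  }
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("duplicate gene symbols: ", paste(head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (any(x < 0)) stop("negative entries in count matrix")
  x
}

.checkWholeCounts <- function(x) {
  off <- which(abs(x - round(x)) > 1e-8, arr.ind = TRUE)
  if (nrow(off) > 0) {
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(x)[off[1, 1]], colnames(x)[off[1, 2]]))
  }
  invisible(TRUE)
}

# Condition vector for a counts matrix: named character, or pulled from
# the colData of a SummarizedExperiment.
.conditionOf <- function(x, condition = NULL) {
  if (is.null(condition) && methods::is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (!"condition" %in% colnames(cd)) {
      stop("no 'condition' column in colData and none supplied")
    }
    condition <- setNames(as.character(cd$condition), colnames(x))
  }
  if (is.null(condition)) stop("a sample -> group 'condition' map is required")
  condition
}
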