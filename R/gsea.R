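#' Read and write GMT gene-set collections
#'
#' Standard tab-delimited GMT: one set per line, fields name, description,
#' then member gene symbols. Symbols are whitespace-trimmed,
#' case-preserved and de-duplicated.
#'
#' @param path file path.
#' @return `readGMT` returns a named list of character gene vectors with a
#'   `"descriptions"` attribute; `writeGMT` writes one and returns the path
#'   invisibly.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3) stop(sprintf("GMT line %d has fewer than 3 fields", i))
    name <- f[1]
    if (name %in% names(sets)) stop("duplicate set name: ", name)
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members)) stop(sprintf("GMT line %d has no members", i))
    sets[[name]] <- members
    desc[name] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @param sets named list of character gene vectors (optionally with a
#'   `"descriptions"` attribute).
#' @rdname readGMT
#' @export
writeGMT <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(n) {
    d <- if (!is.null(desc) && n %in% names(desc)) desc[[n]] else "na"
    paste(c(n, d, sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a ranked gene list from a DE result table
#'
#' Ranks genes by the Wald statistic, either by its absolute value
#' (`transform = "absolute"`, the default used for the knockout-clone
#' analysis) or signed. Ties are broken lexicographically by gene symbol;
#' genes with non-finite statistics are dropped with a warning.
#'
#' @param table result of [runDE()] (needs `gene` and `stat` columns).
#' @param transform `"absolute"` or `"signed"`.
#' @return data.frame with columns `gene` and `score`, ordered by
#'   descending score; the transform is recorded as an attribute.
#' @export
makeRankedList <- function(table, transform = c("absolute", "signed")) {
  transform <- match.arg(transform)
  gene <- as.character(table$gene)
  stat <- as.numeric(table$stat)
  bad <- !is.finite(stat)
  if (any(bad)) {
    warning(sum(bad), " genes with non-finite statistic dropped")
    gene <- gene[!bad]
    stat <- stat[!bad]
  }
  score <- if (transform == "absolute") abs(stat) else stat
  o <- order(-score, gene)
  out <- data.frame(gene = gene[o], score = score[o],
                    stringsAsFactors = FALSE)
  attr(out, "transform") <- transform
  out
}

# ES from sorted hit positions; w = per-gene weights |score|^p, N = length.
# Candidates for the extremum: the running sum at each hit (maximum) and
# just before each hit (minimum); the tail always returns to 0.
.esFromPositions <- function(pos, w, N) {
  k <- length(pos)
  wh <- w[pos]
  W <- sum(wh)
  if (W <= 0) {
    wh <- rep(1, k)
    W <- k
  }
  cw <- cumsum(wh)
  missStep <- (pos - seq_len(k)) / (N - k)
  hitVals <- cw / W - missStep
  beforeVals <- (cw - wh) / W - missStep
  mx <- max(hitVals)
  mn <- min(c(beforeVals, 0))
  if (mx >= -mn) mx else mn
}

#' Weighted running-sum enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov enrichment statistic: walking down
#' the ranked list, the running sum increases by `|score|^p / sum(|score|^p
#' over hits)` at set members and decreases by `1 / (N - nHits)` elsewhere;
#' the enrichment score is the signed maximum deviation from zero and the
#' leading edge contains the set members at or before the extremum (at or
#' after it for a negative score).
#'
#' @param ranked data.frame from [makeRankedList()].
#' @param geneSet character vector of member symbols.
#' @param weightP weighting exponent p (default 1).
#' @return list with `es`, `running` (profile over the list), `leadingEdge`
#'   and `size` (members in the ranked universe).
#' @export
enrichmentScore <- function(ranked, geneSet, weightP = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% geneSet
  k <- sum(hit)
  if (k == 0) stop("gene set has no member in the ranked universe")
  if (k == N) stop("gene set covers the entire ranked universe")
  w <- abs(ranked$score)^weightP
  wh <- w * hit
  W <- sum(wh)
  if (W <= 0) {
    wh <- as.numeric(hit)
    W <- k
  }
  running <- cumsum(wh / W - (!hit) / (N - k))
  mx <- max(running)
  mn <- min(c(running, 0))
  es <- if (mx >= -mn) mx else mn
  if (es >= 0) {
    peak <- which.max(running)
    leading <- ranked$gene[seq_len(peak)][hit[seq_len(peak)]]
  } else {
    trough <- which.min(running)
    idx <- seq(trough, N)
    leading <- ranked$gene[idx][hit[idx]]
  }
  list(es = es, running = running, leadingEdge = leading, size = k)
}

#' Pre-ranked gene-set enrichment analysis
#'
#' For each collection set with between `minSize` and `maxSize` members in
#' the ranked universe, computes the weighted running-sum enrichment score
#' and a gene-label permutation null (random same-size subsets of ranked
#' positions). The p-value is `(1 + #same-sign null at least as extreme) /
#' (1 + #same-sign null)` (floor `1/(nPerm + 1)`); NES divides the score by
#' the mean absolute same-sign null score; BH adjustment across tested
#' sets. Deterministic given `seed`.
#'
#' @inheritParams enrichmentScore
#' @param collection named list of gene sets (see [readGMT()]).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @param minSize,maxSize set-size bounds within the ranked universe.
#' @return [S4Vectors::DataFrame] with columns `set`, `size`, `es`, `nes`,
#'   `pvalue`, `padj` and `leadingEdge` (comma-joined); skipped sets are
#'   recorded in `metadata(result)$skipped`.
#' @export
gseaPreranked <- function(ranked, collection, nPerm = 1000L, seed = 1L,
                          minSize = 5L, maxSize = 500L, weightP = 1) {
  stopifnot(nPerm >= 100)
  N <- nrow(ranked)
  w <- abs(ranked$score)^weightP
  sizes <- vapply(collection, function(s) sum(ranked$gene %in% s), integer(1))
  testable <- names(collection)[sizes >= minSize & sizes <= maxSize]
  skipped <- data.frame(
    set = setdiff(names(collection), testable),
    reason = sprintf("size %d outside [%d, %d]",
                     sizes[setdiff(names(collection), testable)],
                     minSize, maxSize),
    stringsAsFactors = FALSE)
  if (!length(testable)) {
    res <- S4Vectors::DataFrame(set = character(), size = integer(),
                                es = numeric(), nes = numeric(),
                                pvalue = numeric(), padj = numeric(),
                                leadingEdge = character())
    S4Vectors::metadata(res) <- list(skipped = skipped, nPerm = nPerm)
    return(res)
  }

  set.seed(subSeed(seed, "gsea"))
  # one permutation pool per distinct set size
  nullES <- new.env()
  for (k in sort(unique(sizes[testable]))) {
    key <- as.character(k)
    nullES[[key]] <- vapply(seq_len(nPerm), function(i) {
      .esFromPositions(sort.int(sample.int(N, k)), w, N)
    }, numeric(1))
  }

  rows <- lapply(testable, function(nm) {
    obs <- enrichmentScore(ranked, collection[[nm]], weightP)
    null <- nullES[[as.character(obs$size)]]
    same <- if (obs$es >= 0) null[null >= 0] else null[null < 0]
    extreme <- sum(abs(same) >= abs(obs$es))
    p <- (1 + extreme) / (1 + length(same))
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    list(set = nm, size = obs$size, es = obs$es, nes = nes, pvalue = p,
         leadingEdge = paste(obs$leadingEdge, collapse = ","))
  })
  res <- S4Vectors::DataFrame(
    set = vapply(rows, `[[`, character(1), "set"),
    size = vapply(rows, `[[`, integer(1), "size"),
    es = vapply(rows, `[[`, numeric(1), "es"),
    nes = vapply(rows, `[[`, numeric(1), "nes"),
    pvalue = vapply(rows, `[[`, numeric(1), "pvalue"),
    leadingEdge = vapply(rows, `[[`, character(1), "leadingEdge"))
  res$padj <- benjaminiHochberg(res$pvalue)
  res <- res[, c("set", "size", "es", "nes", "pvalue", "padj", "leadingEdge")]
  rownames(res) <- res$set
  S4Vectors::metadata(res) <- list(skipped = skipped, nPerm = nPerm,
                                   seed = seed, weightP = weightP)
  res
}
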