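#' Read and write count matrices
#'
#' TSV layout: header row of sample ids, first column of gene symbols.
#' MatrixMarket layout: coordinate file with 1-based indices plus
#' `.rows`/`.cols` sidecar files (one name per line) next to the `.mtx`.
#' Matrices are validated: integer, non-negative, unique gene and sample
#' names; violations are reported with coordinates.
#'
#' @param path file path (`.mtx` for MatrixMarket).
#' @param format `"tsv"` or `"mtx"`; guessed from the extension when
#'   missing.
#' @return `readCountMatrix` returns an integer gene-by-sample matrix;
#'   `writeCountMatrix` writes one and returns the path invisibly.
#' @export
readCountMatrix <- function(path, format = c("tsv", "mtx")) {
  if (length(format) > 1)
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- genes
  } else {
    side <- function(ext) {
      p <- sub("\\.mtx$", ext, path)
      if (!file.exists(p)) stop("missing sidecar file: ", p)
      readLines(p)
    }
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "%")]
    hdr <- scan(text = body[1], quiet = TRUE)
    ent <- matrix(scan(text = body[-1], quiet = TRUE), ncol = 3, byrow = TRUE)
    if (nrow(ent) != hdr[3]) stop("MatrixMarket entry count mismatch")
    if (nrow(ent) && (min(ent[, 1]) < 1 || min(ent[, 2]) < 1))
      stop("MatrixMarket indices must be 1-based (found index < 1)")
    if (nrow(ent) && (max(ent[, 1]) > hdr[1] || max(ent[, 2]) > hdr[2]))
      stop("MatrixMarket index exceeds declared dimensions")
    m <- as.matrix(Matrix::sparseMatrix(i = ent[, 1], j = ent[, 2],
                                        x = ent[, 3],
                                        dims = c(hdr[1], hdr[2])))
    rownames(m) <- side(".rows")
    colnames(m) <- side(".cols")
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    stop("duplicate gene symbols: ", paste(head(dup, 5), collapse = ", "))
  }
  if (any(m < 0)) stop("negative count entries")
  .checkWholeCounts(m)
  storage.mode(m) <- "integer"
  m
}

#' @param mat integer gene-by-sample matrix.
#' @rdname readCountMatrix
#' @export
writeCountMatrix <- function(mat, path, format = c("tsv", "mtx")) {
  if (length(format) > 1)
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  format <- match.arg(format)
  m <- .asCountsMatrix(mat)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(m != 0, arr.ind = TRUE)
    o <- order(idx[, 2], idx[, 1])
    idx <- idx[o, , drop = FALSE]
    con <- file(path, "w")
    writeLines("%%MatrixMarket matrix coordinate integer general", con)
    writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(idx)), con)
    writeLines(sprintf("%d %d %d", idx[, 1], idx[, 2], m[idx]), con)
    close(con)
    writeLines(rownames(m), sub("\\.mtx$", ".rows", path))
    writeLines(colnames(m), sub("\\.mtx$", ".cols", path))
  }
  invisible(path)
}

#' Read a sample-condition table
#'
#' TSV with columns `sample` and `group` (header required).
#'
#' @param path file path.
#' @return named character vector, sample -> group.
#' @export
readConditionTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% colnames(df)))
  setNames(as.character(df$group), df$sample)
}

#' Read an ortholog symbol map
#'
#' TSV with columns `ref_symbol` and `target_symbol`.
#'
#' @param path file path.
#' @return data.frame with the two columns.
#' @export
readOrthologMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("ref_symbol", "target_symbol") %in% colnames(df)))
  df
}

#' Write a scenario to, and read one back from, a YAML config
#'
#' Serializes the generative parameters of a [BulkScenario-class] so a run
#' can be reproduced from one file.
#'
#' @param scenario a [BulkScenario-class].
#' @param path YAML file path.
#' @return `writeScenarioYaml` the path invisibly; `readScenarioYaml` a
#'   [BulkScenario-class].
#' @export
writeScenarioYaml <- function(scenario, path) {
  stopifnot(methods::is(scenario, "BulkScenario"))
  cfg <- list(
    nGenes = scenario@nGenes,
    groups = setNames(as.list(scenario@groups$n), scenario@groups$label),
    refGroup = scenario@refGroup,
    baselineLog2Range = scenario@baselineLog2Range,
    dispersion = scenario@dispersion,
    libSizeFactors = scenario@libSizeFactors,
    seed = scenario@seed,
    geneIds = scenario@geneIds,
    programs = lapply(scenario@programs, function(p) {
      list(name = p@name, genes = p@genes,
           log2fcByGroup = as.list(p@log2fcByGroup))
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeScenarioYaml
#' @export
readScenarioYaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  programs <- lapply(cfg$programs, function(p) {
    fc <- vapply(p$log2fcByGroup, function(x) {
      if (identical(x, "-Inf") || identical(x, ".inf.neg")) -Inf else
        as.numeric(x)
    }, numeric(1))
    plantedProgram(p$name, unlist(p$genes), setNames(fc, names(p$log2fcByGroup)))
  })
  bulkScenario(nGenes = cfg$nGenes,
               groups = setNames(as.integer(unlist(cfg$groups)),
                                 names(cfg$groups)),
               refGroup = cfg$refGroup,
               baselineLog2Range = as.numeric(unlist(cfg$baselineLog2Range)),
               dispersion = cfg$dispersion,
               programs = programs,
               libSizeFactors = as.numeric(unlist(cfg$libSizeFactors)),
               geneIds = unlist(cfg$geneIds),
               seed = cfg$seed)
}
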