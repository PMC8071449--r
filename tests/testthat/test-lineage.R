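test_that("ortholog mapping renames, drops ambiguity and falls back to case identity", {
  m <- matrix(1:6, 3, 2, dimnames = list(c("Ret", "Axl", "Gene3"),
                                         c("c1", "c2")))
  map <- data.frame(ref_symbol = c("Ret", "Axl"),
                    target_symbol = c("RET", "AXL"))
  out <- mapOrthologs(m, map)
  expect_identical(rownames(out$matrix), c("RET", "AXL"))
  expect_identical(out$unmapped, "Gene3")

  fb <- mapOrthologs(matrix(1:2, 1, 2, dimnames = list("Yap1", c("c1", "c2"))))
  expect_identical(rownames(fb$matrix), "YAP1")

  # round-trip with an invertible map restores the original rows
  inv <- data.frame(ref_symbol = map$target_symbol,
                    target_symbol = map$ref_symbol)
  back <- mapOrthologs(out$matrix, inv)
  expect_identical(back$matrix, m[c("Ret", "Axl"), ])

  amb <- data.frame(ref_symbol = c("Ret", "Ret", "Axl"),
                    target_symbol = c("RET", "RET2", "AXL"))
  outAmb <- mapOrthologs(m, amb)
  expect_equal(outAmb$nDroppedAmbiguous, 2)
  expect_identical(rownames(outAmb$matrix), "AXL")

  expect_error(mapOrthologs(m, data.frame(ref_symbol = "Foo",
                                          target_symbol = "BAR")),
               "no reference gene maps")
})

test_that("clone-cell correlations hit the exact extremes on constructed profiles", {
  set.seed(40)
  n <- 150
  x <- rpois(n, 60) + 1L
  genes <- sprintf("g%03d", 1:n)
  clone <- matrix(x, n, 1, dimnames = list(genes, "cloneA_R1"))
  cells <- cbind(same = x, anti = as.integer(max(x) + 1L - x))
  rownames(cells) <- genes
  cm <- correlateClonesToCells(clone, cells,
                               cloneCondition = c(cloneA_R1 = "cloneA"),
                               cellInfo = data.frame(
                                 cell_id = c("same", "anti"),
                                 cell_type = c("SCP", "bridge"),
                                 dev_order = 1:2),
                               useLog = FALSE)
  r <- corMatrix(cm)
  expect_equal(r["same", "cloneA"], 1, tolerance = 1e-12)
  expect_equal(r["anti", "cloneA"], -1, tolerance = 1e-12)
  expect_equal(cm@nGenesUsed, n)
})

test_that("per-type mean correlations equal a brute-force group-by and ignore cell order", {
  set.seed(41)
  nc <- 60
  ann <- data.frame(cell_id = sprintf("c%02d", 1:nc),
                    cell_type = sample(c("SCP", "bridge", "chromaffin"), nc,
                                       replace = TRUE),
                    dev_order = 0L)
  ann$dev_order <- match(ann$cell_type, c("SCP", "bridge", "chromaffin"))
  r <- matrix(runif(nc * 3, -1, 1), nc, 3,
              dimnames = list(ann$cell_id, c("p", "k1", "k2")))
  cmap <- new("CorrelationMap", r = r, cellAnnotations = ann,
              nGenesUsed = 100L,
              droppedPairs = data.frame(cell = character(),
                                        clone = character()))
  tm <- meanCorrelationByType(cmap)
  oracle <- bruteMeanByType(r, ann$cell_type)
  for (i in seq_len(nrow(tm))) {
    expect_equal(tm$meanR[i], oracle[[paste(tm$cellType[i], tm$clone[i])]])
  }
  perm <- sample(nc)
  cmapP <- new("CorrelationMap", r = r[perm, ],
               cellAnnotations = ann[perm, ], nGenesUsed = 100L,
               droppedPairs = data.frame(cell = character(),
                                         clone = character()))
  tmP <- meanCorrelationByType(cmapP)
  expect_equal(tm$meanR, tmP$meanR)
})

test_that("binarization is a strict zero test and survives normalization", {
  m <- matrix(c(0L, 1L, 3L, 0L), 2, 2, dimnames = list(c("a", "b"),
                                                       c("c1", "c2")))
  expect_identical(unname(binarizeExpression(m)),
                   matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_true(all(!binarizeExpression(matrix(0, 2, 2))))
  norm <- normalizeCounts(m + 0, c(c1 = 0.5, c2 = 2))
  expect_identical(binarizeExpression(norm), binarizeExpression(m))
  expect_error(binarizeExpression(matrix(-1, 1, 1)), "negative")
})

test_that("Fisher's exact p matches hypergeometric enumeration and is symmetric", {
  expect_equal(fisherExact2x2(matrix(5, 2, 2))$pvalue, 1)

  diag10 <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(fisherExact2x2(diag10)$pvalue, bruteFisherP(diag10),
               tolerance = 1e-12)
  expect_identical(fisherExact2x2(diag10)$flag, "0-cell")

  zm <- matrix(c(0, 0, 4, 6), 2, 2, byrow = TRUE)
  res <- fisherExact2x2(zm)
  expect_equal(res$pvalue, 1)
  expect_identical(res$flag, "zero-margin")

  set.seed(50)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisherExact2x2(tab)$pvalue
    expect_equal(p, bruteFisherP(tab), tolerance = 1e-10)
    expect_equal(fisherExact2x2(t(tab))$pvalue, p, tolerance = 1e-12)
    expect_equal(fisherExact2x2(tab[2:1, 2:1])$pvalue, p, tolerance = 1e-12)
  }
})

test_that("exclusivity tests classify planted patterns and stay uniform under the null", {
  # perfectly exclusive 40-cell pattern
  cells <- sprintf("c%02d", 1:40)
  m <- rbind(A = c(rep(1L, 20), rep(0L, 20)),
             B = c(rep(0L, 20), rep(1L, 20)))
  colnames(m) <- cells
  ex <- exclusivityTest(m, "A", "B")
  expect_identical(ex$direction, "exclusive")
  expect_identical(ex$flag, "0-cell")
  expect_equal(ex$pvalue, bruteFisherP(ex$table), tolerance = 1e-12)
  expect_error(exclusivityTest(m, "A", "missing"), "missing")

  # relabeling the two genes leaves the p-value unchanged
  expect_equal(exclusivityTest(m, "B", "A")$pvalue, ex$pvalue)

  set.seed(51)
  ps <- replicate(200, {
    b <- matrix(rbinom(2 * 1000, 1, 0.5) == 1, 2, 1000,
                dimnames = list(c("A", "B"), sprintf("c%04d", 1:1000)))
    exclusivityTest(b, "A", "B")$pvalue
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("gene-versus-type contingency reproduces the planted SCP on-fractions", {
  sce <- simulateScReference(defaultScScenario(seed = 33))
  cnt <- SummarizedExperiment::assay(sce)
  ty <- SummarizedExperiment::colData(sce)$cell_type
  axl <- typeEnrichmentTest(cnt, "AXLL", ty, "SCP")
  ret <- typeEnrichmentTest(cnt, "RETL", ty, "SCP")
  expect_gt(axl$fractionOnInType, 0.7)
  expect_lt(ret$fractionOnInType, 0.3)
  expect_gt(axl$oddsRatio, 1)   # AXL-like enriched in SCPs
  expect_lt(ret$oddsRatio, 1)   # RET-like depleted in SCPs
  expect_lt(axl$pvalue, 1e-6)
})

test_that("hierarchical clustering splits planted structure with monotone heights", {
  m <- rbind(matrix(rep(c(0, 0, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(9, 9, 9), 4), 4, byrow = TRUE))
  rownames(m) <- sprintf("r%d", 1:7)
  hc <- hierarchicalCluster(m, k = 2)
  expect_equal(unname(hc$labels), c(1, 1, 1, 2, 2, 2, 2))

  set.seed(60)
  rnd <- matrix(rnorm(40 * 5), 40, 5,
                dimnames = list(sprintf("i%02d", 1:40), sprintf("v%d", 1:5)))
  hr <- hierarchicalCluster(rnd, linkage = "complete", k = 4)
  expect_true(all(diff(hr$heights) >= -1e-12))

  # flat clusters invariant to input row order
  skip_if_not_installed("mclust")
  perm <- sample(40)
  hp <- hierarchicalCluster(rnd[perm, ], linkage = "complete", k = 4)
  expect_equal(mclust::adjustedRandIndex(hr$labels[rownames(rnd)[perm]],
                                         hp$labels), 1)

  bad <- rnd
  bad[3, 2] <- NaN
  expect_error(hierarchicalCluster(bad), "i03")

  nwk <- tempfile(fileext = ".nwk")
  writeDendrogramNewick(hr, nwk)
  expect_equal(length(ape::read.tree(nwk)$tip.label), 40)
})
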