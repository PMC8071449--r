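test_that("median-of-ratios size factors match forced cases and the brute-force oracle", {
  m <- matrix(c(2L, 10L, 4L, 20L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- estimateSizeFactorsMOR(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  same <- cbind(s1 = c(g1 = 3L, g2 = 7L), s2 = c(3L, 7L), s3 = c(3L, 7L))
  expect_equal(unname(estimateSizeFactorsMOR(same)), rep(1, 3))

  rnd <- randomCounts(500, 4, seed = 42)
  expect_equal(unname(estimateSizeFactorsMOR(rnd)), bruteSizeFactors(rnd),
               tolerance = 1e-12)
})

test_that("size factors agree with an established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  # odd, all-positive gene count: the two implementations' median
  # conventions coincide (they differ only in how an even-length median
  # averages its two middle ratios: arithmetically vs geometrically)
  rnd <- randomCounts(401, 6, seed = 7) + 1L
  expect_equal(unname(estimateSizeFactorsMOR(rnd)),
               unname(DESeq2::estimateSizeFactorsForMatrix(rnd)),
               tolerance = 1e-10)
})

test_that("size factors are scale-equivariant and normalization is idempotent", {
  # scaling one column by c scales its factor by c relative to the others
  # (factors are defined up to the geometric-mean reference, so the
  # invariance is on ratios)
  rnd <- randomCounts(300, 4, seed = 3) + 1L  # all-positive: eligibility fixed
  sf <- estimateSizeFactorsMOR(rnd)
  scaled <- rnd
  scaled[, 2] <- scaled[, 2] * 3L
  sf2 <- estimateSizeFactorsMOR(scaled)
  rel <- sf2 / sf
  expect_equal(unname(rel[2] / rel[1]), 3, tolerance = 1e-12)
  expect_lt(diff(range(rel[-2])), 1e-12)

  # noiseless proportional data: re-estimating on normalized values -> 1
  base <- matrix(c(2, 4, 8, 100), 4, 1)
  prop <- cbind(s1 = base[, 1], s2 = 2 * base[, 1], s3 = 5 * base[, 1])
  rownames(prop) <- sprintf("g%d", 1:4)
  norm <- normalizeCounts(prop, estimateSizeFactorsMOR(prop))
  renorm <- apply(norm, 2, function(x) median(x / exp(rowMeans(log(norm)))))
  expect_equal(unname(renorm), rep(1, 3), tolerance = 1e-6)

  noCommon <- matrix(c(5L, 0L, 0L, 5L), 2, 2,
                     dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimateSizeFactorsMOR(noCommon), "fallbackPositiveGeomean")
  sparse <- matrix(c(5L, 0L, 0L, 6L, 8L, 0L), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_length(estimateSizeFactorsMOR(sparse, fallbackPositiveGeomean = TRUE), 2)
})

test_that("normalization divides by size factors and preserves names", {
  m <- matrix(c(1L, 4L), 1, 2, dimnames = list("g", c("s1", "s2")))
  expect_equal(unname(normalizeCounts(m, c(s1 = 0.5, s2 = 2))),
               matrix(c(2, 2), 1, 2))
  rnd <- randomCounts(100, 3, seed = 5)
  expect_identical(normalizeCounts(rnd, rep(1, 3)), rnd * 1)
  expect_identical(dimnames(normalizeCounts(rnd)), dimnames(rnd))

  # columns inflated by known factors are re-equalized up to NB noise
  sc <- bulkScenario(nGenes = 2000, groups = c(A = 3L), refGroup = "A",
                     libSizeFactors = c(1, 2, 4), seed = 6)
  cnt <- SummarizedExperiment::assay(simulateBulkCounts(sc))
  cs <- colSums(normalizeCounts(cnt))
  expect_lt(max(cs) / min(cs), 1.05)
})

test_that("the NB Wald test is symmetric, null-calibrated at the gene level, and guards its inputs", {
  sc <- bulkScenario(nGenes = 500, groups = c(A = 3L, B = 3L), refGroup = "A",
                     dispersion = 0.05, seed = 13)
  se <- simulateBulkCounts(sc)
  ab <- runDE(se, ref = "A", alt = "B")
  ba <- runDE(se, ref = "B", alt = "A")
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$stat, -ba$stat, tolerance = 1e-12)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-12)

  # identical normalized group means: log2fc = 0, stat = 0, p = 1
  m <- cbind(A1 = c(10L, 50L), A2 = c(12L, 48L), B1 = c(10L, 50L),
             B2 = c(12L, 48L))
  rownames(m) <- c("g1", "g2")
  cond <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  res <- runDE(m, cond, ref = "A", alt = "B",
               config = deConfig(minTotalCount = 0))
  expect_equal(unname(res$log2fc), c(0, 0))
  expect_equal(unname(res$stat), c(0, 0))
  expect_equal(unname(res$pvalue), c(1, 1))

  expect_error(runDE(m[, 1:3], cond[1:3], ref = "A", alt = "B"),
               ">= 2 samples")

  # an all-zero knockout gene yields a large finite fold change, flagged
  ko <- rbind(m, RET = c(400L, 380L, 0L, 0L))
  resKo <- runDE(ko, cond, ref = "A", alt = "B",
                 config = deConfig(minTotalCount = 0))
  expect_true(is.finite(resKo["RET", "log2fc"]))
  expect_lt(resKo["RET", "log2fc"], -5)
  expect_true(resKo["RET", "zeroInGroup"])
})

test_that("BH adjustment matches the step-up definition and rejects bad input", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjaminiHochberg(0.73), 0.73)
  expect_error(benjaminiHochberg(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(benjaminiHochberg(c(0.2, NA)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(benjaminiHochberg(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("DE calls use strict thresholds and clone intersection follows set algebra", {
  tab <- S4Vectors::DataFrame(gene = c("at", "above", "below"),
                              log2fc = c(2.0, 2.01, 1.99),
                              padj = c(1e-6, 1e-6, 1e-6))
  calls <- callDEGenes(tab)
  expect_identical(calls$up, "above")
  empty <- callDEGenes(tab[0, ])
  expect_identical(empty, list(up = character(), down = character()))

  same <- list(a = list(up = c("x", "y"), down = "z"),
               b = list(up = c("x", "y"), down = "z"))
  expect_setequal(intersectDEAcrossClones(same)$up, c("x", "y"))
  disjoint <- list(a = list(up = "x", down = character()),
                   b = list(up = "y", down = character()))
  expect_length(intersectDEAcrossClones(disjoint)$up, 0)

  set.seed(2)
  genes <- sprintf("g%02d", 1:40)
  lists <- lapply(setNames(1:4, paste0("c", 1:4)), function(i)
    list(up = sample(genes, 15), down = sample(genes, 10)))
  out <- intersectDEAcrossClones(lists)
  expect_setequal(out$up, Reduce(intersect, lapply(lists, `[[`, "up")))
  upRegions <- out$regions[out$regions$direction == "up", ]
  expect_equal(sum(upRegions$count),
               length(unique(unlist(lapply(lists, `[[`, "up")))))
  expect_error(intersectDEAcrossClones(lists[1]), ">= 2")
})

test_that("planted fold changes shared by five knockout clones survive the intersection", {
  sc <- defaultBulkScenario(seed = 17)
  se <- simulateBulkCounts(sc)
  cond <- setNames(SummarizedExperiment::colData(se)$condition, colnames(se))
  calls <- lapply(setNames(koClones, koClones), function(cl)
    callDEGenes(runDE(se, cond, ref = "parental", alt = cl)))
  common <- intersectDEAcrossClones(calls)
  mes <- sprintf("MES%03d", 1:50)
  expect_gte(length(intersect(common$up, mes)), 45)
})
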