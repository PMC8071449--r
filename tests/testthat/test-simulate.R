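test_that("bulk simulation is reproducible and matches its generative means", {
  sc <- defaultBulkScenario(seed = 11)
  se1 <- simulateBulkCounts(sc)
  se2 <- simulateBulkCounts(sc)
  expect_identical(SummarizedExperiment::assay(se1),
                   SummarizedExperiment::assay(se2))

  # written files are byte-for-byte identical across regenerations
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  writeCountMatrix(SummarizedExperiment::assay(se1), f1)
  writeCountMatrix(SummarizedExperiment::assay(se2), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # null design: per-gene sample means sit within 3 theoretical SEs of 2^b
  null <- bulkScenario(nGenes = 300, groups = c(A = 20L), refGroup = "A",
                       dispersion = 0.05, seed = 3)
  seN <- simulateBulkCounts(null)
  mu <- 2^SummarizedExperiment::rowData(seN)$baselineLog2
  m <- rowMeans(SummarizedExperiment::assay(seN))
  se3 <- 3 * sqrt((mu + 0.05 * mu^2) / 20)
  expect_gt(mean(abs(m - mu) <= se3), 0.95)
})

test_that("knockout programs force zeros and planted fold changes are recovered", {
  sc <- defaultBulkScenario(seed = 5)
  se <- simulateBulkCounts(sc)
  cnt <- SummarizedExperiment::assay(se)
  cond <- SummarizedExperiment::colData(se)$condition
  expect_true(all(cnt["RETL", cond %in% koClones] == 0))
  expect_true(all(cnt["RETL", cond == "parental"] > 0))

  # planted Delta = +3: median empirical log2 ratio of normalized group
  # means over the planted genes within +-0.3 of 3, across 10 seeds
  meds <- vapply(1:10, function(s) {
    sc <- bulkScenario(
      nGenes = 1000, groups = c(A = 2L, B = 2L), refGroup = "A",
      dispersion = 0.05, seed = s,
      programs = list(plantedProgram("up", sprintf("P%03d", 1:200),
                                     c(B = 3))))
    se <- simulateBulkCounts(sc)
    nc <- normalizeCounts(SummarizedExperiment::assay(se))
    cond <- SummarizedExperiment::colData(se)$condition
    ratio <- log2(rowMeans(nc[1:200, cond == "B"]) /
                  rowMeans(nc[1:200, cond == "A"]))
    median(ratio)
  }, numeric(1))
  expect_true(all(abs(meds - 3) <= 0.3))
})

test_that("simulated counts follow the var = mu + alpha mu^2 dispersion model", {
  sc <- bulkScenario(nGenes = 200, groups = c(A = 1000L), refGroup = "A",
                     baselineLog2Range = c(4, 8), dispersion = 0.1, seed = 9)
  se <- simulateBulkCounts(sc)
  cnt <- SummarizedExperiment::assay(se)
  m <- rowMeans(cnt)
  v <- apply(cnt, 1, var)
  expected <- m + 0.1 * m^2
  expect_gt(mean(v / expected > 0.8 & v / expected < 1.25), 0.95)
})

test_that("truth table is exhaustive and conflicting programs are rejected", {
  sc <- defaultBulkScenario(seed = 2)
  truth <- S4Vectors::metadata(simulateBulkCounts(sc))$truth
  # every planted (gene, group) with Delta != 0 appears exactly once
  expect_false(anyDuplicated(paste(truth$gene, truth$group)) > 0)
  mesRows <- truth[truth$gene == "MES001", ]
  expect_setequal(mesRows$group, c(koClones, "C1"))
  expect_equal(truth$log2fc[truth$gene == "RETL" & truth$group == "C2"], -Inf)
  nPlanted <- sum(vapply(sc@programs, function(p)
    length(p@genes) * length(p@log2fcByGroup), numeric(1)))
  expect_equal(nrow(truth), nPlanted)

  clash <- bulkScenario(
    nGenes = 100, groups = c(A = 2L, B = 2L), refGroup = "A", seed = 1,
    programs = list(plantedProgram("p1", "X1", c(B = 2)),
                    plantedProgram("p2", "X1", c(B = -2))))
  expect_error(simulateBulkCounts(clash), "conflicting log2 fold changes")
})

test_that("single-cell exclusivity genes follow their Bernoulli on/off model", {
  # degenerate probabilities: always-on gene positive, always-off gene zero
  pops <- data.frame(label = c("SCP", "bridge"), nCells = c(40L, 40L),
                     devOrder = 1:2)
  sc <- scRefScenario(
    nGenes = 120, populations = pops,
    exclusivityPairs = list(list(
      geneA = "A", geneB = "B",
      pOnA = c(SCP = 1, bridge = 0.5), pOnB = c(SCP = 0, bridge = 0.5))),
    seed = 4)
  sce <- simulateScReference(sc)
  cnt <- SummarizedExperiment::assay(sce)
  scp <- SummarizedExperiment::colData(sce)$cell_type == "SCP"
  expect_true(all(cnt["A", scp] > 0))
  expect_true(all(cnt["B", scp] == 0))

  # default scenario: SCP on-fraction of the RET-like gene within the
  # 99% binomial interval of 0.17
  sce2 <- simulateScReference(defaultScScenario(seed = 21))
  cnt2 <- SummarizedExperiment::assay(sce2)
  scp2 <- SummarizedExperiment::colData(sce2)$cell_type == "SCP"
  nOn <- sum(cnt2["RETL", scp2] > 0)
  expect_gte(nOn, qbinom(0.005, sum(scp2), 0.17))
  expect_lte(nOn, qbinom(0.995, sum(scp2), 0.17))

  expect_error(scRefScenario(
    nGenes = 120,
    populations = data.frame(label = "medulla", nCells = 30L, devOrder = 1L)),
    "unknown cell-type")
})

test_that("populations with identical parameters differ only by sampling noise", {
  pops <- data.frame(label = c("SCP", "bridge"), nCells = c(30L, 30L),
                     devOrder = 1:2)
  sce <- simulateScReference(
    scRefScenario(nGenes = 300, populations = pops, seed = 8))
  cnt <- SummarizedExperiment::assay(sce)
  ty <- SummarizedExperiment::colData(sce)$cell_type
  p <- apply(cnt, 1, function(x) t.test(x[ty == "SCP"], x[ty == "bridge"])$p.value)
  expect_gte(mean(p.adjust(p, "BH") > 0.05), 0.95)
})
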