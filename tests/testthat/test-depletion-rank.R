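test_that("normalization matches the stated reads-per-million formula", {
  m <- matrix(c(100L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  norm <- normalizeCounts(m, pseudocount = 0.5)
  expect_equal(unname(norm[, 1]), c(100.5, 0.5) / 101 * 1e6,
               tolerance = 1e-12)
  # single-shRNA column normalizes to 1e6 whatever the count
  one <- matrix(7L, 1, 1, dimnames = list("a", "s1"))
  expect_equal(unname(normalizeCounts(one)[1, 1]), 1e6)
  # pseudocount 0 on strictly positive counts is plain RPM
  pos <- matrix(c(2L, 8L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(normalizeCounts(pos, 0)[, 1]), c(0.2, 0.8) * 1e6)
  # every column sums to 1e6
  lib <- smallLibrary()
  eff <- plantEffects(lib, 0.1, seed = 61)
  sim <- simulateScreen(lib, eff, settings = "untreated", coverage = 100,
                        seed = 62)
  norm2 <- normalizeCounts(counts(sim$se))
  expect_equal(unname(colSums(norm2)), rep(1e6, 4), tolerance = 1e-6)
  # an all-zero column is a validation error naming the sample
  zero <- matrix(c(1L, 0L, 0L, 0L), 2,
                 dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(normalizeCounts(zero), "empty")
})

test_that("fold changes are depletion-oriented and depth-invariant", {
  m <- matrix(c(100L, 50L, 100L, 0L), 2,
              dimnames = list(c("a", "b"), c("base", "follow")))
  norm <- normalizeCounts(m, pseudocount = 0.5)
  fc <- foldChanges(norm, "base", "follow")
  # b drops 50 -> 0; pseudocounted column sums are 151 and 101
  expect_equal(fc$fc_depletion[fc$shrna_id == "b"],
               (50.5 / 151) / (0.5 / 101), tolerance = 1e-12)
  # identical columns give fc 1 everywhere
  twin <- matrix(c(100L, 50L, 100L, 50L), 2,
                 dimnames = list(c("a", "b"), c("d0", "d9")))
  same <- foldChanges(normalizeCounts(twin, 0.5), "d0", "d9")
  expect_equal(same$fc_depletion, rep(1, 2), tolerance = 1e-12)
  # doubling follow-up depth leaves fold changes unchanged (pseudocount 0)
  pos <- matrix(c(10L, 90L, 40L, 60L), 2,
                dimnames = list(c("a", "b"), c("base", "follow")))
  doubled <- pos
  doubled[, "follow"] <- doubled[, "follow"] * 2L
  fc1 <- foldChanges(normalizeCounts(pos, 0), "base", "follow")
  fc2 <- foldChanges(normalizeCounts(doubled, 0), "base", "follow")
  expect_equal(fc1$fc_depletion, fc2$fc_depletion, tolerance = 1e-12)
  expect_error(foldChanges(norm, "base", "nope"), "unknown sample")
})

test_that("a fully depleted shRNA at equal depths gives fc 201", {
  # 100 baseline reads, 0 follow-up reads, pseudocount 0.5, depths equal
  m <- matrix(c(100L, 100L, 0L, 200L), 2,
              dimnames = list(c("hit", "ref"), c("base", "follow")))
  fc <- foldChanges(normalizeCounts(m, 0.5), "base", "follow")
  # depth factors: baseline 201, follow-up 201 -> they cancel
  expect_equal(fc$fc_depletion[fc$shrna_id == "hit"], 100.5 / 0.5,
               tolerance = 1e-12)
})

test_that("the second-best statistic matches a brute-force oracle", {
  # hand example first
  fc <- S4Vectors::DataFrame(shrna_id = paste0("sh", 1:5),
                             gene_symbol = rep("G1", 5),
                             fc_depletion = c(8, 3, 2, 1.1, 0.9))
  rk <- rankGenesSecondBest(fc)
  expect_equal(rk$score, 3)
  # two genes rank by descending score
  fc2 <- S4Vectors::DataFrame(
    shrna_id = paste0("sh", 1:4),
    gene_symbol = c("A", "A", "B", "B"),
    fc_depletion = c(5, 4, 2, 1))
  rk2 <- rankGenesSecondBest(fc2)
  expect_identical(rk2$gene_symbol, c("A", "B"))
  expect_identical(rk2$rank, 1:2)
  expect_equal(rk2$score, c(4, 1))
  # random fixtures against an independent per-gene sort
  set.seed(71)
  for (trial in 1:25) {
    genes <- sprintf("g%03d", 1:100)
    nPer <- sample(5:6, 100, replace = TRUE)
    gene <- rep(genes, nPer)
    v <- rlnorm(length(gene), 0, 1.5)
    tab <- S4Vectors::DataFrame(shrna_id = sprintf("s%04d", seq_along(gene)),
                                gene_symbol = gene, fc_depletion = v)
    rk <- rankGenesSecondBest(tab)
    oracle <- vapply(genes, function(g) {
      sort(v[gene == g], decreasing = TRUE)[2]
    }, numeric(1))
    expect_equal(setNames(rk$score, rk$gene_symbol)[genes], oracle,
                 tolerance = 1e-12)
    expect_identical(sort(rk$rank), 1:100)
  }
})

test_that("gene-score ties break lexicographically and are flagged", {
  fc <- S4Vectors::DataFrame(
    shrna_id = paste0("sh", 1:6),
    gene_symbol = c("ZZZ", "ZZZ", "AAA", "AAA", "MMM", "MMM"),
    fc_depletion = c(9, 4, 9, 4, 9, 2))
  rk <- rankGenesSecondBest(fc)
  expect_identical(rk$gene_symbol, c("AAA", "ZZZ", "MMM"))
  expect_identical(rk$tie, c(TRUE, TRUE, FALSE))
})

test_that("genes with fewer than two measured shRNAs are rejected", {
  fc <- S4Vectors::DataFrame(shrna_id = c("a", "b", "c"),
                             gene_symbol = c("G1", "G1", "G2"),
                             fc_depletion = c(2, 1, 5))
  expect_error(rankGenesSecondBest(fc), "G2")
})

test_that("auxiliary targets are excluded from ranking when a design is given", {
  lib <- generateLibrary(4, 33, barcodeLength = 8,
                         nReliableShrnas = 22L, seed = 81)
  fcv <- seq_len(length(lib))
  fc <- S4Vectors::DataFrame(shrna_id = shrnaIds(lib),
                             fc_depletion = as.numeric(fcv))
  rk <- rankGenesSecondBest(fc, design = lib)
  expect_identical(nrow(rk), 4L)
  expect_false(any(grepl("^AUX", rk$gene_symbol)))
})

test_that("replicate concordance identities hold", {
  fc1 <- S4Vectors::DataFrame(shrna_id = sprintf("s%d", 1:50),
                              fc_depletion = exp(rnorm(50)))
  fc2 <- fc1
  cc <- replicateConcordance(fc1, fc2)
  expect_equal(cc$spearman, 1)
  expect_equal(cc$pearson_on_log, 1)
  inv <- S4Vectors::DataFrame(shrna_id = fc1$shrna_id,
                              fc_depletion = 1 / fc1$fc_depletion)
  cc2 <- replicateConcordance(fc1, inv)
  expect_equal(cc2$spearman, -1)
  expect_equal(cc2$pearson_on_log, -1)
  tiny <- fc1[1:2, ]
  expect_error(replicateConcordance(tiny, tiny), "fewer than 3")
})

test_that("top-fraction sets take the ceiling of the requested slice", {
  rk <- S4Vectors::DataFrame(gene_symbol = sprintf("g%04d", 1:4974),
                             score = rev(seq_len(4974)),
                             rank = seq_len(4974))
  expect_length(topGeneSet(rk, 0.01), 50L)  # ceiling(49.74)
  expect_length(topGeneSet(rk, 1), 4974L)
  small <- rk[1:100, ]
  expect_length(topGeneSet(small, 0.01), 1L)
  expect_error(topGeneSet(rk, 0), "fraction")
})

test_that("condition-specific set algebra is intersection minus union", {
  expect_identical(
    conditionSpecificGenes(list(c("A", "B", "C"), c("B", "C", "D")),
                           list("C")),
    "B")
  expect_identical(
    conditionSpecificGenes(list(c("A", "B")), list(c("A", "B"))),
    character(0))
})

test_that("recovery metrics match the planted truth definitions", {
  rk <- S4Vectors::DataFrame(gene_symbol = sprintf("g%02d", 1:20),
                             score = rev(seq_len(20)),
                             rank = seq_len(20))
  planted <- c("g01", "g02", "g03")
  res <- recoveryMetrics(rk, planted, topFraction = 0.2)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$precision, 3 / 4)
  # sensitivity is non-decreasing in the top fraction
  sens <- vapply(c(0.05, 0.15, 0.5, 1),
                 function(f) recoveryMetrics(rk, planted, f)$sensitivity,
                 numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_error(recoveryMetrics(rk, character(0), 0.1), "empty")
})

test_that("neutral scores are exchangeable under a null screen", {
  lib <- generateLibrary(150, 760, barcodeLength = 10, seed = 91)
  eff <- plantEffects(lib, fractionEssential = 0, seed = 92)
  sim <- simulateScreen(lib, eff, settings = "untreated", replicates = 1,
                        coverage = 300, seed = 93)
  seN <- normalizeCounts(sim$se)
  fc <- foldChanges(seN, "rep1_baseline", "rep1_untreated", design = lib)
  rk <- rankGenesSecondBest(fc, design = lib)
  # a random split of genes shows no score difference (rank-sum, alpha 0.01)
  set.seed(94)
  grp <- sample(c(TRUE, FALSE), nrow(rk), replace = TRUE)
  p <- wilcox.test(rk$score[grp], rk$score[!grp])$p.value
  expect_gt(p, 0.01)
})
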