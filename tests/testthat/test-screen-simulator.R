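test_that("plantEffects plants the exact gene and shRNA counts", {
  lib <- generateLibrary(100, 510, barcodeLength = 10, seed = 11)
  eff <- plantEffects(lib, fractionEssential = 0.05, seed = 11)
  expect_length(essentialGenes(eff), 5L)  # floor(0.05 * 100)
  for (g in essentialGenes(eff)) {
    sg <- eff@s[eff@geneSymbol == g]
    expect_identical(sum(sg > 0), as.integer(ceiling(0.8 * length(sg))))
  }
  neutral <- setdiff(unique(geneSymbols(lib)[isReliable(lib)]),
                     essentialGenes(eff))
  expect_true(all(eff@s[eff@geneSymbol %in% neutral] == 0))
})

test_that("a zero essential fraction yields an all-zero effect map", {
  lib <- smallLibrary()
  eff <- plantEffects(lib, fractionEssential = 0, backgroundSd = 0,
                      seed = 1)
  expect_true(all(eff@s == 0))
  expect_true(all(eff@background == 0))
  expect_length(essentialGenes(eff), 0L)
})

test_that("condition-specific essentials take labels from the conditions", {
  lib <- smallLibrary()
  eff <- plantEffects(lib, fractionEssential = 0.5,
                      fractionConditionSpecific = 0.4,
                      conditions = "cm", seed = 3)
  lab <- eff@geneLabel
  expect_identical(sum(lab == "essential_condition:cm"), 4L)  # floor(0.4*10)
  expect_identical(sum(lab == "essential_all"), 6L)
  expect_error(plantEffects(lib, 0.5, 0.4, conditions = character(0)),
               "conditions")
})

test_that("baseline profiles are complete, normalized and seed-independent", {
  lib <- smallLibrary()
  p1 <- simulateBaseline(lib, dispersion = 0.5, seed = 2)
  expect_equal(sum(abundances(p1)), 1, tolerance = 1e-12)
  expect_true(all(abundances(p1) > 0))
  expect_identical(p1@day, 0)
  # dispersion -> 0 approaches the uniform profile
  pu <- simulateBaseline(lib, dispersion = 1e-4, seed = 2)
  expect_lt(max(abundances(pu)) / min(abundances(pu)), 1.2)
  # different seeds give uncorrelated skews on a larger library
  big <- generateLibrary(200, 1000, barcodeLength = 10, seed = 4)
  rs <- vapply(1:10, function(i) {
    a <- abundances(simulateBaseline(big, seed = i))
    b <- abundances(simulateBaseline(big, seed = i + 100))
    cor(a, b, method = "spearman")
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.12)
})

test_that("selection depletes exponentially and renormalizes", {
  lib <- ShrnaLibrary(data.frame(
    shrna_id = paste0("g1_sh", 1:5), gene_symbol = "G1",
    barcode = c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT"),
    reliable_flag = TRUE))
  # hand-built effects: sh1 carries s = ln 2, others nothing
  eff <- new("EffectMap", shrnaId = shrnaIds(lib),
             geneSymbol = geneSymbols(lib),
             s = c(log(2), rep(0, 4)), background = rep(0, 5),
             geneLabel = c(G1 = "essential_all"), effectiveFraction = 0.2)
  uniform <- new("AbundanceProfile",
                 abundance = setNames(rep(0.2, 5), shrnaIds(lib)),
                 day = 0, condition = "baseline")
  # two-shRNA hand computation: exp(-ln2) halves sh1, then renormalize
  two <- new("AbundanceProfile",
             abundance = setNames(c(0.5, 0.5), c("g1_sh1", "g1_sh2")),
             day = 0, condition = "baseline")
  effTwo <- new("EffectMap", shrnaId = c("g1_sh1", "g1_sh2"),
                geneSymbol = c("G1", "G1"), s = c(log(2), 0),
                background = c(0, 0), geneLabel = c(G1 = "essential_all"),
                effectiveFraction = 0.5)
  out <- applySelection(two, effTwo, days = 1, condition = "any")
  expect_equal(unname(abundances(out)), c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_identical(out@day, 1)

  # all-zero effects leave the profile unchanged
  effNull <- new("EffectMap", shrnaId = shrnaIds(lib),
                 geneSymbol = geneSymbols(lib), s = rep(0, 5),
                 background = rep(0, 5), geneLabel = c(G1 = "neutral"),
                 effectiveFraction = 0)
  same <- applySelection(uniform, effNull, days = 9, condition = "x")
  expect_equal(abundances(same), abundances(uniform), tolerance = 1e-12)

  # condition-specific effects are gated on the matching condition
  effCond <- new("EffectMap", shrnaId = shrnaIds(lib),
                 geneSymbol = geneSymbols(lib),
                 s = c(1, rep(0, 4)), background = rep(0, 5),
                 geneLabel = c(G1 = "essential_condition:cm"),
                 effectiveFraction = 0.2)
  other <- applySelection(uniform, effCond, days = 9, condition = "plain")
  expect_equal(abundances(other), abundances(uniform), tolerance = 1e-12)
  gated <- applySelection(uniform, effCond, days = 9, condition = "cm")
  expect_lt(abundances(gated)[["g1_sh1"]], 0.2)
})

test_that("longer selection monotonically depletes affected shRNAs", {
  lib <- smallLibrary()
  eff <- plantEffects(lib, fractionEssential = 0.2, backgroundSd = 0,
                      seed = 5)
  prof <- simulateBaseline(lib, seed = 6)
  hit <- which(eff@s > 0)[1]
  rel <- vapply(c(1, 3, 6, 9), function(d) {
    abundances(applySelection(prof, eff, d, "x"))[hit]
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_equal(sum(abundances(applySelection(prof, eff, 9, "x"))), 1,
               tolerance = 1e-12)
})

test_that("emitFastq writes exact reads at zero error rate", {
  lib <- smallLibrary()
  prof <- simulateBaseline(lib, seed = 7)
  path <- withr::local_tempfile(fileext = ".fastq")
  em <- emitFastq(prof, lib, 500, path, errorRate = 0, seed = 8)
  lines <- readLines(path)
  expect_length(lines, 2000L)
  seqs <- lines[seq(2, 2000, 4)]
  bcs <- substr(seqs, 21, 32)
  expect_true(all(bcs %in% barcodes(lib)))
  expect_identical(sum(em$truth), 500L)
  tab <- table(factor(bcs, levels = barcodes(lib)))
  expect_identical(as.integer(tab), unname(as.integer(em$truth)))
})

test_that("emitFastq handles zero reads and is byte-deterministic", {
  lib <- smallLibrary()
  prof <- simulateBaseline(lib, seed = 7)
  empty <- withr::local_tempfile(fileext = ".fastq")
  emitFastq(prof, lib, 0, empty, seed = 1)
  expect_identical(readLines(empty), character(0))
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  emitFastq(prof, lib, 2000, p1, errorRate = 0.01, seed = 9)
  emitFastq(prof, lib, 2000, p2, errorRate = 0.01, seed = 9)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("the injected substitution rate matches the binomial expectation", {
  # P(>=1 barcode error) = 1 - (1-e)^len; check on the barcode region
  lib <- generateLibrary(40, 200, barcodeLength = 18, seed = 21)
  prof <- simulateBaseline(lib, seed = 22)
  path <- withr::local_tempfile(fileext = ".fastq")
  em <- emitFastq(prof, lib, 50000, path, errorRate = 0.01, seed = 23)
  idx <- buildBarcodeIndex(lib, maxMismatch = 0)
  q <- quantifyFastq(path, idx)
  observed <- 1 - q$qc$assigned_reads / q$qc$total_reads
  expect_equal(observed, 1 - 0.99^18, tolerance = 0.015)
})

test_that("simulateScreen lays out replicates, arms and metadata", {
  lib <- smallLibrary()
  eff <- plantEffects(lib, 0.1, seed = 12)
  sim <- simulateScreen(lib, eff, settings = "untreated", replicates = 2,
                        coverage = 100, seed = 13)
  expect_identical(nrow(sim$samples), 4L)  # 2 baselines + 2 follow-ups
  expect_identical(sum(sim$samples$condition == "baseline"), 2L)
  te <- sim$samples$transduction_efficiency
  expect_true(all(te >= 0.10 & te <= 0.40))
  # baselines are shared within a replicate, independent across replicates
  expect_identical(sim$profiles$rep1_baseline@day, 0)
  expect_false(identical(abundances(sim$profiles$rep1_baseline),
                         abundances(sim$profiles$rep2_baseline)))
  # counts-mode output carries a valid ScreenExperiment
  expect_s4_class(sim$se, "ScreenExperiment")
  expect_identical(dim(counts(sim$se)), c(105L, 4L))
  # same seed reproduces everything including the sampled counts
  sim2 <- simulateScreen(lib, eff, settings = "untreated", replicates = 2,
                         coverage = 100, seed = 13)
  expect_identical(counts(sim$se), counts(sim2$se))
})

test_that("sample sheets round-trip through TSV", {
  lib <- smallLibrary()
  eff <- plantEffects(lib, 0.1, seed = 14)
  sim <- simulateScreen(lib, eff, settings = "untreated", coverage = 50,
                        seed = 15)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSampleSheet(sim$samples, path)
  back <- readSampleSheet(path)
  expect_identical(back$sample_id, sim$samples$sample_id)
  expect_identical(back$condition, sim$samples$condition)
  expect_equal(back$transduction_efficiency,
               sim$samples$transduction_efficiency, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tcondition", bad)
  expect_error(readSampleSheet(bad), "sample sheet")
})

test_that("planted essentials deplete relative to baseline in simulation", {
  lib <- generateLibrary(50, 260, barcodeLength = 10, seed = 31)
  eff <- plantEffects(lib, 0.1, seed = 32)
  sim <- simulateScreen(lib, eff, settings = "untreated", replicates = 1,
                        coverage = 300, seed = 33)
  essSh <- eff@s > 0
  base <- sim$truth$rep1_baseline
  post <- sim$truth$rep1_untreated
  ratio <- (post[essSh] + 0.5) / (base[essSh] + 0.5)
  expect_lt(mean(ratio), 0.5)
})
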