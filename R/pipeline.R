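#' Default run configuration for the simulate-quantify-rank pipeline
#'
#' Returns the full default configuration as a nested list; supply
#' overrides as a nested list (or a YAML file path in
#' [runScreenPipeline()]) and they are merged over these defaults.
#' Defaults mirror the screen protocol: 9-day selection, 500x coverage
#' within the mandated 200-1000x window, transduction-efficiency QC window
#' \[0.10, 0.40\], and top-1% hit calling.
#'
#' @param overrides Nested list of parameter overrides.
#' @return The merged configuration list.
#' @export
screenConfig <- function(overrides = list()) {
  defaults <- list(
    seed = 1L,
    library = list(n_reliable_genes = 1000L, n_total_shrnas = 5500L,
                   barcode_length = 18L),
    effects = list(fraction_essential = 0.05,
                   fraction_condition_specific = 0,
                   s_mean = 0.5, s_sd = 0.2,
                   effective_fraction = 0.8,
                   background_sd = 0.03),
    screen = list(settings = c("untreated", "ruxolitinib", "cm_ruxolitinib"),
                  replicates = 2L, days = 9, coverage = 500,
                  error_rate = 0.005, dispersion = 0.5,
                  te_range = c(0.10, 0.40), emit_reads = FALSE),
    quant = list(max_mismatch = 1L, barcode_offset = nchar(DEFAULT_FLANK5)),
    rank = list(pseudocount = 0.5, top_fraction = 0.01),
    qc = list(te_low = 0.10, te_high = 0.40))
  .mergeConfig(defaults, overrides)
}

.mergeConfig <- function(base, over) {
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      base[[k]] <- .mergeConfig(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

.logLine <- function(logPath, stage, ...) {
  kv <- c(...)
  msg <- paste0("stage=", stage,
                if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                                  collapse = " ")) else "")
  cat(msg, "\n", file = logPath, append = TRUE, sep = "")
}

#' Run the full dropout-screen pipeline on simulated data
#'
#' Orchestrates library generation, effect planting, screen simulation,
#' (optional FASTQ emission and) quantification, QC filtering,
#' normalization, per-experiment fold changes and gene ranking, replicate
#' concordance, per-setting top-set comparison, condition-specific gene
#' calling and truth-based recovery metrics.  All outputs are plain files
#' in `outDir` plus a JSON manifest with per-file checksums; re-running
#' with the same configuration reproduces identical outputs.
#'
#' @param config A nested override list (see [screenConfig()]) or a path to
#'   a YAML file of overrides.
#' @param outDir Output directory (created; existing files overwritten).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list with the run `manifest`, the `ranks` tables,
#'   the `comparison` report and the `qc` report.
#' @examples
#' \donttest{
#' run <- runScreenPipeline(list(library = list(n_reliable_genes = 50L,
#'                                              n_total_shrnas = 260L),
#'                               screen = list(coverage = 100)),
#'                          outDir = tempfile("run"))
#' names(run)
#' }
#' @export
runScreenPipeline <- function(config = list(), outDir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- screenConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) stop("a seed is mandatory", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  cat("", file = logPath)

  stage <- "config"
  result <- tryCatch({
    configPath <- file.path(outDir, "config.json")
    jsonlite::write_json(cfg, configPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    stage <- "library"
    lib <- generateLibrary(cfg$library$n_reliable_genes,
                           cfg$library$n_total_shrnas,
                           barcodeLength = cfg$library$barcode_length,
                           seed = cfg$seed)
    writeLibrary(lib, file.path(outDir, "library.tsv"))
    .logLine(logPath, "library", shrnas = length(lib))

    stage <- "effects"
    eff <- plantEffects(lib,
                        fractionEssential = cfg$effects$fraction_essential,
                        fractionConditionSpecific =
                          cfg$effects$fraction_condition_specific,
                        conditions = utils::tail(cfg$screen$settings, 1L),
                        sMean = cfg$effects$s_mean, sSd = cfg$effects$s_sd,
                        effectiveFraction = cfg$effects$effective_fraction,
                        backgroundSd = cfg$effects$background_sd,
                        seed = cfg$seed + 1L)
    .logLine(logPath, "effects",
             essential = length(essentialGenes(eff)))

    stage <- "simulate"
    sim <- simulateScreen(lib, eff,
                          settings = cfg$screen$settings,
                          replicates = cfg$screen$replicates,
                          days = cfg$screen$days,
                          coverage = cfg$screen$coverage,
                          errorRate = cfg$screen$error_rate,
                          dispersion = cfg$screen$dispersion,
                          teRange = cfg$screen$te_range,
                          emitReads = isTRUE(cfg$screen$emit_reads),
                          outDir = file.path(outDir, "fastq"),
                          seed = cfg$seed + 2L)
    writeSampleSheet(sim$samples, file.path(outDir, "sample_sheet.tsv"))
    .logLine(logPath, "simulate", samples = nrow(sim$samples))

    stage <- "quantify"
    qcPerSample <- list()
    if (isTRUE(cfg$screen$emit_reads)) {
      idx <- buildBarcodeIndex(lib, maxMismatch = cfg$quant$max_mismatch)
      quant <- lapply(sim$samples$sample_id, function(sid) {
        quantifyFastq(sim$samples[sid, "fastq_path"], idx,
                      barcodeOffset = cfg$quant$barcode_offset)
      })
      names(quant) <- sim$samples$sample_id
      qcPerSample <- lapply(quant, `[[`, "qc")
      se <- assembleCountMatrix(lapply(quant, `[[`, "counts"),
                                sim$samples, lib)
    } else {
      se <- sim$se
      qcPerSample <- lapply(sim$truth, function(ct) {
        list(total_reads = sum(ct), assigned_reads = sum(ct),
             ambiguous_reads = 0L, unassigned_reads = 0L,
             barcode_recovery = mean(ct > 0))
      })
    }
    cts <- counts(se)
    write.table(data.frame(shrna_id = rownames(cts), cts,
                           check.names = FALSE),
                file.path(outDir, "counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, eol = "\n")
    .logLine(logPath, "quantify", samples = ncol(se))

    stage <- "qc"
    qcRes <- qcFilterSamples(sim$samples, low = cfg$qc$te_low,
                             high = cfg$qc$te_high)
    qcReport <- list(per_sample = qcPerSample,
                     excluded = as.list(setNames(qcRes$excluded$reason,
                                                 qcRes$excluded$sample_id)))
    jsonlite::write_json(qcReport, file.path(outDir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    followups <- qcRes$retained[qcRes$retained$condition != "baseline", ,
                                drop = FALSE]
    if (nrow(followups) == 0L) {
      stop("all non-baseline samples excluded by transduction-efficiency ",
           "QC; see qc.json", call. = FALSE)
    }
    .logLine(logPath, "qc", retained = nrow(qcRes$retained),
             excluded = nrow(qcRes$excluded))

    stage <- "rank"
    seN <- normalizeCounts(se, pseudocount = cfg$rank$pseudocount)
    fcTables <- list()
    ranks <- list()
    topSets <- list()
    for (i in seq_len(nrow(followups))) {
      sid <- followups$sample_id[i]
      r <- followups$replicate[i]
      baseId <- sprintf("rep%d_baseline", r)
      fc <- foldChanges(seN, baseId, sid, design = lib)
      fcTables[[sid]] <- fc
      rk <- rankGenesSecondBest(fc, design = lib)
      ranks[[sid]] <- rk
      topSets[[sid]] <- topGeneSet(rk, cfg$rank$top_fraction)
      write.table(as.data.frame(fc),
                  file.path(outDir, sprintf("fold_changes_%s.tsv", sid)),
                  sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
      write.table(as.data.frame(rk),
                  file.path(outDir, sprintf("gene_ranks_%s.tsv", sid)),
                  sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    }
    .logLine(logPath, "rank", experiments = length(ranks))

    stage <- "compare"
    settings <- intersect(cfg$screen$settings, followups$condition)
    concord <- list()
    for (cond in settings) {
      sids <- followups$sample_id[followups$condition == cond]
      if (length(sids) >= 2L) {
        concord[[cond]] <- replicateConcordance(fcTables[[sids[1L]]],
                                                fcTables[[sids[2L]]])
      }
    }
    condSpecific <- character(0)
    target <- utils::tail(settings, 1L)
    if (length(settings) > 1L) {
      tgt <- topSets[followups$sample_id[followups$condition == target]]
      oth <- topSets[followups$sample_id[followups$condition != target]]
      if (length(tgt) && length(oth)) {
        condSpecific <- conditionSpecificGenes(tgt, oth)
      }
    }
    recovery <- NULL
    planted <- essentialGenes(eff)
    if (length(planted)) {
      recovery <- lapply(ranks, function(rk) {
        recoveryMetrics(rk, eff, topFraction = cfg$rank$top_fraction,
                        condition = target)
      })
    }
    comparison <- list(replicate_concordance = concord,
                       top_sets = topSets,
                       condition_specific_genes = condSpecific,
                       recovery = recovery)
    jsonlite::write_json(comparison, file.path(outDir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .logLine(logPath, "compare", settings = length(settings))

    stage <- "manifest"
    files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                          c("manifest.json", "run.log")))
    sums <- tools::md5sum(file.path(outDir, files))
    manifest <- list(package_version = as.character(packageVersion("dropscreen")),
                     seed = cfg$seed,
                     config_md5 = unname(tools::md5sum(configPath)),
                     files = as.list(setNames(unname(sums), files)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .logLine(logPath, "done")

    list(manifest = manifest, ranks = ranks, comparison = comparison,
         qc = qcReport)
  }, error = function(e) {
    .logLine(logPath, "error", at = stage)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Summarize a completed pipeline run
#'
#' Verifies the manifest checksums (a tampered or missing artifact is an
#' error) and assembles a human-readable summary: per-sample barcode
#' recovery, replicate concordance per setting, top gene sets, genes
#' specific to the target setting, and recovery metrics when simulation
#' truth was available.
#'
#' @param runDir A directory written by [runScreenPipeline()].
#' @return Invisibly, the summary as a character vector (also printed).
#' @export
screenReport <- function(runDir) {
  manifestPath <- file.path(runDir, "manifest.json")
  if (!file.exists(manifestPath)) {
    stop("incomplete run: missing manifest.json", call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifestPath)
  missing <- names(manifest$files)[!file.exists(file.path(runDir,
                                                names(manifest$files)))]
  if (length(missing)) {
    stop("incomplete run: missing artifact(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in names(manifest$files)) {
    actual <- unname(tools::md5sum(file.path(runDir, f)))
    if (!identical(actual, manifest$files[[f]])) {
      stop("checksum mismatch for ", f, call. = FALSE)
    }
  }
  qc <- jsonlite::read_json(file.path(runDir, "qc.json"))
  comp <- jsonlite::read_json(file.path(runDir, "comparison.json"))

  out <- c(sprintf("dropout screen run: %s (seed %s)", runDir,
                   manifest$seed),
           "barcode recovery per sample:")
  for (s in names(qc$per_sample)) {
    out <- c(out, sprintf("  %s: %.4f", s,
                          qc$per_sample[[s]]$barcode_recovery))
  }
  if (length(comp$replicate_concordance)) {
    out <- c(out, "replicate concordance (spearman / pearson on log2):")
    for (cond in names(comp$replicate_concordance)) {
      cc <- comp$replicate_concordance[[cond]]
      out <- c(out, sprintf("  %s: %.3f / %.3f", cond, cc$spearman,
                            cc$pearson_on_log))
    }
  }
  out <- c(out, sprintf("top-set sizes: %s",
                        paste(sprintf("%s=%d", names(comp$top_sets),
                                      lengths(comp$top_sets)),
                              collapse = ", ")))
  out <- c(out, sprintf("condition-specific genes: %s",
                        if (length(comp$condition_specific_genes))
                          paste(unlist(comp$condition_specific_genes),
                                collapse = ", ") else "(none)"))
  if (!is.null(comp$recovery) && length(comp$recovery)) {
    out <- c(out, "planted-essential recovery (sensitivity / precision):")
    for (s in names(comp$recovery)) {
      out <- c(out, sprintf("  %s: %.3f / %.3f", s,
                            comp$recovery[[s]]$sensitivity,
                            comp$recovery[[s]]$precision))
    }
  }
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
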