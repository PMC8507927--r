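# Default amplicon layout: fixed 5' flank, barcode, fixed 3' flank.  The
# quantifier locates the barcode by offset = nchar(flank5), so simulator and
# quantifier share one layout definition.
DEFAULT_FLANK5 <- "ACCGGTTAACTCGAGAAGGT"
DEFAULT_FLANK3 <- "TTTTTGAATTCTCGACCTCG"

#' Plant essentiality effects on a library
#'
#' Labels a seeded random subset of the reliable genes as essential -- a
#' sub-fraction of them essential only under a named condition -- and draws
#' a positive per-day depletion rate `s` (normal truncated at zero) for
#' `ceiling(effectiveFraction * n)` of each essential gene's shRNAs.  All
#' shRNAs additionally receive a small zero-mean `background` rate shared
#' across replicates, modelling construct-intrinsic burden; set
#' `backgroundSd = 0` for a perfectly clean null.
#'
#' @param design A [ShrnaLibrary-class].
#' @param fractionEssential Fraction of reliable genes planted as essential
#'   (`floor(fraction * nGenes)` genes).
#' @param fractionConditionSpecific Fraction of the essential genes (floor)
#'   whose effect is gated on one of `conditions`.
#' @param conditions Character vector of setting labels for
#'   condition-specific essentials (assigned round-robin); required when
#'   `fractionConditionSpecific > 0`.
#' @param sMean,sSd Mean and sd of the per-day depletion rate before
#'   truncation at zero (defaults 0.5 and 0.2).
#' @param effectiveFraction Fraction of an essential gene's shRNAs carrying
#'   its effect (default 0.8).
#' @param backgroundSd Sd of the per-day background rate (default 0.03).
#' @param seed Integer seed.
#' @return An [EffectMap-class].
#' @examples
#' lib <- generateLibrary(50, 250, barcodeLength = 10, seed = 1)
#' eff <- plantEffects(lib, fractionEssential = 0.1, seed = 2)
#' essentialGenes(eff)
#' @export
plantEffects <- function(design, fractionEssential = 0.05,
                         fractionConditionSpecific = 0,
                         conditions = character(0),
                         sMean = 0.5, sSd = 0.2,
                         effectiveFraction = 0.8,
                         backgroundSd = 0.03,
                         seed = 1L) {
  stopifnot(is(design, "ShrnaLibrary"))
  .assertFraction(fractionEssential, "fractionEssential")
  .assertFraction(fractionConditionSpecific, "fractionConditionSpecific")
  .assertFraction(effectiveFraction, "effectiveFraction")
  if (sMean <= 0) stop("sMean must be > 0", call. = FALSE)
  if (sSd < 0 || backgroundSd < 0) {
    stop("sSd and backgroundSd must be >= 0", call. = FALSE)
  }

  ids <- shrnaIds(design)
  gene <- geneSymbols(design)
  relGenes <- unique(gene[isReliable(design)])

  withSeed(seed, {
    nEss <- floor(fractionEssential * length(relGenes))
    essential <- if (nEss > 0L) sample(relGenes, nEss) else character(0)
    nCond <- floor(fractionConditionSpecific * nEss)
    if (nCond > 0L && length(conditions) == 0L) {
      stop("conditions must be supplied when planting condition-specific ",
           "essentials", call. = FALSE)
    }
    label <- setNames(rep("neutral", length(relGenes)), relGenes)
    if (nEss > 0L) label[essential] <- "essential_all"
    if (nCond > 0L) {
      condGenes <- essential[seq_len(nCond)]
      label[condGenes] <- paste0("essential_condition:",
                                 rep(conditions, length.out = nCond))
    }

    s <- numeric(length(ids))
    for (g in essential) {
      at <- which(gene == g)
      nEff <- ceiling(effectiveFraction * length(at))
      hit <- sample(at, nEff)
      s[hit] <- .truncNorm(nEff, sMean, sSd)
    }
    bg <- if (backgroundSd > 0) rnorm(length(ids), 0, backgroundSd)
          else numeric(length(ids))

    em <- new("EffectMap", shrnaId = ids, geneSymbol = gene, s = s,
              background = bg, geneLabel = label,
              effectiveFraction = effectiveFraction)
    validObject(em)
    em
  })
}

# Normal truncated at zero (rejection sampling; positive mean assumed).
.truncNorm <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- out <= 0
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  out[out <= 0] <- mean
  out
}

#' @rdname EffectMap-class
#' @export
setMethod("essentialGenes", "EffectMap", function(object, condition = NULL) {
  lab <- object@geneLabel
  keep <- lab == "essential_all"
  if (!is.null(condition)) {
    keep <- keep | lab == paste0("essential_condition:", condition)
  }
  names(lab)[keep]
})

setMethod("show", "EffectMap", function(object) {
  lab <- object@geneLabel
  cat(sprintf(paste0("EffectMap: %d shRNAs / %d genes; %d essential ",
                     "(%d condition-specific); effective fraction %.2f\n"),
              length(object@shrnaId), length(lab),
              sum(lab != "neutral"),
              sum(startsWith(lab, "essential_condition")),
              object@effectiveFraction))
})

#' Simulate baseline library representation
#'
#' Draws per-shRNA relative abundances from a symmetric Dirichlet with
#' concentration `1/dispersion`, modelling the uneven but complete
#' representation of a freshly transduced pool: every shRNA has positive
#' abundance, and small `dispersion` approaches the uniform profile.
#'
#' @param design A [ShrnaLibrary-class].
#' @param dispersion Positive dispersion of the baseline representation
#'   (default 0.5, a moderate library skew).
#' @param seed Integer seed.
#' @return An [AbundanceProfile-class] at day 0, condition `"baseline"`.
#' @export
simulateBaseline <- function(design, dispersion = 0.5, seed = 1L) {
  stopifnot(is(design, "ShrnaLibrary"))
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("dispersion must be > 0", call. = FALSE)
  }
  n <- length(design)
  withSeed(seed, {
    g <- rgamma(n, shape = 1 / dispersion, rate = 1)
    g[g <= 0] <- .Machine$double.xmin  # guard against underflow at tiny shape
    a <- g / sum(g)
    new("AbundanceProfile", abundance = setNames(a, shrnaIds(design)),
        day = 0, condition = "baseline")
  })
}

#' Apply selection to an abundance profile
#'
#' Each shRNA's abundance is multiplied by `exp(-rate * days)` and the
#' profile renormalized; `rate` is the background rate plus the planted
#' coefficient `s` when the gene's effect applies (label `essential_all`,
#' or `essential_condition:<cond>` matching `condition`).  The profile's
#' day advances by `days` and its condition is set to `condition`.
#'
#' @param profile An [AbundanceProfile-class].
#' @param effects An [EffectMap-class] over the same shRNAs.
#' @param days Positive selection duration in days (the screen design uses
#'   9).
#' @param condition Setting label of this culture arm.
#' @return The post-selection [AbundanceProfile-class].
#' @export
applySelection <- function(profile, effects, days, condition) {
  stopifnot(is(profile, "AbundanceProfile"), is(effects, "EffectMap"))
  if (!is.numeric(days) || days <= 0) stop("days must be > 0", call. = FALSE)
  a <- profile@abundance
  if (!identical(names(a), effects@shrnaId)) {
    stop("profile and effects index different shRNA sets", call. = FALSE)
  }
  lab <- effects@geneLabel[effects@geneSymbol]
  gate <- lab == "essential_all" |
    lab == paste0("essential_condition:", condition)
  gate[is.na(gate)] <- FALSE  # auxiliary targets carry no planted effect
  rate <- effects@background + ifelse(gate, effects@s, 0)
  w <- a * exp(-rate * days)
  new("AbundanceProfile", abundance = w / sum(w),
      day = profile@day + days, condition = as.character(condition))
}

setMethod("show", "AbundanceProfile", function(object) {
  cat(sprintf("AbundanceProfile: %d shRNAs, day %g, condition '%s'\n",
              length(object@abundance), object@day, object@condition))
})

#' @rdname AbundanceProfile-class
#' @export
setMethod("abundances", "AbundanceProfile", function(object) object@abundance)

#' Emit FASTQ reads from an abundance profile
#'
#' Draws `nReads` barcodes multinomially from the profile, embeds each as
#' `flank5 + barcode + flank3`, applies i.i.d. per-base substitution errors
#' at `errorRate` across the whole read, and writes a 4-line-record FASTQ
#' with constant quality `I` (Phred+33).  The returned ground-truth tally
#' records how many reads were drawn for each shRNA before errors.
#'
#' @param profile An [AbundanceProfile-class].
#' @param design The matching [ShrnaLibrary-class].
#' @param nReads Number of reads (>= 0).
#' @param path Output FASTQ path.
#' @param errorRate Per-base substitution probability in \[0, 0.2\]
#'   (default 0.005).
#' @param flank5,flank3 Fixed flanking sequences around the barcode.
#' @param seed Integer seed; output is byte-reproducible.
#' @return Invisibly, a list with `path`, `truth` (named integer tally of
#'   reads per shRNA) and `nReads`.
#' @export
emitFastq <- function(profile, design, nReads, path,
                      errorRate = 0.005,
                      flank5 = DEFAULT_FLANK5, flank3 = DEFAULT_FLANK3,
                      seed = 1L) {
  stopifnot(is(profile, "AbundanceProfile"), is(design, "ShrnaLibrary"))
  if (length(profile@abundance) == 0L) {
    stop("empty abundance profile", call. = FALSE)
  }
  .assertFraction(errorRate, "errorRate", 0, 0.2)
  nReads <- .assertCount(nReads, "nReads", min = 0L)

  res <- withSeed(seed, {
    counts <- as.vector(rmultinom(1, nReads, profile@abundance))
    truth <- setNames(as.integer(counts), names(profile@abundance))
    if (nReads == 0L) {
      writeLines(character(0), path)
      list(path = path, truth = truth, nReads = 0L)
    } else {
    bcOfRead <- rep(barcodes(design), times = counts)
    bcOfRead <- bcOfRead[sample.int(length(bcOfRead))]
    seqs <- paste0(flank5, bcOfRead, flank3)
    L <- nchar(seqs[1L])
    if (errorRate > 0) {
      nErr <- rbinom(1, as.double(nReads) * L, errorRate)
      if (nErr > 0) {
        pos <- sample(as.double(nReads) * L, nErr)
        i <- as.integer((pos - 1) %/% L) + 1L
        p <- as.integer((pos - 1) %% L) + 1L
        cur <- substring(seqs[i], p, p)
        shift <- sample.int(3L, nErr, replace = TRUE)
        newBase <- DNA_BASES[((match(cur, DNA_BASES) - 1L + shift) %% 4L) + 1L]
        # multiple errors can hit one read: apply one per read per pass
        rank <- stats::ave(seq_len(nErr), i, FUN = seq_along)
        for (k in seq_len(max(rank))) {
          sel <- rank == k
          x <- seqs[i[sel]]
          substr(x, p[sel], p[sel]) <- newBase[sel]
          seqs[i[sel]] <- x
        }
      }
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("read%d", seq_len(nReads))
    qual <- Biostrings::BStringSet(rep(strrep("I", L), nReads))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = qual)
    list(path = path, truth = truth, nReads = nReads)
    }
  })
  invisible(res)
}

#' Simulate a complete dropout screen
#'
#' For each replicate, draws an independent baseline pool (shared across
#' settings within the replicate, as when one third of a transduced culture
#' is frozen as control), applies `days` of selection per setting, and
#' sequences each sample.  Transduction efficiency is sampled uniformly in
#' `teRange` once per replicate and recorded as metadata (used only by QC
#' filtering).
#'
#' With `emitReads = TRUE` each sample is written as a FASTQ file under
#' `outDir` for [quantifyFastq()].  With the default counts mode,
#' sequencing is modelled directly: reads surviving barcode-intact
#' (probability `(1 - errorRate)^barcodeLength`) are drawn multinomially
#' from the abundance profile, skipping the FASTQ round trip.
#'
#' @param design A [ShrnaLibrary-class].
#' @param effects An [EffectMap-class] from [plantEffects()].
#' @param settings Character vector of selection-arm labels.
#' @param replicates Number of full experimental replicates (default 2).
#' @param days Selection period in days (default 9).
#' @param coverage Reads per library construct (default 500; the screen
#'   protocol calls for 200-1000x representation). `nReads` overrides.
#' @param nReads Reads per sample; default `coverage * length(design)`.
#' @param errorRate Per-base substitution probability (default 0.005).
#' @param dispersion Baseline representation dispersion
#'   (see [simulateBaseline()]).
#' @param teRange Interval for the uniform transduction-efficiency draw
#'   (default `c(0.10, 0.40)`).
#' @param emitReads Write FASTQ files instead of direct count sampling.
#' @param outDir Output directory for FASTQ files (required when
#'   `emitReads = TRUE`).
#' @param flank5,flank3 Read layout for FASTQ emission.
#' @param seed Integer seed governing the whole simulation.
#' @return A list with `samples` (a [S4Vectors::DataFrame] sample sheet:
#'   sample_id, condition, replicate, transduction_efficiency, fastq_path,
#'   day), `truth` (named list of per-sample ground-truth read tallies),
#'   `profiles` (named list of [AbundanceProfile-class]), and in counts
#'   mode `se`, a [ScreenExperiment-class] of the sampled counts.
#' @examples
#' lib <- generateLibrary(40, 200, barcodeLength = 10, seed = 1)
#' eff <- plantEffects(lib, 0.1, seed = 2)
#' sim <- simulateScreen(lib, eff, settings = "untreated", replicates = 2,
#'                       coverage = 100, seed = 3)
#' sim$samples
#' @export
simulateScreen <- function(design, effects,
                           settings = c("untreated", "ruxolitinib",
                                        "cm_ruxolitinib"),
                           replicates = 2L, days = 9, coverage = 500,
                           nReads = NULL, errorRate = 0.005,
                           dispersion = 0.5, teRange = c(0.10, 0.40),
                           emitReads = FALSE, outDir = NULL,
                           flank5 = DEFAULT_FLANK5, flank3 = DEFAULT_FLANK3,
                           seed = 1L) {
  stopifnot(is(design, "ShrnaLibrary"), is(effects, "EffectMap"))
  replicates <- .assertCount(replicates, "replicates")
  if (is.null(nReads)) nReads <- as.integer(round(coverage * length(design)))
  nReads <- .assertCount(nReads, "nReads")
  stopifnot(length(teRange) == 2L, teRange[1] <= teRange[2])
  if (emitReads) {
    if (is.null(outDir)) stop("outDir required when emitReads = TRUE",
                              call. = FALSE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  }

  pOk <- (1 - errorRate)^barcodeLength(design)
  samples <- list()
  truth <- list()
  profiles <- list()
  countsList <- list()

  withSeed(seed, {
    for (r in seq_len(replicates)) {
      te <- runif(1, teRange[1], teRange[2])
      base <- simulateBaseline(design, dispersion = dispersion, seed = NULL)
      arms <- c(list(baseline = base),
                setNames(lapply(settings, function(cond) {
                  applySelection(base, effects, days, cond)
                }), settings))
      for (arm in names(arms)) {
        sid <- sprintf("rep%d_%s", r, arm)
        prof <- arms[[arm]]
        profiles[[sid]] <- prof
        fq <- NA_character_
        if (emitReads) {
          fq <- file.path(outDir, paste0(sid, ".fastq"))
          em <- emitFastq(prof, design, nReads, fq, errorRate = errorRate,
                          flank5 = flank5, flank3 = flank3, seed = NULL)
          truth[[sid]] <- em$truth
        } else {
          nAssigned <- rbinom(1, nReads, pOk)
          cts <- as.vector(rmultinom(1, nAssigned, prof@abundance))
          cts <- setNames(as.integer(cts), shrnaIds(design))
          truth[[sid]] <- cts
          countsList[[sid]] <- cts
        }
        samples[[sid]] <- data.frame(
          sample_id = sid, condition = arm, replicate = r,
          transduction_efficiency = te, fastq_path = fq,
          day = prof@day, stringsAsFactors = FALSE)
      }
    }
  })

  sheet <- DataFrame(do.call(rbind, samples))
  rownames(sheet) <- sheet$sample_id
  out <- list(samples = sheet, truth = truth, profiles = profiles)
  if (!emitReads) {
    out$se <- assembleCountMatrix(countsList, sheet, design)
  }
  out
}

#' Write / read a sample sheet TSV
#'
#' Columns: sample_id, condition, replicate, transduction_efficiency,
#' fastq_path (and day when present).
#'
#' @param samples A data.frame or DataFrame of sample records.
#' @param path File path.
#' @return `readSampleSheet` returns a [S4Vectors::DataFrame];
#'   `writeSampleSheet` returns `path` invisibly.
#' @export
writeSampleSheet <- function(samples, path) {
  write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate", "transduction_efficiency")
  if (!all(need %in% colnames(df))) {
    stop("sample sheet must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- DataFrame(df)
  rownames(out) <- out$sample_id
  out
}
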