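#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ShrnaLibrary: the gene/shRNA/barcode catalogue
#'
#' Container for a pooled shRNA library design: one record per shRNA
#' construct giving its identifier, target gene, fixed-length DNA barcode
#' and whether the target is a "reliable" gene (screened and ranked) or an
#' auxiliary target (counted but never ranked).
#'
#' Validity requires all barcodes to be distinct, to use only A/C/G/T, and
#' to share the library-wide barcode length; every reliable gene must be
#' targeted by five or six shRNAs.
#'
#' @slot records A [S4Vectors::DataFrame] with columns `shrna_id`,
#'   `gene_symbol`, `barcode`, `reliable_flag`.
#' @slot barcodeLength Integer, barcode length in nucleotides.
#' @slot name Free-text library name.
#'
#' @seealso [generateLibrary()], [readLibrary()], [writeLibrary()]
#' @export
setClass("ShrnaLibrary",
         slots = c(records = "DataFrame",
                   barcodeLength = "integer",
                   name = "character"))

setValidity("ShrnaLibrary", function(object) {
  rec <- object@records
  need <- c("shrna_id", "gene_symbol", "barcode", "reliable_flag")
  if (!all(need %in% colnames(rec))) {
    return(paste("records must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(rec) == 0L) return(TRUE)
  if (!is.character(rec$shrna_id) || !is.character(rec$gene_symbol) ||
      !is.character(rec$barcode) || !is.logical(rec$reliable_flag)) {
    return("record columns have wrong types")
  }
  if (anyDuplicated(rec$shrna_id)) return("shrna_id values must be unique")
  dup <- rec$barcode[duplicated(rec$barcode)]
  if (length(dup)) {
    return(sprintf("duplicate barcode(s): %s",
                   paste(unique(dup)[seq_len(min(3, length(unique(dup))))],
                         collapse = ", ")))
  }
  if (any(nchar(rec$barcode) != object@barcodeLength)) {
    return(sprintf("all barcodes must have length %d", object@barcodeLength))
  }
  if (any(!grepl("^[ACGT]+$", rec$barcode))) {
    return("barcodes may contain only A, C, G, T")
  }
  tab <- table(rec$gene_symbol[rec$reliable_flag])
  bad <- names(tab)[tab < 5L | tab > 6L]
  if (length(bad)) {
    return(sprintf("reliable gene(s) with shRNA count outside 5-6: %s",
                   paste(head(bad, 3), collapse = ", ")))
  }
  TRUE
})

#' BarcodeIndex: lookup structure for barcode assignment
#'
#' Exact-lookup table over a library's barcodes, optionally augmented with a
#' precomputed Hamming-distance-1 neighborhood so single-substitution reads
#' can be rescued.  A neighbor sequence reachable from two different
#' barcodes is stored as ambiguous and never assigned.
#'
#' @slot barcodes Character vector of library barcodes (design order).
#' @slot shrnaIds Parallel shRNA identifiers.
#' @slot neighborLookup Named integer vector mapping distance-1 sequences to
#'   the 1-based barcode index, with 0 marking ambiguous sequences. Empty
#'   when `maxMismatch` is 0.
#' @slot maxMismatch 0 or 1.
#' @slot barcodeLength Barcode length in nucleotides.
#'
#' @seealso [buildBarcodeIndex()], [quantifyFastq()]
#' @export
setClass("BarcodeIndex",
         slots = c(barcodes = "character",
                   shrnaIds = "character",
                   neighborLookup = "integer",
                   maxMismatch = "integer",
                   barcodeLength = "integer"))

#' EffectMap: planted per-shRNA selection effects
#'
#' Ground truth for a simulated dropout screen.  Each gene is labelled
#' `neutral`, `essential_all`, or `essential_condition:<name>`; shRNAs of
#' essential genes carry a positive per-day depletion rate `s` on at least
#' `ceiling(effectiveFraction * n)` of the gene's constructs.  A separate
#' zero-mean `background` rate models shRNA-intrinsic burden shared across
#' replicates (see the package vignette); it is not part of the
#' essentiality labels, and neutral genes always have `s == 0`.
#'
#' @slot shrnaId,geneSymbol Parallel per-shRNA identifiers.
#' @slot s Nonnegative per-day depletion rate per shRNA (essentiality).
#' @slot background Zero-mean per-day rate per shRNA, condition-independent.
#' @slot geneLabel Named character vector (one label per reliable gene).
#' @slot effectiveFraction Fraction of an essential gene's shRNAs that
#'   carry its effect.
#'
#' @seealso [plantEffects()], [applySelection()]
#' @export
setClass("EffectMap",
         slots = c(shrnaId = "character",
                   geneSymbol = "character",
                   s = "numeric",
                   background = "numeric",
                   geneLabel = "character",
                   effectiveFraction = "numeric"))

setValidity("EffectMap", function(object) {
  n <- length(object@shrnaId)
  if (length(object@geneSymbol) != n || length(object@s) != n ||
      length(object@background) != n) {
    return("per-shRNA slots must have equal length")
  }
  if (any(object@s < 0)) return("selection coefficients must be >= 0")
  lab <- object@geneLabel
  if (is.null(names(lab))) return("geneLabel must be named by gene symbol")
  neutral <- names(lab)[lab == "neutral"]
  if (any(object@s[object@geneSymbol %in% neutral] != 0)) {
    return("neutral genes must have s = 0 on all their shRNAs")
  }
  ess <- names(lab)[lab != "neutral"]
  for (g in ess) {
    sg <- object@s[object@geneSymbol == g]
    if (sum(sg > 0) < ceiling(object@effectiveFraction * length(sg))) {
      return(sprintf("essential gene %s has too few effective shRNAs", g))
    }
  }
  TRUE
})

#' AbundanceProfile: relative shRNA abundances in a cell pool
#'
#' Per-shRNA relative abundance (nonnegative, summing to one) at a given
#' number of days since transduction, under one culture condition.
#'
#' @slot abundance Named numeric vector (names are shRNA ids), summing to 1
#'   within 1e-9.
#' @slot day Days since transduction.
#' @slot condition Setting label (`"baseline"` at day 0).
#'
#' @seealso [simulateBaseline()], [applySelection()]
#' @export
setClass("AbundanceProfile",
         slots = c(abundance = "numeric",
                   day = "numeric",
                   condition = "character"))

setValidity("AbundanceProfile", function(object) {
  a <- object@abundance
  if (is.null(names(a))) return("abundance must be named by shrna_id")
  if (any(a < 0)) return("abundances must be nonnegative")
  if (abs(sum(a) - 1) > 1e-9) return("abundances must sum to 1 (tol 1e-9)")
  if (object@day < 0) return("day must be nonnegative")
  TRUE
})

#' ScreenExperiment: shRNA x sample count matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the integer
#' `counts` assay (rows = shRNAs, columns = samples), with the library
#' records as `rowData` and the sample sheet (condition, replicate,
#' transduction efficiency, FASTQ path) as `colData`.
#'
#' @seealso [assembleCountMatrix()], [normalizeCounts()]
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("a 'counts' assay is required")
  }
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts))) {
    return("counts must be nonnegative integers")
  }
  if (anyDuplicated(colnames(object))) return("sample ids must be unique")
  TRUE
})

#' MedianEffectFit: Chou-Talalay median-effect parameters for one drug
#'
#' Parameters of the median-effect equation fa/fu = (D/Dm)^m fitted by
#' ordinary least squares on the log-log (logit) scale: `m` is the
#' sigmoidicity slope, `Dm` the dose giving fa = 0.5 (the IC50 under this
#' model) and `r` the correlation coefficient of the linearised fit.
#'
#' @slot m Slope (dimensionless); > 0 for an inhibitor.
#' @slot Dm Median-effect dose, same units as the input doses (nM).
#' @slot r Correlation coefficient of the linearised fit.
#' @slot drugLabel Drug name.
#' @slot status `"ok"`, or `"nonpositive_slope"` for a flagged fit.
#' @slot n Number of dose points used.
#'
#' @seealso [fitMedianEffect()], [doseForEffect()], [combinationIndex()]
#' @export
setClass("MedianEffectFit",
         slots = c(m = "numeric", Dm = "numeric", r = "numeric",
                   drugLabel = "character", status = "character",
                   n = "integer"))

#' DoseResponseCurve: dose vs fraction-affected observations
#'
#' Strictly increasing positive doses with the fraction affected
#' (1 - viability relative to untreated control) at each dose, clamped
#' strictly inside (0, 1).
#'
#' @slot doses Positive, strictly increasing concentrations (nM).
#' @slot fa Fractions affected, each in (0, 1).
#' @slot drugLabel Drug name.
#'
#' @seealso [fitMedianEffect()], [simulateDoseResponse()]
#' @export
setClass("DoseResponseCurve",
         slots = c(doses = "numeric", fa = "numeric", drugLabel = "character"))

setValidity("DoseResponseCurve", function(object) {
  d <- object@doses
  if (length(d) != length(object@fa)) return("doses and fa lengths differ")
  if (any(d <= 0)) return("doses must be strictly positive")
  if (is.unsorted(d, strictly = TRUE)) {
    return("doses must be strictly increasing")
  }
  if (any(object@fa <= 0 | object@fa >= 1)) {
    return("fa values must lie strictly inside (0, 1)")
  }
  TRUE
})
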