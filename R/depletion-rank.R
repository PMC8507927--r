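#' @describeIn normalizeCounts Normalize a raw counts matrix.
#' @export
setMethod("normalizeCounts", "matrix", function(object, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  zero <- colSums(object) == 0
  if (any(zero)) {
    stop("all-zero counts for sample(s): ",
         paste(colnames(object)[zero], collapse = ", "), call. = FALSE)
  }
  shifted <- object + pseudocount
  sweep(shifted, 2, colSums(shifted), "/") * 1e6
})

#' @describeIn normalizeCounts Add a `"normalized"` assay to a
#'   `ScreenExperiment`.
#' @export
setMethod("normalizeCounts", "ScreenExperiment",
          function(object, pseudocount = 0.5) {
  norm <- normalizeCounts(counts(object), pseudocount = pseudocount)
  SummarizedExperiment::assay(object, "normalized") <- norm
  S4Vectors::metadata(object)$pseudocount <- pseudocount
  object
})

#' Per-shRNA depletion fold changes between baseline and follow-up
#'
#' Computes `fc_depletion = normalized_baseline / normalized_followup` for
#' every shRNA; values above 1 indicate depletion during selection.  Because
#' both columns are normalized to reads-per-million, fold changes are
#' invariant to sequencing depth.
#'
#' @param object A normalized matrix (from [normalizeCounts()]) or a
#'   [ScreenExperiment-class] carrying a `"normalized"` assay.
#' @param baseline,followup Sample (column) identifiers.
#' @param design Optional [ShrnaLibrary-class] used to attach gene symbols.
#' @return A [S4Vectors::DataFrame] with columns `shrna_id`,
#'   (`gene_symbol`,) `fc_depletion`, `log2_fc`, and metadata recording the
#'   sample pair.
#' @export
foldChanges <- function(object, baseline, followup, design = NULL) {
  norm <- if (is(object, "ScreenExperiment")) {
    if (!"normalized" %in% SummarizedExperiment::assayNames(object)) {
      stop("run normalizeCounts() first", call. = FALSE)
    }
    SummarizedExperiment::assay(object, "normalized")
  } else object
  for (s in c(baseline, followup)) {
    if (!s %in% colnames(norm)) {
      stop("unknown sample id '", s, "'", call. = FALSE)
    }
  }
  fc <- norm[, baseline] / norm[, followup]
  out <- DataFrame(shrna_id = rownames(norm), fc_depletion = unname(fc),
                   log2_fc = unname(log2(fc)))
  if (!is.null(design)) {
    out$gene_symbol <- geneSymbols(design)[match(out$shrna_id,
                                                 shrnaIds(design))]
    out <- out[, c("shrna_id", "gene_symbol", "fc_depletion", "log2_fc")]
  }
  metadata(out) <- list(baseline_sample_id = baseline,
                        followup_sample_id = followup)
  out
}

#' Rank genes by the second-largest depletion fold change
#'
#' The essentiality score of a gene is the second-largest `fc_depletion`
#' among its shRNAs, so every scoring shRNA is backed by another shRNA
#' against the same gene with an even larger depletion -- a guard against
#' single-shRNA off-target artifacts.  Only reliable genes are ranked;
#' auxiliary targets are ignored.  Ties are broken by lexicographic gene
#' symbol and flagged.
#'
#' @param fc A fold-change table from [foldChanges()] (must carry
#'   `gene_symbol`, or supply `design`).
#' @param design Optional [ShrnaLibrary-class] supplying gene symbols and
#'   reliable flags; required when `fc` lacks `gene_symbol`.
#' @return A [S4Vectors::DataFrame] sorted by rank with columns
#'   `gene_symbol`, `score`, `rank` (1 = most essential), `n_shrnas`,
#'   `tie`.
#' @examples
#' fc <- S4Vectors::DataFrame(shrna_id = paste0("sh", 1:5),
#'                            gene_symbol = rep("G1", 5),
#'                            fc_depletion = c(8, 3, 2, 1.1, 0.9))
#' rankGenesSecondBest(fc)
#' @export
rankGenesSecondBest <- function(fc, design = NULL) {
  gene <- fc$gene_symbol
  keep <- rep(TRUE, nrow(fc))
  if (!is.null(design)) {
    m <- match(fc$shrna_id, shrnaIds(design))
    if (anyNA(m)) stop("fold-change table contains shRNAs absent from the ",
                       "design", call. = FALSE)
    gene <- geneSymbols(design)[m]
    keep <- isReliable(design)[m]
  }
  if (is.null(gene)) {
    stop("gene symbols unavailable: pass a design or a fold-change table ",
         "with a gene_symbol column", call. = FALSE)
  }
  gene <- gene[keep]
  v <- fc$fc_depletion[keep]

  nPer <- table(gene)
  short <- names(nPer)[nPer < 2L]
  if (length(short)) {
    stop("gene(s) with fewer than 2 measured shRNAs: ",
         paste(head(short, 5), collapse = ", "), call. = FALSE)
  }

  # group-wise second largest without per-gene sorting: order by
  # (gene, -fc) and pick the element one past each group start
  o <- order(gene, -v, method = "radix")
  gs <- gene[o]
  vs <- v[o]
  start <- which(!duplicated(gs))
  score <- vs[start + 1L]
  genes <- gs[start]

  r <- order(-score, genes, method = "radix")
  out <- DataFrame(gene_symbol = genes[r],
                   score = score[r],
                   rank = seq_along(r),
                   n_shrnas = as.integer(nPer[genes[r]]))
  out$tie <- out$score %in% out$score[duplicated(out$score)]
  rownames(out) <- out$gene_symbol
  out
}

#' Replicate concordance of depletion fold changes
#'
#' Spearman rank correlation of the fold changes (headline statistic,
#' robust to the heavy right tail of depletion fold changes) and Pearson
#' correlation of log2 fold changes, over the shared shRNA set.
#'
#' @param fc1,fc2 Fold-change tables from [foldChanges()] over the same
#'   shRNA set; fewer than 3 shared shRNAs is a validation error.
#' @return A list with `spearman` and `pearson_on_log`.
#' @export
replicateConcordance <- function(fc1, fc2) {
  m <- match(fc1$shrna_id, fc2$shrna_id)
  ok <- !is.na(m)
  if (sum(ok) < 3L) {
    stop("fewer than 3 shared shRNAs between the two tables", call. = FALSE)
  }
  a <- fc1$fc_depletion[ok]
  b <- fc2$fc_depletion[m[ok]]
  list(spearman = cor(a, b, method = "spearman"),
       pearson_on_log = cor(log2(a), log2(b)))
}

#' Top-ranked gene set
#'
#' @param ranks A rank table from [rankGenesSecondBest()].
#' @param fraction Fraction of genes to take (default 0.01, the top 1%);
#'   the set has `ceiling(fraction * n_genes)` members.
#' @return Character vector of gene symbols.
#' @export
topGeneSet <- function(ranks, fraction = 0.01) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  k <- ceiling(fraction * nrow(ranks))
  ranks$gene_symbol[ranks$rank <= k]
}

#' Genes specific to a target setting
#'
#' Set algebra used to call hits unique to one culture condition: the
#' intersection of the target setting's replicate top sets, minus the union
#' of every top set observed in the other settings.
#'
#' @param targetSets List of gene sets (one per replicate of the target
#'   setting).
#' @param otherSets List of gene sets from all other settings/replicates.
#' @return Character vector of setting-specific genes.
#' @examples
#' conditionSpecificGenes(list(c("A", "B", "C"), c("B", "C", "D")),
#'                        list("C"))
#' @export
conditionSpecificGenes <- function(targetSets, otherSets) {
  stopifnot(length(targetSets) >= 1L, length(otherSets) >= 1L)
  setdiff(Reduce(intersect, targetSets), Reduce(union, otherSets))
}

#' Recovery of planted essential genes
#'
#' Validation harness for simulated screens: compares the top-ranked gene
#' set against the simulator's planted truth.
#'
#' @param ranks A rank table from [rankGenesSecondBest()].
#' @param truth An [EffectMap-class], or a character vector of planted
#'   gene symbols.  For an `EffectMap`, `condition` selects which
#'   condition-specific essentials count as planted.
#' @param topFraction Fraction of genes called hits.
#' @param condition Optional setting label passed to [essentialGenes()].
#' @return A list with `sensitivity` and `precision`.
#' @export
recoveryMetrics <- function(ranks, truth, topFraction = 0.05,
                            condition = NULL) {
  planted <- if (is(truth, "EffectMap")) essentialGenes(truth, condition)
             else as.character(truth)
  if (length(planted) == 0L) {
    stop("planted gene set is empty", call. = FALSE)
  }
  top <- topGeneSet(ranks, topFraction)
  nHit <- length(intersect(planted, top))
  list(sensitivity = nHit / length(planted),
       precision = nHit / length(top))
}
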