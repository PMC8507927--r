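# Accept both the native column names and the DESeq2 results dialect.
.deColumns <- function(records) {
  df <- as.data.frame(records)
  alias <- c(gene = "gene_symbol", log2FoldChange = "log2_fc",
             pvalue = "p_value")
  for (from in names(alias)) {
    to <- alias[[from]]
    if (!to %in% colnames(df) && from %in% colnames(df)) {
      df[[to]] <- df[[from]]
    }
  }
  need <- c("gene_symbol", "log2_fc", "p_value", "padj")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' Filter a differential-expression table
#'
#' Retains a gene iff `p_value < pThresh` AND `padj < padjThresh` AND
#' `|log2_fc| > lfcThresh` -- all inequalities strict, so boundary values
#' are excluded.  A missing adjusted p-value (as produced by independent
#' filtering in standard DE tools) fails the filter silently and is counted
#' in the report.
#'
#' @param records DE results, a data.frame with columns `gene_symbol`,
#'   `log2_fc`, `p_value`, `padj` (the `gene`/`log2FoldChange`/`pvalue`
#'   dialect is also accepted).
#' @param pThresh,padjThresh,lfcThresh Strict thresholds (defaults 0.05,
#'   0.05 and 1).
#' @return A list: `retained` (data.frame), `n_up`, `n_down` (retained
#'   genes with positive / non-positive log2 fold change) and
#'   `n_missing_padj`.
#' @examples
#' de <- data.frame(gene_symbol = c("a", "b"), log2_fc = c(-2.1, 1.5),
#'                  p_value = c(1e-4, 0.001), padj = c(0.01, 0.2))
#' filterDE(de)
#' @export
filterDE <- function(records, pThresh = 0.05, padjThresh = 0.05,
                     lfcThresh = 1.0) {
  stopifnot(pThresh > 0, padjThresh > 0, lfcThresh > 0)
  df <- .deColumns(records)
  missPadj <- is.na(df$padj)
  keep <- !missPadj & df$p_value < pThresh & df$padj < padjThresh &
    abs(df$log2_fc) > lfcThresh
  keep[is.na(keep)] <- FALSE
  retained <- df[keep, , drop = FALSE]
  list(retained = retained,
       n_up = sum(retained$log2_fc > 0),
       n_down = sum(retained$log2_fc <= 0),
       n_missing_padj = sum(missPadj))
}

#' Signed pre-ranking metric for gene set enrichment
#'
#' `metric = -log10(p_value) * sign(log2_fc)` per gene, with `sign(0) = 0`
#' and p-values of zero clamped to the smallest positive double before the
#' logarithm.  The list is sorted by descending metric with ties broken by
#' gene symbol, giving a total, deterministic order.
#'
#' @param records DE results (same columns as [filterDE()]).
#' @return A data.frame with columns `gene_symbol` and `metric`, sorted for
#'   use as a pre-ranked enrichment input.
#' @examples
#' de <- data.frame(gene_symbol = c("a", "b"), log2_fc = c(-1.5, 0.3),
#'                  p_value = c(0.01, 1e-4), padj = c(0.1, 0.1))
#' gseaRankMetric(de)
#' @export
gseaRankMetric <- function(records) {
  df <- .deColumns(records)
  p <- pmax(df$p_value, .Machine$double.xmin)
  metric <- -log10(p) * sign(df$log2_fc)
  out <- data.frame(gene_symbol = df$gene_symbol, metric = metric,
                    stringsAsFactors = FALSE)
  out[order(-out$metric, out$gene_symbol, method = "radix"), , drop = FALSE]
}

#' Write a pre-ranked gene list in the conventional two-column tab format
#'
#' @param ranked Output of [gseaRankMetric()].
#' @param path Output path (no header, gene then metric, tab-separated).
#' @return Invisibly, `path`.
#' @export
writeRankFile <- function(ranked, path) {
  write.table(ranked[, c("gene_symbol", "metric")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE,
              eol = "\n")
  invisible(path)
}
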