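#' Construct a ShrnaLibrary from a records table
#'
#' @param records A data.frame or DataFrame with columns `shrna_id`,
#'   `gene_symbol`, `barcode`, `reliable_flag`.
#' @param name Library name.
#' @return A validated [ShrnaLibrary-class].
#' @export
ShrnaLibrary <- function(records, name = "unnamed") {
  records <- DataFrame(shrna_id = as.character(records$shrna_id),
                       gene_symbol = as.character(records$gene_symbol),
                       barcode = as.character(records$barcode),
                       reliable_flag = as.logical(records$reliable_flag))
  len <- if (nrow(records)) nchar(records$barcode[1L]) else 0L
  new("ShrnaLibrary", records = records, barcodeLength = as.integer(len),
      name = as.character(name))
}

#' Generate a synthetic pooled shRNA library catalogue
#'
#' Builds a library of `nTotalShrnas` constructs over `nReliableGenes`
#' reliable genes, each targeted by five or six shRNAs; any constructs
#' beyond the reliable allocation are assigned to auxiliary targets
#' (`AUX0001`, ...), which downstream ranking reports separately.  The
#' genes receiving a sixth shRNA are the first `k` genes in a seeded random
#' order, where `k` is the reliable allocation minus five per gene.
#'
#' Barcodes are drawn uniformly from a checksum-constrained code with
#' minimum pairwise Hamming distance 2, so single-mismatch matching in
#' [quantifyFastq()] is unambiguous by construction.
#'
#' @param nReliableGenes Number of reliable (rankable) genes.
#' @param nTotalShrnas Total library complexity; must be at least
#'   `5 * nReliableGenes`.
#' @param barcodeLength Barcode length in nucleotides (default 18); the
#'   barcode space `4^barcodeLength` must be at least `2 * nTotalShrnas`.
#' @param nReliableShrnas Number of constructs targeting reliable genes
#'   (between `5 *` and `6 * nReliableGenes`); defaults to everything that
#'   fits, leaving the remainder as auxiliary constructs.
#' @param auxPerTarget shRNAs per auxiliary target (default 5; the last
#'   auxiliary target absorbs any remainder).
#' @param seed Integer seed; equal arguments and seed give identical
#'   libraries.
#' @param name Library name.
#' @return A [ShrnaLibrary-class] with `nTotalShrnas` records.
#' @examples
#' lib <- generateLibrary(20, 105, barcodeLength = 10, seed = 1)
#' lib
#' @export
generateLibrary <- function(nReliableGenes, nTotalShrnas,
                            barcodeLength = 18L,
                            nReliableShrnas = NULL,
                            auxPerTarget = 5L,
                            seed = 1L,
                            name = "synthetic-library") {
  nReliableGenes <- .assertCount(nReliableGenes, "nReliableGenes")
  nTotalShrnas <- .assertCount(nTotalShrnas, "nTotalShrnas")
  barcodeLength <- .assertCount(barcodeLength, "barcodeLength", min = 2L)
  if (nTotalShrnas < 5L * nReliableGenes) {
    stop(sprintf(paste0("infeasible allocation: %d shRNAs cannot give %d ",
                        "reliable genes at least 5 shRNAs each"),
                 nTotalShrnas, nReliableGenes), call. = FALSE)
  }
  if (4^barcodeLength < 2 * nTotalShrnas) {
    stop(sprintf("barcode space too small: need 4^%d >= 2 * %d",
                 barcodeLength, nTotalShrnas), call. = FALSE)
  }
  if (is.null(nReliableShrnas)) {
    nReliableShrnas <- min(nTotalShrnas, 6L * nReliableGenes)
  }
  nReliableShrnas <- .assertCount(nReliableShrnas, "nReliableShrnas")
  if (nReliableShrnas < 5L * nReliableGenes ||
      nReliableShrnas > 6L * nReliableGenes ||
      nReliableShrnas > nTotalShrnas) {
    stop("nReliableShrnas must lie in [5, 6] x nReliableGenes and not ",
         "exceed nTotalShrnas", call. = FALSE)
  }

  withSeed(seed, {
    genes <- sprintf("GENE%05d", seq_len(nReliableGenes))
    k <- nReliableShrnas - 5L * nReliableGenes
    perm <- sample(genes)
    nPer <- setNames(rep(5L, nReliableGenes), perm)
    if (k > 0L) nPer[seq_len(k)] <- 6L
    nPer <- nPer[genes]

    nAux <- nTotalShrnas - nReliableShrnas
    auxGene <- character(0)
    if (nAux > 0L) {
      nTargets <- max(1L, nAux %/% auxPerTarget)
      idx <- pmin(((seq_len(nAux) - 1L) %/% auxPerTarget) + 1L, nTargets)
      auxGene <- sprintf("AUX%04d", idx)
    }

    geneCol <- c(rep(genes, times = nPer), auxGene)
    reliable <- c(rep(TRUE, nReliableShrnas), rep(FALSE, nAux))
    within <- unlist(lapply(c(nPer, table(auxGene)[unique(auxGene)]),
                            seq_len), use.names = FALSE)
    ids <- sprintf("%s_sh%d", geneCol, within)
    bc <- .randomBarcodes(nTotalShrnas, barcodeLength)
    lib <- ShrnaLibrary(data.frame(shrna_id = ids, gene_symbol = geneCol,
                                   barcode = bc, reliable_flag = reliable),
                        name = name)
    validObject(lib)
    lib
  })
}

#' Read a library design from a tab-separated file
#'
#' Expects a header with columns `shrna_id`, `gene_symbol`, `barcode`,
#' `reliable_flag` (true/false).  Row order is preserved and all class
#' invariants are checked; a duplicated barcode raises an integrity error
#' naming the barcode.
#'
#' @param path Path to a library TSV.
#' @return A [ShrnaLibrary-class].
#' @export
readLibrary <- function(path) {
  raw <- tryCatch(
    read.delim(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop("failed to parse library file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("shrna_id", "gene_symbol", "barcode", "reliable_flag")
  if (!all(need %in% colnames(raw))) {
    stop("library file must have header columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(raw$shrna_id) | is.na(raw$barcode) |
                 !(tolower(raw$reliable_flag) %in% c("true", "false")))
  if (length(bad)) {
    stop(sprintf("invalid row at line %d of '%s'", bad[1L] + 1L, path),
         call. = FALSE)
  }
  raw$reliable_flag <- tolower(raw$reliable_flag) == "true"
  lib <- ShrnaLibrary(raw, name = basename(path))
  validObject(lib)
  lib
}

#' Write a library design to a tab-separated file
#'
#' @param design A [ShrnaLibrary-class].
#' @param path Output path; the file re-reads to an equal design with
#'   [readLibrary()].
#' @return Invisibly, `path`.
#' @export
writeLibrary <- function(design, path) {
  stopifnot(is(design, "ShrnaLibrary"))
  validObject(design)
  df <- as.data.frame(design@records)
  df$reliable_flag <- ifelse(df$reliable_flag, "true", "false")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname ShrnaLibrary-class
#' @export
setMethod("shrnaIds", "ShrnaLibrary", function(object) object@records$shrna_id)

#' @rdname ShrnaLibrary-class
#' @export
setMethod("geneSymbols", "ShrnaLibrary",
          function(object) object@records$gene_symbol)

#' @rdname ShrnaLibrary-class
#' @export
setMethod("barcodes", "ShrnaLibrary", function(object) object@records$barcode)

#' @rdname ShrnaLibrary-class
#' @export
setMethod("isReliable", "ShrnaLibrary",
          function(object) object@records$reliable_flag)

#' @rdname ShrnaLibrary-class
#' @export
setMethod("barcodeLength", "ShrnaLibrary",
          function(object) object@barcodeLength)

#' @rdname ShrnaLibrary-class
#' @export
setMethod("libraryRecords", "ShrnaLibrary", function(object) object@records)

#' @rdname ShrnaLibrary-class
#' @export
setMethod("length", "ShrnaLibrary", function(x) nrow(x@records))

setMethod("show", "ShrnaLibrary", function(object) {
  rec <- object@records
  nRel <- sum(rec$reliable_flag)
  cat(sprintf(paste0("ShrnaLibrary '%s': %d shRNAs (%d targeting %d ",
                     "reliable genes), barcode length %d nt\n"),
              object@name, nrow(rec), nRel,
              length(unique(rec$gene_symbol[rec$reliable_flag])),
              object@barcodeLength))
})
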