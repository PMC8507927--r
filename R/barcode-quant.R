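#' Build a barcode lookup index
#'
#' Exact hash lookup over the design's barcodes; with `maxMismatch = 1` a
#' Hamming-distance-1 neighborhood is precomputed so a read barcode with a
#' single substitution resolves to its unique neighbor.  A sequence at
#' distance 1 from two different barcodes is recorded as ambiguous and such
#' reads are discarded (never fractionally assigned).  An exact barcode hit
#' always wins over a distance-1 rescue.
#'
#' @param design A [ShrnaLibrary-class]; duplicate barcodes are an
#'   integrity error.
#' @param maxMismatch 0 or 1.
#' @return A [BarcodeIndex-class].
#' @export
buildBarcodeIndex <- function(design, maxMismatch = 1L) {
  stopifnot(is(design, "ShrnaLibrary"))
  if (!maxMismatch %in% c(0L, 1L)) {
    stop("maxMismatch must be 0 or 1", call. = FALSE)
  }
  bc <- barcodes(design)
  if (anyDuplicated(bc)) {
    stop("design contains duplicate barcodes", call. = FALSE)
  }
  nb <- integer(0)
  if (maxMismatch == 1L && length(bc)) {
    tab <- .neighbors1(bc, barcodeLength(design))
    # neighbor equal to a real barcode: exact lookup takes precedence
    tab <- tab[!(tab$neighbor %in% bc), , drop = FALSE]
    dupSeq <- unique(tab$neighbor[duplicated(tab$neighbor)])
    tab <- tab[!duplicated(tab$neighbor), , drop = FALSE]
    nb <- tab$origin
    nb[tab$neighbor %in% dupSeq] <- 0L  # ambiguous
    names(nb) <- tab$neighbor
  }
  new("BarcodeIndex", barcodes = bc, shrnaIds = shrnaIds(design),
      neighborLookup = nb, maxMismatch = as.integer(maxMismatch),
      barcodeLength = barcodeLength(design))
}

#' Look up read barcodes in a BarcodeIndex
#'
#' @param index A [BarcodeIndex-class].
#' @param queries Character vector of barcode-length sequences.
#' @return Integer vector: the 1-based barcode index, 0 for ambiguous,
#'   NA for no match.
#' @export
matchBarcodes <- function(index, queries) {
  stopifnot(is(index, "BarcodeIndex"))
  hit <- match(queries, index@barcodes)
  if (index@maxMismatch == 1L && length(index@neighborLookup)) {
    miss <- which(is.na(hit))
    if (length(miss)) {
      hit[miss] <- unname(index@neighborLookup[queries[miss]])
    }
  }
  hit
}

setMethod("show", "BarcodeIndex", function(object) {
  cat(sprintf("BarcodeIndex: %d barcodes (%d nt), maxMismatch %d\n",
              length(object@barcodes), object@barcodeLength,
              object@maxMismatch))
})

#' Quantify barcodes in a FASTQ file
#'
#' Extracts the barcode substring of each read at a fixed offset (the
#' amplicon layout fixes its position), looks it up in the index, and
#' tallies assigned, ambiguous and unassigned reads.  Reads shorter than
#' `offset + barcodeLength` are counted unassigned, never truncated-matched.
#' Gzipped FASTQ is accepted.
#'
#' @param path FASTQ path.
#' @param index A [BarcodeIndex-class].
#' @param barcodeOffset 0-based offset of the barcode within the read
#'   (default `nchar(DEFAULT_FLANK5)`, the simulator's layout).
#' @return A list with `counts` (named integer vector per shRNA, zeros
#'   kept) and `qc`, itself a list: total_reads, assigned_reads,
#'   ambiguous_reads, unassigned_reads, barcode_recovery (fraction of
#'   design barcodes seen).  Conservation `total = assigned + ambiguous +
#'   unassigned` always holds.
#' @export
quantifyFastq <- function(path, index, barcodeOffset = nchar(DEFAULT_FLANK5)) {
  stopifnot(is(index, "BarcodeIndex"))
  barcodeOffset <- .assertCount(barcodeOffset, "barcodeOffset", min = 0L)
  nLines <- .countLines(path)
  if (nLines %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': truncated record %d",
                 path, nLines %/% 4L + 1L), call. = FALSE)
  }
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      .diagnoseFastq(path)
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  len <- index@barcodeLength
  n <- length(reads)
  longEnough <- Biostrings::width(reads) >= barcodeOffset + len
  assigned <- integer(length(index@barcodes))
  nAmb <- 0L
  if (any(longEnough)) {
    bcs <- as.character(Biostrings::subseq(reads[longEnough],
                                           start = barcodeOffset + 1L,
                                           width = len))
    hit <- matchBarcodes(index, bcs)
    nAmb <- sum(hit == 0L, na.rm = TRUE)
    ok <- !is.na(hit) & hit > 0L
    assigned <- tabulate(hit[ok], nbins = length(index@barcodes))
  }
  counts <- setNames(as.integer(assigned), index@shrnaIds)
  qc <- list(total_reads = n,
             assigned_reads = sum(assigned),
             ambiguous_reads = nAmb,
             unassigned_reads = n - sum(assigned) - nAmb,
             barcode_recovery = if (length(counts)) mean(counts > 0) else 0)
  list(counts = counts, qc = qc)
}

# Newline count without loading the file into memory (gzip transparent).
.countLines <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  n <- 0
  last <- as.raw(10L)
  repeat {
    chunk <- readBin(con, "raw", n = 1048576L)
    if (length(chunk) == 0L) break
    n <- n + sum(chunk == as.raw(10L))
    last <- chunk[length(chunk)]
  }
  if (last != as.raw(10L)) n <- n + 1  # final line without trailing newline
  as.integer(n)
}

# Locate the first structurally broken FASTQ record, for error reporting.
.diagnoseFastq <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (is.null(lines)) return(invisible(NULL))
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': truncated record %d",
                 path, length(lines) %/% 4L + 1L), call. = FALSE)
  }
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': record %d", path, bad[1L]),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Assemble a count matrix from per-sample count vectors
#'
#' @param countsList Named list (names = sample ids, sample-sheet order) of
#'   integer vectors named by shrna_id; every design shRNA must be present.
#' @param samples Sample sheet (data.frame or DataFrame) with a
#'   `sample_id` column; duplicated ids are an integrity error.
#' @param design The [ShrnaLibrary-class] the counts index against.
#' @return A [ScreenExperiment-class] (rows in design order, columns in
#'   sample-sheet order).
#' @export
assembleCountMatrix <- function(countsList, samples, design) {
  stopifnot(is(design, "ShrnaLibrary"))
  samples <- DataFrame(samples)
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id collision in sample sheet", call. = FALSE)
  }
  if (!setequal(names(countsList), samples$sample_id)) {
    stop("countsList names must match sample sheet sample_id", call. = FALSE)
  }
  ids <- shrnaIds(design)
  mat <- vapply(samples$sample_id, function(s) {
    v <- countsList[[s]]
    if (is.null(names(v)) || !all(ids %in% names(v))) {
      stop("counts for sample '", s, "' do not cover every design shRNA",
           call. = FALSE)
    }
    as.integer(v[ids])
  }, integer(length(ids)))
  dimnames(mat) <- list(ids, samples$sample_id)
  rownames(samples) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    rowData = libraryRecords(design),
    colData = samples)
  new("ScreenExperiment", se)
}

#' Filter samples by transduction efficiency
#'
#' A sample passes iff `low <= transduction_efficiency <= high`; the screen
#' protocol excludes experiments with efficiency above 40% (multiple
#' integrations likely) or below 10% (poor representation).  Baseline
#' samples are always retained; a non-baseline sample with missing
#' efficiency is a validation error.
#'
#' @param samples Sample sheet with columns `sample_id`, `condition`,
#'   `transduction_efficiency`.
#' @param low,high QC window bounds (defaults 0.10 and 0.40).
#' @return A list with `retained` (DataFrame) and `excluded` (DataFrame
#'   with a `reason` column).
#' @examples
#' sheet <- data.frame(sample_id = c("b", "s1", "s2"),
#'                     condition = c("baseline", "arm", "arm"),
#'                     transduction_efficiency = c(NA, 0.25, 0.45))
#' qcFilterSamples(sheet)$excluded
#' @export
qcFilterSamples <- function(samples, low = 0.10, high = 0.40) {
  samples <- DataFrame(samples)
  .assertFraction(low, "low"); .assertFraction(high, "high")
  te <- samples$transduction_efficiency
  isBase <- samples$condition == "baseline"
  if (any(!isBase & is.na(te))) {
    stop("missing transduction_efficiency for non-baseline sample(s): ",
         paste(samples$sample_id[!isBase & is.na(te)], collapse = ", "),
         call. = FALSE)
  }
  keep <- isBase | (te >= low & te <= high)
  reason <- rep(NA_character_, nrow(samples))
  reason[!keep & te > high] <- sprintf("transduction efficiency %.2f > %.2f",
                                       te[!keep & te > high], high)
  reason[!keep & te < low] <- sprintf("transduction efficiency %.2f < %.2f",
                                      te[!keep & te < low], low)
  excluded <- samples[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(retained = samples[keep, , drop = FALSE], excluded = excluded)
}

#' @rdname ScreenExperiment-class
#' @param object A `ScreenExperiment`.
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethod counts
setMethod("counts", "ScreenExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})
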