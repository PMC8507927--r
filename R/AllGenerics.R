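#' @rdname ShrnaLibrary-class
#' @param object,x A `ShrnaLibrary`.
#' @export
setGeneric("shrnaIds", function(object) standardGeneric("shrnaIds"))

#' @rdname ShrnaLibrary-class
#' @export
setGeneric("geneSymbols", function(object) standardGeneric("geneSymbols"))

#' @rdname ShrnaLibrary-class
#' @export
setGeneric("barcodes", function(object) standardGeneric("barcodes"))

#' @rdname ShrnaLibrary-class
#' @export
setGeneric("isReliable", function(object) standardGeneric("isReliable"))

#' @rdname ShrnaLibrary-class
#' @export
setGeneric("barcodeLength", function(object) standardGeneric("barcodeLength"))

#' @rdname ShrnaLibrary-class
#' @export
setGeneric("libraryRecords", function(object) standardGeneric("libraryRecords"))

#' @rdname EffectMap-class
#' @param object An `EffectMap`.
#' @param condition Optional setting label; when given, genes whose effect is
#'   specific to that condition are included alongside unconditional
#'   essentials.
#' @export
setGeneric("essentialGenes",
           function(object, condition = NULL) standardGeneric("essentialGenes"))

#' @rdname AbundanceProfile-class
#' @param object An `AbundanceProfile`.
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))

#' Normalize screen counts to reads-per-million
#'
#' Adds `pseudocount` to every cell, scales each sample (column) to a total
#' of one million, guarding fold-change computation against zero counts for
#' fully depleted shRNAs.
#'
#' @param object A counts matrix (rows = shRNAs, columns = samples) or a
#'   [ScreenExperiment-class].
#' @param pseudocount Nonnegative value added to every cell before
#'   normalization (default 0.5).
#' @return For a matrix, the normalized matrix (columns sum to 1e6); for a
#'   `ScreenExperiment`, the object with an added `"normalized"` assay.
#' @examples
#' m <- matrix(c(100L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' normalizeCounts(m)
#' @export
setGeneric("normalizeCounts",
           function(object, pseudocount = 0.5)
             standardGeneric("normalizeCounts"))
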