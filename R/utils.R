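#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats cor lm coef rnorm runif rbinom rmultinom rgamma setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a locally set RNG seed, restoring global RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

.assertFraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Pairwise-safe random barcodes: every barcode satisfies a GF(4) checksum
# (sum of base codes == 0 mod 4), so any two distinct barcodes differ in at
# least two positions.  Capacity is 4^(len-1), the Singleton bound for a
# length-len distance-2 code, so the feasibility check is tight.
.randomBarcodes <- function(n, len) {
  if (len < 2L) stop("barcode length must be at least 2", call. = FALSE)
  capacity <- 4^(len - 1L)
  if (capacity < n) {
    stop(sprintf(paste0("barcode space too small: %d barcodes of length %d ",
                        "cannot keep pairwise Hamming distance >= 2"),
                 n, len), call. = FALSE)
  }
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("failed to draw enough distinct barcodes; barcode space too dense",
           call. = FALSE)
    }
    need <- n - length(out)
    draw <- max(need * 2L, 64L)
    prefix <- matrix(sample.int(4L, draw * (len - 1L), replace = TRUE) - 1L,
                     nrow = draw)
    check <- (-rowSums(prefix)) %% 4L
    mat <- cbind(prefix, check)
    bc <- do.call(paste0, as.data.frame(matrix(DNA_BASES[mat + 1L],
                                               nrow = draw)))
    out <- unique(c(out, bc))
  }
  out[seq_len(n)]
}

# Hamming distance between two equal-length strings (small-scale helper).
hammingDistance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# All sequences within Hamming distance exactly 1 of each input string.
# Returns a data.frame (neighbor, origin index); identities are excluded.
.neighbors1 <- function(x, len) {
  pieces <- vector("list", len * 4L)
  origin <- rep(seq_along(x), times = len * 4L)
  k <- 0L
  for (p in seq_len(len)) {
    for (b in DNA_BASES) {
      v <- x
      substr(v, p, p) <- b
      k <- k + 1L
      pieces[[k]] <- v
    }
  }
  nb <- unlist(pieces, use.names = FALSE)
  keep <- nb != rep(x, times = len * 4L)
  data.frame(neighbor = nb[keep], origin = origin[keep],
             stringsAsFactors = FALSE)
}
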