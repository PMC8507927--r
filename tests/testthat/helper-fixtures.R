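# Small fixtures built in code; all randomness seeded.

smallLibrary <- function(nGenes = 20L, nShrnas = 105L, bcLen = 12L,
                         seed = 101L) {
  generateLibrary(nGenes, nShrnas, barcodeLength = bcLen, seed = seed)
}

# Hand-built adversarial design: two barcodes at Hamming distance 2 (so a
# 1-mismatch read can sit exactly between them) plus a distant third.
adversarialLibrary <- function() {
  ShrnaLibrary(data.frame(
    shrna_id = c("g1_sh1", "g1_sh2", "g1_sh3", "g1_sh4", "g1_sh5"),
    gene_symbol = rep("G1", 5),
    barcode = c("AAAAAAAA",  # distance 2 from the next
                "AAAAAACC",
                "GGGGGGGG",
                "TTTTTTTT",
                "CCCCCCCC"),
    reliable_flag = TRUE))
}

writeFastq <- function(path, seqs, ids = sprintf("r%d", seq_along(seqs))) {
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

randomFit <- function(m, Dm, label = "x") {
  new("MedianEffectFit", m = m, Dm = Dm, r = 1, drugLabel = label,
      status = "ok", n = 5L)
}
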