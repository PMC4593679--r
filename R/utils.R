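# Shared low-level helpers: alphabets, IUPAC masks, seed derivation, logging.

AMINO_ACIDS <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# 4-bit nucleotide masks: A=1, C=2, G=4, T=8; ambiguity codes are unions.
.nucMaskTable <- local({
  base <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  codes <- Biostrings::IUPAC_CODE_MAP
  m <- vapply(strsplit(codes, ""), function(b) sum(base[b]), integer(1))
  names(m) <- names(codes)
  c(m, "-" = 15L, "N" = 15L, "?" = 15L, "U" = 8L)
})

# inverse: mask -> IUPAC character (mask 15 -> "N")
.maskToIupac <- local({
  inv <- character(15)
  for (nm in names(Biostrings::IUPAC_CODE_MAP)) {
    base <- c(A = 1L, C = 2L, G = 4L, T = 8L)
    bits <- sum(base[strsplit(Biostrings::IUPAC_CODE_MAP[[nm]], "")[[1]]])
    inv[bits] <- nm
  }
  inv
})

nucMask <- function(chars) {
  m <- .nucMaskTable[chars]
  m[is.na(m)] <- 15L
  unname(m)
}

iupacUnion <- function(chars) {
  .maskToIupac[Reduce(bitwOr, nucMask(chars))]
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme: each pipeline stage draws child seed
#' \code{(seed * 48271 + stage) mod (2^31 - 1)}, so one master seed controls
#' every source of randomness without correlated streams across stages.
#'
#' @param seed master integer seed
#' @param stage integer stage counter (>= 1)
#' @return an integer seed
#' @export
childSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage) %% (2^31 - 1))
}

.msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}

# split a character vector of sequences into a matrix of single characters
.seqsToMatrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

.matrixToSeqs <- function(m) {
  s <- apply(m, 1L, paste0, collapse = "")
  names(s) <- rownames(m)
  s
}

# write/read FASTA via Biostrings, tolerant of plain character input
writeFasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

readFastaChar <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path) else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
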