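# Degeneracy coding: rewrite codons so that synonymous differences are
# eliminated while non-synonymous differences are preserved. All codons of
# one synonymous family (Leu, Ser and Arg each form a single merged family
# across their codon sets) map to one degenerate pattern: the position-wise
# IUPAC union of the family's codons.

#' Build the degeneracy-coding table
#'
#' For every amino acid, its codon family (under the given genetic code) is
#' collapsed to a single pattern: per codon position the IUPAC code covering
#' every base the family uses there. Amino acids with a single codon (Met,
#' Trp under the standard code) keep their codon unchanged.
#'
#' @param geneticCode named character vector codon -> residue (default
#'   standard code)
#' @return list: table (named character vector codon -> degenerate pattern),
#'   families (list residue -> codons), patterns (named vector residue ->
#'   pattern)
#' @export
buildDegenTable <- function(geneticCode = Biostrings::GENETIC_CODE) {
  sense <- geneticCode[geneticCode != "*"]
  fam <- split(names(sense), unname(sense))
  patterns <- vapply(fam, function(codons) {
    chars <- do.call(rbind, strsplit(codons, ""))
    paste0(vapply(1:3, function(p) iupacUnion(chars[, p]), character(1)),
           collapse = "")
  }, character(1))
  tab <- setNames(patterns[unname(sense)], names(sense))
  list(table = tab, families = fam, patterns = patterns)
}

# resolve one codon (possibly containing IUPAC ambiguity) to its degenerate
# pattern; returns NA when the codon is not attributable to a single family
.degenCodon <- function(codon, degen, cache) {
  hit <- cache[[codon]]
  if (!is.null(hit)) return(hit)
  out <- degen$table[codon]
  if (is.na(out)) {
    chars <- strsplit(codon, "")[[1]]
    if (any(chars %in% c("-", ".", "?"))) {
      out <- if (all(chars %in% c("-", ".", "?"))) "---" else NA_character_
    } else {
      # expand ambiguity codes to candidate codons
      base <- c(A = 1L, C = 2L, G = 4L, T = 8L)
      sets <- lapply(chars, function(ch) {
        m <- nucMask(ch)
        names(base)[bitwAnd(m, base) > 0L]
      })
      cand <- as.vector(outer(outer(sets[[1]], sets[[2]], paste0),
                              sets[[3]], paste0))
      pats <- unique(degen$table[cand])
      pats <- pats[!is.na(pats)]   # candidates that are stop codons drop out
      out <- if (length(pats) == 1L) unname(pats) else NA_character_
    }
  }
  out <- unname(out)
  cache[[codon]] <- out
  out
}

#' Degeneracy-code a supermatrix
#'
#' Rewrites every codon to its family's degenerate pattern. Codons that
#' cannot be attributed to a single synonymous family -- partial gaps,
#' unresolvable ambiguity spanning several families -- become \code{NNN}
#' (all-gap codons stay \code{---}). In-frame stop codons also become
#' \code{NNN} and trigger a warning. The per-category counts are attached as
#' attribute "log".
#'
#' @param sm a \linkS4class{SuperMatrix} containing all three codon
#'   positions, or a character matrix with columns divisible by 3
#' @param geneticCode genetic code (default standard)
#' @return object of the same kind with recoded sequences
#' @export
degenEncode <- function(sm, geneticCode = Biostrings::GENETIC_CODE) {
  mat <- if (is(sm, "SuperMatrix")) sm@seqs else sm
  if (is(sm, "SuperMatrix") && !all(1:3 %in% sm@labels$codon_pos))
    stop("degeneracy coding requires all three codon positions")
  if (ncol(mat) %% 3L != 0L) stop("column count must be divisible by 3")
  degen <- buildDegenTable(geneticCode)
  stops <- names(geneticCode)[geneticCode == "*"]
  cache <- new.env(parent = emptyenv())
  nStop <- 0L; nUnresolved <- 0L; nRecoded <- 0L
  out <- mat
  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    nCod <- length(row) %/% 3L
    codons <- vapply(seq_len(nCod), function(j)
      paste0(row[(3L * j - 2L):(3L * j)], collapse = ""), character(1))
    isStop <- codons %in% stops
    nStop <- nStop + sum(isStop)
    enc <- vapply(codons, .degenCodon, character(1), degen = degen,
                  cache = cache)
    unres <- is.na(enc) & !isStop & codons != "---"
    nUnresolved <- nUnresolved + sum(unres)
    enc[is.na(enc)] <- "NNN"
    nRecoded <- nRecoded + sum(enc != codons & codons != "---")
    out[r, ] <- unlist(strsplit(enc, ""), use.names = FALSE)
  }
  if (nStop > 0L)
    warning(nStop, " in-frame stop codon(s) encountered; recoded as NNN")
  res <- if (is(sm, "SuperMatrix")) SuperMatrix(out, sm@labels) else out
  attr(res, "log") <- c(stops = nStop, unresolved = nUnresolved,
                        recoded = nRecoded)
  res
}

#' Write the degeneracy table as TSV
#'
#' @param path output file
#' @param geneticCode genetic code (default standard)
#' @export
writeDegenTable <- function(path, geneticCode = Biostrings::GENETIC_CODE) {
  degen <- buildDegenTable(geneticCode)
  df <- data.frame(codon = names(degen$table),
                   residue = unname(geneticCode[names(degen$table)]),
                   pattern = unname(degen$table))
  write.table(df[order(df$residue, df$codon), ], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
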