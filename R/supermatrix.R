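# Supermatrix assembly: threading fragments onto reference proteins,
# backtranslation to codon-backed nucleotide rows, concatenation, occupancy
# filtering, completeness, codon-position selection, and text writers.

# --- threading ---------------------------------------------------------------

#' Thread a fragment peptide onto a reference protein
#'
#' Smith-Waterman local alignment (affine gaps, custom matrix) of the
#' peptide against the orthogroup's reference protein; aligned residues land
#' in their reference columns, unaligned reference columns become gaps.
#' Peptide residues falling into insertions relative to the reference have
#' no column and are dropped (their count is reported).
#'
#' @param peptide fragment peptide (character scalar)
#' @param refProtein reference protein (character scalar, ungapped)
#' @param matrix a \linkS4class{SubstitutionMatrix}
#' @param gapOpen,gapExtend affine gap penalties (defaults 11, 1)
#' @return list(row (character vector, length = nchar(refProtein)), map
#'   (integer vector: per reference column the 1-based peptide position or
#'   NA), score, dropped (insertion residue count), qstart/qend/tstart/tend)
#' @export
threadFragment <- function(peptide, refProtein, matrix, gapOpen = 11,
                           gapExtend = 1) {
  M <- rbind(cbind(scoreMatrix(matrix), X = 0L), X = 0L)
  qi <- .pepIdx(peptide); ti <- .pepIdx(refProtein)
  S <- M[qi, ti, drop = FALSE]
  al <- .sw_align_scores(S, gapOpen, gapExtend)
  n <- nchar(refProtein)
  row <- rep("-", n)
  map <- rep(NA_integer_, n)
  pep <- strsplit(peptide, "")[[1]]
  if (nrow(al$pairs)) {
    map[al$pairs[, 2]] <- al$pairs[, 1]
    row[al$pairs[, 2]] <- pep[al$pairs[, 1]]
  }
  aligned <- nrow(al$pairs)
  spanned <- if (aligned) al$qend - al$qstart + 1L else 0L
  list(row = row, map = map, score = al$score, dropped = spanned - aligned,
       qstart = al$qstart, qend = al$qend, tstart = al$tstart, tend = al$tend)
}

#' Backtranslate threaded protein rows to nucleotides
#'
#' Each aligned residue is replaced by its source codon; gap columns become
#' \code{---}. The codon of residue i comes from \code{codons[[row]][i]}.
#'
#' @param rows list of threaded rows (character vectors over one reference
#'   length, gaps as "-")
#' @param maps list of per-row reference-column -> peptide-position maps
#'   (from \code{\link{threadFragment}})
#' @param codons list of per-row character vectors: the source codon of each
#'   peptide residue
#' @return character matrix, one row per input row, 3x reference-length
#'   columns
#' @export
backtranslate <- function(rows, maps, codons) {
  stopifnot(length(rows) == length(maps), length(rows) == length(codons))
  n <- length(rows[[1]])
  out <- matrix("-", nrow = length(rows), ncol = 3L * n)
  for (r in seq_along(rows)) {
    stopifnot(length(rows[[r]]) == n)
    for (j in seq_len(n)) {
      p <- maps[[r]][j]
      cod <- if (is.na(p)) "---" else codons[[r]][p]
      out[r, (3L * j - 2L):(3L * j)] <- strsplit(cod, "")[[1]]
    }
  }
  rownames(out) <- names(rows)
  out
}

# --- concatenation -----------------------------------------------------------

#' Concatenate per-orthogroup alignments into a supermatrix
#'
#' Rows are the union of taxa (or an explicit taxon set); taxa absent from
#' an orthogroup get all-gap stretches. Column labels record the source
#' orthogroup and the codon position cycling 1,2,3.
#'
#' @param alignments named list of character matrices (rows = taxa, columns
#'   divisible by 3)
#' @param taxa optional explicit row order (default: union, sorted)
#' @return a \linkS4class{SuperMatrix}
#' @export
concatenateAlignments <- function(alignments, taxa = NULL) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be named by orthogroup")
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(alignments, rownames))))
  blocks <- lapply(names(alignments), function(og) {
    a <- alignments[[og]]
    if (ncol(a) %% 3L != 0L) stop("alignment ", og, " is not codon-aligned")
    m <- matrix("-", nrow = length(taxa), ncol = ncol(a),
                dimnames = list(taxa, NULL))
    common <- intersect(taxa, rownames(a))
    m[common, ] <- a[common, , drop = FALSE]
    m
  })
  seqs <- do.call(cbind, blocks)
  labels <- do.call(rbind, lapply(names(alignments), function(og) {
    nc <- ncol(alignments[[og]])
    data.frame(orthogroup = og, codon_pos = rep_len(1:3, nc))
  }))
  SuperMatrix(seqs, labels)
}

# --- occupancy and completeness ---------------------------------------------

# non-missing cells: anything except '-' '.' '?' counts as data (ambiguity
# codes such as N carry partial information)
.isData <- function(m) !(m == "-" | m == "." | m == "?")

#' Filter supermatrix columns by taxon occupancy
#'
#' Keeps columns where at least \code{minTaxa} rows carry data (ambiguity
#' codes count as data; gaps do not). \code{minTaxa = 0} keeps everything;
#' \code{minTaxa = nrow} keeps only complete columns.
#'
#' @param sm a \linkS4class{SuperMatrix}
#' @param minTaxa minimum number of data-bearing rows per column
#' @return filtered \linkS4class{SuperMatrix}
#' @export
filterByOccupancy <- function(sm, minTaxa) {
  occ <- colSums(.isData(sm@seqs))
  keep <- occ >= minTaxa
  SuperMatrix(sm@seqs[, keep, drop = FALSE],
              sm@labels[keep, , drop = FALSE])
}

#' Percent completeness of a supermatrix
#'
#' 100 times the fraction of data-bearing cells. A zero-column matrix is
#' reported as 100 percent complete (with a message), so downstream summary
#' code need not special-case it.
#'
#' @param sm a \linkS4class{SuperMatrix}
#' @return numeric percentage in [0, 100]
#' @export
completeness <- function(sm) {
  if (ncol(sm@seqs) == 0L || nrow(sm@seqs) == 0L) {
    message("empty supermatrix: completeness reported as 100")
    return(100)
  }
  100 * mean(.isData(sm@seqs))
}

#' Select codon positions from a supermatrix
#'
#' @param sm a \linkS4class{SuperMatrix}
#' @param positions codon positions to keep (subset of 1:3), e.g.
#'   \code{c(1, 2)} for an nt12 variant
#' @return filtered \linkS4class{SuperMatrix}
#' @export
selectCodonPositions <- function(sm, positions) {
  keep <- sm@labels$codon_pos %in% positions
  SuperMatrix(sm@seqs[, keep, drop = FALSE], sm@labels[keep, , drop = FALSE])
}

# --- writers -----------------------------------------------------------------

#' Write a supermatrix in relaxed PHYLIP format
#'
#' Header line "ntaxa ncols", then one "name sequence" line per taxon
#' (names of any length, single space separator).
#'
#' @param sm a \linkS4class{SuperMatrix}
#' @param path output file
#' @export
writePhylip <- function(sm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(sm@seqs), ncol(sm@seqs)), con)
  for (i in seq_len(nrow(sm@seqs)))
    writeLines(paste(rownames(sm@seqs)[i],
                     paste0(sm@seqs[i, ], collapse = "")), con)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param path input file
#' @return character matrix (rows = taxa)
#' @export
readPhylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  seqs <- setNames(vapply(parts, `[[`, "", 2), vapply(parts, `[[`, "", 1))
  if (length(seqs) != hdr[1] || any(nchar(seqs) != hdr[2]))
    stop("malformed PHYLIP file")
  .seqsToMatrix(seqs)
}

#' Write a supermatrix in NEXUS format
#'
#' @param sm a \linkS4class{SuperMatrix}
#' @param path output file
#' @export
writeNexus <- function(sm, path) {
  x <- lapply(seq_len(nrow(sm@seqs)), function(i) sm@seqs[i, ])
  names(x) <- rownames(sm@seqs)
  ape::write.nexus.data(x, path, format = "dna", interleaved = FALSE)
  invisible(path)
}

#' Write a codon-position partition file
#'
#' RAxML-style lines, one per codon position present, listing the 1-based
#' column indices of that position as comma-separated runs.
#'
#' @param sm a \linkS4class{SuperMatrix}
#' @param path output file
#' @export
writePartitions <- function(sm, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in sort(unique(sm@labels$codon_pos))) {
    idx <- which(sm@labels$codon_pos == p)
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    spec <- paste(vapply(runs, function(r)
      if (length(r) == 1L) as.character(r) else
        sprintf("%d-%d", r[1], r[length(r)]), character(1)), collapse = ", ")
    writeLines(sprintf("DNA, pos%d = %s", p, spec), con)
  }
  invisible(path)
}

#' Write the per-column label table
#'
#' @param sm a \linkS4class{SuperMatrix}
#' @param path output TSV
#' @export
writeColumnLabels <- function(sm, path) {
  write.table(cbind(column = seq_len(nrow(sm@labels)), sm@labels), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- matrix variants ---------------------------------------------------------

#' Build the standard set of supermatrix variants
#'
#' From the unfiltered nt123 supermatrix: occupancy-filtered variants at the
#' given taxon thresholds, an nt12 variant (third positions removed) of the
#' base occupancy variant, and a degeneracy-coded variant of the same.
#'
#' @param sm unfiltered \linkS4class{SuperMatrix}
#' @param occupancyLevels named integer vector of minimum-taxa thresholds;
#'   the default mirrors a 20-taxon study: unfiltered (0), nt123 (4),
#'   min16 (16), min18 (18), complete (all taxa)
#' @param nt12From name of the occupancy variant the nt12 and degen1
#'   variants derive from (default "nt123")
#' @return named list of SuperMatrix objects (occupancy variants plus
#'   \code{nt12} and \code{degen1}) with attribute "summary" (data.frame of
#'   variant, columns, completeness)
#' @export
supermatrixVariants <- function(sm, occupancyLevels = NULL,
                                nt12From = "nt123") {
  nTaxa <- nrow(sm@seqs)
  if (is.null(occupancyLevels))
    occupancyLevels <- c(unfiltered = 0L, nt123 = 4L,
                         min16 = 16L, min18 = 18L, complete = nTaxa)
  out <- lapply(occupancyLevels, function(k) filterByOccupancy(sm, k))
  names(out) <- names(occupancyLevels)
  if (!nt12From %in% names(out))
    stop("nt12From must name one of the occupancy variants")
  out$nt12 <- selectCodonPositions(out[[nt12From]], c(1L, 2L))
  out$degen1 <- degenEncode(out[[nt12From]])
  summary <- data.frame(variant = names(out),
                        columns = vapply(out, function(x) ncol(x@seqs), 0L),
                        completeness = vapply(out, completeness, 0))
  attr(out, "summary") <- summary
  out
}
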