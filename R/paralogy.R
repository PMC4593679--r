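# Gene-tree based paralogy filtering: clan detection on unrooted gene trees,
# out-paralogue discard, in-paralogue consensus.

#' Classify a taxon's sequences on an unrooted gene tree
#'
#' A taxon with one leaf is "single". With several leaves, they form a clan
#' when some edge of the unrooted tree separates exactly those leaves from
#' everything else (either side of the split may be the taxon's side). If
#' so the copies are in-paralogues ("in_paralogue"); otherwise they are
#' out-paralogues ("out_paralogue").
#'
#' @param tree ape phylo gene tree (leaf labels carry taxon ids)
#' @param taxon taxon to classify
#' @param taxonOf function mapping a leaf label to its taxon id (default:
#'   strip a "__copy" suffix)
#' @return list(taxon, class, leaves)
#' @export
detectClans <- function(tree, taxon, taxonOf = .leafTaxon) {
  taxa <- taxonOf(tree$tip.label)
  leaves <- which(taxa == taxon)
  if (length(leaves) == 0L)
    return(list(taxon = taxon, class = "absent", leaves = character(0)))
  if (length(leaves) == 1L)
    return(list(taxon = taxon, class = "single",
                leaves = tree$tip.label[leaves]))
  nTip <- length(tree$tip.label)
  isClan <- FALSE
  if (length(leaves) >= nTip - 1L) {
    # all leaves, or all but one: the complement is empty or a single tip,
    # so the set sits on one side of a (pendant) edge by construction
    isClan <- TRUE
  } else {
    utree <- ape::unroot(tree)
    desc <- .tipDescendants(utree)   # per node: tip indices on the child side
    all <- seq_len(nTip)
    for (nd in (nTip + 1L):max(utree$edge)) {
      side <- desc[[nd]]
      if (setequal(side, leaves) || setequal(setdiff(all, side), leaves)) {
        isClan <- TRUE; break
      }
    }
  }
  list(taxon = taxon,
       class = if (isClan) "in_paralogue" else "out_paralogue",
       leaves = tree$tip.label[leaves])
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column, gaps are ignored and the most frequent residue wins. Ties are
#' resolved by the IUPAC code covering the tied residues (nucleotides) or by
#' X (amino acids). Columns where every sequence has a gap stay gaps.
#'
#' @param seqs character vector (equal lengths) or character matrix of
#'   aligned sequences
#' @param alphabet "DNA" or "AA"
#' @return consensus sequence (character scalar)
#' @export
consensusSequence <- function(seqs, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  mat <- if (is.matrix(seqs)) seqs else .seqsToMatrix(seqs)
  out <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[!(col %in% c("-", "."))]
    if (length(col) == 0L) { out[j] <- "-"; next }
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    out[j] <- if (length(top) == 1L) top
      else if (alphabet == "DNA") iupacUnion(top)
      else "X"
  }
  paste0(out, collapse = "")
}

#' Filter one orthogroup for paralogy
#'
#' Every taxon with more than one sequence is classified on the gene tree
#' (\code{\link{detectClans}}). If any taxon's copies are out-paralogues the
#' orthogroup is discarded. Otherwise each in-paralogous set is collapsed to
#' a single consensus row and all rows are renamed to plain taxon ids.
#'
#' @param tree ape phylo gene tree whose leaves are the alignment rows
#' @param alignment character matrix (rows named by the tree's leaf labels)
#' @param alphabet "DNA" or "AA" (consensus tie handling)
#' @param taxonOf leaf label -> taxon mapping (default: strip "__copy")
#' @return list(keep (logical), alignment (merged matrix, rows = taxa; NULL
#'   when discarded), report (data.frame taxon/class/n_leaves))
#' @export
filterOrthogroup <- function(tree, alignment, alphabet = c("DNA", "AA"),
                             taxonOf = .leafTaxon) {
  alphabet <- match.arg(alphabet)
  if (!all(tree$tip.label %in% rownames(alignment)))
    stop("alignment must contain a row for every tree leaf")
  taxa <- unique(taxonOf(tree$tip.label))
  cls <- lapply(taxa, function(tx) detectClans(tree, tx, taxonOf))
  report <- data.frame(taxon = taxa,
                       class = vapply(cls, `[[`, "", "class"),
                       n_leaves = vapply(cls, function(x) length(x$leaves), 0L),
                       stringsAsFactors = FALSE)
  if (any(report$class == "out_paralogue"))
    return(list(keep = FALSE, alignment = NULL, report = report))
  rows <- lapply(cls, function(x) {
    sub <- alignment[x$leaves, , drop = FALSE]
    if (nrow(sub) == 1L) sub[1, ] else
      strsplit(consensusSequence(sub, alphabet), "")[[1]]
  })
  merged <- do.call(rbind, rows)
  rownames(merged) <- taxa
  list(keep = TRUE, alignment = merged, report = report)
}
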