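# S4 classes for the pipeline's central data objects.

#' SubstitutionMatrix: log-odds amino-acid scoring matrix
#'
#' Integer log-odds scores estimated from weighted residue-pair counts over
#' conserved gap-free alignment blocks, in the style of the BLOSUM series.
#' Carries its estimation by-products (pair and marginal frequencies) and
#' provenance counts.
#'
#' @slot name matrix name (used in the text serialisation header)
#' @slot scores 20 x 20 integer matrix, symmetric, rows/cols named by residue
#' @slot scale bits per score unit (0.5 = half-bits)
#' @slot pairFreqs symmetric matrix q_ij of residue-pair frequencies
#' @slot margFreqs named numeric p_i marginal residue frequencies
#' @slot nBlocks number of blocks used
#' @slot nPositions total alignment positions counted
#' @exportClass SubstitutionMatrix
setClass("SubstitutionMatrix",
  representation(name = "character", scores = "matrix", scale = "numeric",
                 pairFreqs = "matrix", margFreqs = "numeric",
                 nBlocks = "integer", nPositions = "integer"),
  validity = function(object) {
    msgs <- character()
    if (!all(dim(object@scores) == c(20L, 20L)))
      msgs <- c(msgs, "scores must be 20 x 20")
    if (!isTRUE(all.equal(object@scores, t(object@scores), tolerance = 0)))
      msgs <- c(msgs, "scores must be symmetric")
    if (abs(sum(object@pairFreqs) - 1) > 1e-9)
      msgs <- c(msgs, "pair frequencies must sum to 1")
    if (length(msgs)) msgs else TRUE
  })

#' @importFrom methods new show validObject slot is
setMethod("show", "SubstitutionMatrix", function(object) {
  cat("SubstitutionMatrix (", object@scale, "bit units )\n")
  cat("  built from", object@nBlocks, "blocks /", object@nPositions, "positions\n")
  cat("  score range:", min(object@scores), "to", max(object@scores), "\n")
})

#' @rdname SubstitutionMatrix-class
#' @param x a SubstitutionMatrix
#' @export
scoreMatrix <- function(x) x@scores

#' CoreOrthologueSet: profile database anchored on a reference taxon
#'
#' One scoring profile plus one reference protein per orthogroup; the unit
#' against which translated transcript fragments are searched and the target
#' of the reciprocal-best-hit confirmation.
#'
#' @slot referenceTaxon taxon id of the reference proteome
#' @slot orthogroups named list; per orthogroup a list with elements
#'   \code{profile} (ProfileModel list), \code{refProtein} (character
#'   sequence) and \code{refProteinId}
#' @slot proteome named character vector, the full reference proteome
#' @slot log character vector of build messages (exclusions etc.)
#' @exportClass CoreOrthologueSet
setClass("CoreOrthologueSet",
  representation(referenceTaxon = "character", orthogroups = "list",
                 proteome = "character", log = "character"),
  validity = function(object) {
    ok <- vapply(object@orthogroups, function(g)
      all(c("profile", "refProtein", "refProteinId") %in% names(g)), logical(1))
    if (all(ok)) TRUE else "each orthogroup needs profile, refProtein, refProteinId"
  })

setMethod("show", "CoreOrthologueSet", function(object) {
  cat("CoreOrthologueSet:", length(object@orthogroups), "orthogroups,",
      "reference taxon", object@referenceTaxon, ",",
      length(object@proteome), "reference proteins\n")
})

#' @rdname CoreOrthologueSet-class
#' @param x a CoreOrthologueSet
#' @export
orthogroupIds <- function(x) names(x@orthogroups)

#' SuperMatrix: concatenated nucleotide alignment with column labels
#'
#' @slot seqs character matrix, rows = taxa, one character per cell; missing
#'   data as \code{-}
#' @slot labels data.frame with columns \code{orthogroup} and \code{codon_pos}
#'   (1/2/3), one row per alignment column
#' @exportClass SuperMatrix
setClass("SuperMatrix",
  representation(seqs = "matrix", labels = "data.frame"),
  validity = function(object) {
    if (ncol(object@seqs) != nrow(object@labels))
      return("labels must have one row per alignment column")
    if (!all(c("orthogroup", "codon_pos") %in% colnames(object@labels)))
      return("labels need columns orthogroup, codon_pos")
    TRUE
  })

setMethod("show", "SuperMatrix", function(object) {
  cat("SuperMatrix:", nrow(object@seqs), "taxa x", ncol(object@seqs), "columns,",
      sprintf("%.1f%% complete", completeness(object)), "\n")
})

#' @rdname SuperMatrix-class
#' @param seqs character matrix of aligned nucleotides (rows = taxa)
#' @param labels per-column data.frame (orthogroup, codon_pos)
#' @export
SuperMatrix <- function(seqs, labels) {
  new("SuperMatrix", seqs = seqs, labels = labels)
}

#' @rdname SuperMatrix-class
#' @param x a SuperMatrix
#' @export
superMatrixSeqs <- function(x) x@seqs

#' @rdname SuperMatrix-class
#' @export
columnLabels <- function(x) x@labels

setMethod("dim", "SuperMatrix", function(x) dim(x@seqs))

#' GTRParams: GTR+I+G substitution model parameters
#'
#' @slot rates six exchangeabilities in order AC, AG, AT, CG, CT, GT
#' @slot freqs base frequencies (A, C, G, T), sum 1
#' @slot pinv proportion of invariant sites in [0, 1)
#' @slot alpha gamma shape for among-site rate heterogeneity
#' @slot k number of discrete gamma categories
#' @exportClass GTRParams
setClass("GTRParams",
  representation(rates = "numeric", freqs = "numeric", pinv = "numeric",
                 alpha = "numeric", k = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(object@rates) != 6L || any(object@rates <= 0))
      msgs <- c(msgs, "need 6 positive exchangeabilities")
    if (length(object@freqs) != 4L || abs(sum(object@freqs) - 1) > 1e-8)
      msgs <- c(msgs, "freqs must be 4 values summing to 1")
    if (object@pinv < 0 || object@pinv >= 1)
      msgs <- c(msgs, "pinv must lie in [0, 1)")
    if (object@alpha <= 0) msgs <- c(msgs, "alpha must be positive")
    if (length(msgs)) msgs else TRUE
  })

#' @rdname GTRParams-class
#' @param rates six exchangeabilities (AC, AG, AT, CG, CT, GT)
#' @param freqs base frequencies (A, C, G, T)
#' @param pinv proportion of invariant sites
#' @param alpha gamma shape
#' @param k number of gamma categories
#' @export
gtrParams <- function(rates = rep(1, 6), freqs = rep(0.25, 4), pinv = 0,
                      alpha = 1, k = 4L) {
  new("GTRParams", rates = as.numeric(rates), freqs = as.numeric(freqs),
      pinv = as.numeric(pinv), alpha = as.numeric(alpha), k = as.integer(k))
}

setMethod("show", "GTRParams", function(object) {
  cat("GTR+I+G: rates", paste(signif(object@rates, 3), collapse = " "),
      "| pi", paste(signif(object@freqs, 3), collapse = " "),
      "| pinv", signif(object@pinv, 3), "| alpha", signif(object@alpha, 3),
      "|", object@k, "categories\n")
})

#' PartitionScheme: per-subset models over a shared topology
#'
#' Subsets (e.g. codon positions) share the tree topology and branch lengths;
#' each carries its own GTR+I+G parameters and a rate multiplier whose
#' data-weighted mean is 1.
#'
#' @slot subsetOf integer vector, per alignment column the subset index
#' @slot models list of \linkS4class{GTRParams}, one per subset
#' @slot multipliers per-subset branch-length rate multipliers
#' @exportClass PartitionScheme
setClass("PartitionScheme",
  representation(subsetOf = "integer", models = "list", multipliers = "numeric"),
  validity = function(object) {
    n <- length(object@models)
    if (length(object@multipliers) != n)
      return("one multiplier per subset required")
    if (max(object@subsetOf) > n) return("subsetOf indexes beyond models")
    TRUE
  })

#' @rdname PartitionScheme-class
#' @param subsetOf per-column subset index (1-based)
#' @param models list of GTRParams, one per subset
#' @param multipliers per-subset rate multipliers (default all 1)
#' @export
partitionScheme <- function(subsetOf, models,
                            multipliers = rep(1, length(models))) {
  new("PartitionScheme", subsetOf = as.integer(subsetOf), models = models,
      multipliers = as.numeric(multipliers))
}

#' TreeSearchResult: ML search output with bootstrap summaries
#'
#' @slot bestTree best ML tree (ape phylo, unrooted, branch lengths)
#' @slot logLik its log-likelihood
#' @slot replicates data.frame: replicate, logLik, seed
#' @slot model fitted model (GTRParams or PartitionScheme)
#' @slot bootstrapTrees list of ape phylo bootstrap trees
#' @slot consensus majority-rule consensus with support labels (or NULL)
#' @slot supportTree best tree annotated with bootstrap % node labels (or NULL)
#' @exportClass TreeSearchResult
setClass("TreeSearchResult",
  representation(bestTree = "ANY", logLik = "numeric", replicates = "data.frame",
                 model = "ANY", bootstrapTrees = "list", consensus = "ANY",
                 supportTree = "ANY"),
  validity = function(object) {
    if (nrow(object@replicates) &&
        abs(max(object@replicates$logLik) - object@logLik) > 1e-6)
      return("best logLik must equal the maximum over replicates")
    TRUE
  })

setMethod("show", "TreeSearchResult", function(object) {
  cat("TreeSearchResult: best lnL", sprintf("%.3f", object@logLik), "over",
      nrow(object@replicates), "replicates;",
      length(object@bootstrapTrees), "bootstrap trees\n")
})

#' @rdname TreeSearchResult-class
#' @param x a TreeSearchResult
#' @export
bestTree <- function(x) x@bestTree

#' @rdname TreeSearchResult-class
#' @export
bootstrapTrees <- function(x) x@bootstrapTrees
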