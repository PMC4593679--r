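# Custom log-odds substitution matrix from conserved gap-free alignment
# blocks, plus core-orthologue database construction.

# --- cluster utilities -------------------------------------------------------

#' Construct a sequence cluster
#'
#' A cluster is a list of aligned protein sequences (equal length, possibly
#' gapped) with taxon annotations; the lightweight container used by the
#' matrix-construction and database steps.
#'
#' @param id cluster identifier
#' @param taxa taxon of each member
#' @param seqIds sequence id of each member
#' @param seqs aligned sequences (character vector, equal lengths)
#' @return list with class "SequenceCluster"
#' @export
sequenceCluster <- function(id, taxa, seqIds, seqs) {
  seqs <- toupper(as.character(seqs))
  if (length(taxa) != length(seqs) || length(seqIds) != length(seqs))
    stop("taxa, seqIds and seqs must have equal length")
  if (length(seqs) == 0L) stop("cluster must have at least one member")
  if (length(unique(nchar(seqs))) != 1L)
    stop("cluster members must be aligned to equal length")
  structure(list(id = id, taxa = as.character(taxa),
                 seqIds = as.character(seqIds), seqs = setNames(seqs, seqIds)),
            class = "SequenceCluster")
}

#' Mean pairwise percent identity of an aligned cluster
#'
#' For each unordered pair of members, identity is the number of columns
#' where both sequences carry the same non-gap residue, divided by the
#' number of columns where both are non-gap. Pairs with no comparable
#' columns contribute 0. The cluster value is the unweighted mean over all
#' pairs, as a fraction in [0, 1].
#'
#' @param cluster a cluster (from \code{sequenceCluster} or a compatible list)
#' @return numeric scalar; NA for singleton clusters
#' @export
clusterPercentIdentity <- function(cluster) {
  seqs <- cluster$seqs
  n <- length(seqs)
  if (n < 2L) return(NA_real_)
  mat <- .seqsToMatrix(seqs)
  gap <- mat == "-" | mat == "." | mat == "X"
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- !gap[i, ] & !gap[j, ]
    nc <- sum(comp)
    vals <- c(vals, if (nc == 0L) 0 else sum(mat[i, comp] == mat[j, comp]) / nc)
  }
  mean(vals)
}

#' Filter clusters by membership and identity
#'
#' Keeps clusters with at least \code{minMembers} members and mean pairwise
#' identity of at least \code{minIdentity} (boundary inclusive: exactly 70
#' percent passes the default threshold).
#'
#' @param clusters list of clusters
#' @param minMembers minimum member count (default 2: singletons excluded)
#' @param minIdentity identity threshold as a fraction (default 0.70)
#' @return filtered list, with attribute "report" (data.frame of decisions)
#' @export
filterClusters <- function(clusters, minMembers = 2L, minIdentity = 0.70) {
  rep <- data.frame(cluster = vapply(clusters, `[[`, "", "id"),
                    members = vapply(clusters, function(x) length(x$seqs), 0L),
                    identity = vapply(clusters, clusterPercentIdentity, 0),
                    stringsAsFactors = FALSE)
  keep <- rep$members >= minMembers &
    (rep$members < 2L | rep$identity >= minIdentity)
  rep$kept <- keep
  structure(clusters[keep], report = rep)
}

#' Select the reference taxon
#'
#' The taxon present in the largest number of clusters. Ties are broken by
#' lexicographically smallest taxon id and flagged.
#'
#' @param clusters list of clusters
#' @return list(taxon, count, tie (logical), counts (named vector))
#' @export
selectReferenceTaxon <- function(clusters) {
  perCluster <- lapply(clusters, function(x) unique(x$taxa))
  counts <- sort(table(unlist(perCluster)), decreasing = TRUE)
  if (length(counts) == 0L) stop("no taxa present in clusters")
  top <- counts[counts == counts[1]]
  taxon <- sort(names(top))[1]
  list(taxon = taxon, count = unname(counts[1]), tie = length(top) > 1L,
       counts = counts)
}

# --- conserved block extraction ---------------------------------------------

#' Extract conserved gap-free blocks from a cluster alignment
#'
#' A column qualifies when no member has a gap and the most frequent residue
#' accounts for at least \code{minColumnConservation} of the members. Maximal
#' runs of at least \code{minBlockWidth} qualifying columns become blocks.
#' Column ranges are reported 0-based, half-open.
#'
#' @param cluster a cluster of at least 2 aligned members
#' @param minBlockWidth minimum run length in columns (default 10)
#' @param minColumnConservation majority-residue fraction threshold
#'   (default 0.5, boundary inclusive)
#' @return list of blocks: list(cluster, start, end, width, seqs (character
#'   matrix members x width), taxa)
#' @export
extractBlocks <- function(cluster, minBlockWidth = 10L,
                          minColumnConservation = 0.5) {
  seqs <- cluster$seqs
  if (length(seqs) < 2L) return(list())
  mat <- .seqsToMatrix(seqs)
  n <- nrow(mat)
  ok <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (any(col == "-" | col == ".")) return(FALSE)
    max(table(col)) / n >= minColumnConservation
  }, logical(1))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < minBlockWidth) next
    s <- starts[k]; e <- ends[k]
    out[[length(out) + 1L]] <- list(cluster = cluster$id, start = s - 1L,
                                    end = e, width = e - s + 1L,
                                    seqs = mat[, s:e, drop = FALSE],
                                    taxa = cluster$taxa)
  }
  out
}

# --- log-odds matrix ---------------------------------------------------------

# single-linkage clustering of block members at >= threshold identity;
# returns integer component id per member
.blockWeightClusters <- function(blockSeqs, threshold = 0.50) {
  n <- nrow(blockSeqs)
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ident <- mean(blockSeqs[i, ] == blockSeqs[j, ])
    if (ident >= threshold) {
      old <- comp[j]; new <- comp[i]
      comp[comp == old] <- new
    }
  }
  match(comp, unique(comp))
}

#' Compute a log-odds substitution matrix from conserved blocks
#'
#' Within each block, members are clustered by single-linkage at
#' \code{weightingIdentityThreshold} pairwise identity and each sequence is
#' weighted by the inverse of its cluster size, so near-identical sequences
#' do not dominate the counts. Per column, every unordered pair of distinct
#' sequences contributes the product of the two weights to the residue-pair
#' count. If any pair count is zero, one pseudocount is added to every cell
#' before normalisation. Scores are \code{round(log2(q_ij / e_ij) / scale)}
#' with target frequencies q, background-expected frequencies e, and
#' \code{scale = 0.5} (half-bit units) by default.
#'
#' Blocks with more than \code{maxBlockMembers} members are skipped with a
#' warning (the pairwise weighting step is quadratic in members).
#'
#' @param blocks list of blocks from \code{\link{extractBlocks}}
#' @param weightingIdentityThreshold single-linkage identity threshold
#'   (default 0.50)
#' @param scale score scale in bits (default 0.5)
#' @param maxBlockMembers guard on block member count (default 1000)
#' @param name matrix name stored in the result
#' @return a \linkS4class{SubstitutionMatrix}
#' @export
computeLogOddsMatrix <- function(blocks, weightingIdentityThreshold = 0.50,
                                 scale = 0.5, maxBlockMembers = 1000L,
                                 name = "CUSTOM") {
  if (length(blocks) == 0L) stop("no blocks supplied")
  aaIdx <- setNames(seq_along(AMINO_ACIDS), AMINO_ACIDS)
  f <- matrix(0, 20, 20, dimnames = list(AMINO_ACIDS, AMINO_ACIDS))
  nPositions <- 0L
  nUsed <- 0L
  for (b in blocks) {
    n <- nrow(b$seqs)
    if (n < 2L) next
    if (n > maxBlockMembers) {
      warning(sprintf("block in cluster %s has %d members (> %d); skipped",
                      b$cluster, n, maxBlockMembers))
      next
    }
    comp <- .blockWeightClusters(b$seqs, weightingIdentityThreshold)
    wts <- 1 / tabulate(comp)[comp]
    idxMat <- matrix(aaIdx[b$seqs], nrow = n)
    if (anyNA(idxMat)) stop("blocks must contain standard amino acids only")
    for (j in seq_len(ncol(idxMat))) {
      col <- idxMat[, j]
      for (a in seq_len(n - 1L)) {
        w <- wts[a] * wts[(a + 1L):n]
        tb <- col[(a + 1L):n]
        for (t in seq_along(tb)) {
          i1 <- col[a]; i2 <- tb[t]
          f[i1, i2] <- f[i1, i2] + w[t]
          if (i1 != i2) f[i2, i1] <- f[i2, i1] + w[t]
        }
      }
    }
    nPositions <- nPositions + ncol(idxMat)
    nUsed <- nUsed + 1L
  }
  if (nUsed == 0L) stop("no usable blocks (need >= 2 members each)")
  # f holds, per unordered pair {i,j}, the total weight: on the diagonal once,
  # off-diagonal mirrored into both cells. Fold to the half-count convention
  # so the full matrix sums to 1 and p = rowSums(q).
  q <- f
  q[upper.tri(q) | lower.tri(q)] <- q[upper.tri(q) | lower.tri(q)] / 2
  if (any(q == 0)) {
    q <- q + 1
  }
  q <- q / sum(q)
  p <- rowSums(q)
  e <- outer(p, p)
  s <- round(log2(q / e) / scale)
  mode(s) <- "integer"
  new("SubstitutionMatrix", name = name, scores = s, pairFreqs = q,
      margFreqs = p, scale = scale,
      nBlocks = as.integer(nUsed), nPositions = as.integer(nPositions))
}

#' Build the substitution matrix from a cluster set
#'
#' Convenience wrapper: filter clusters, extract blocks from every retained
#' cluster, and compute the log-odds matrix.
#'
#' @param clusters list of clusters
#' @param minMembers,minIdentity cluster filters (see \code{\link{filterClusters}})
#' @param minBlockWidth,minColumnConservation block extraction parameters
#' @param weightingIdentityThreshold,scale matrix parameters
#' @param name matrix name
#' @return a \linkS4class{SubstitutionMatrix} with attribute "blocks"
#' @export
buildSubstitutionMatrix <- function(clusters, minMembers = 2L,
                                    minIdentity = 0.70, minBlockWidth = 10L,
                                    minColumnConservation = 0.5,
                                    weightingIdentityThreshold = 0.50,
                                    scale = 0.5, name = "CUSTOM") {
  kept <- filterClusters(clusters, minMembers, minIdentity)
  blocks <- unlist(lapply(kept, extractBlocks, minBlockWidth = minBlockWidth,
                          minColumnConservation = minColumnConservation),
                   recursive = FALSE)
  m <- computeLogOddsMatrix(blocks,
                            weightingIdentityThreshold = weightingIdentityThreshold,
                            scale = scale, name = name)
  attr(m, "blocks") <- data.frame(
    cluster = vapply(blocks, `[[`, "", "cluster"),
    start = vapply(blocks, `[[`, 0L, "start"),
    end = vapply(blocks, `[[`, 0L, "end"),
    width = vapply(blocks, `[[`, 0L, "width"))
  m
}

# --- matrix I/O --------------------------------------------------------------

#' Write a scoring matrix in plain text
#'
#' Square whitespace-separated layout with a header row/column of residues,
#' preceded by '#' comment lines recording name, scale, and block counts.
#'
#' @param matrix a \linkS4class{SubstitutionMatrix}
#' @param path output file
#' @export
writeScoringMatrix <- function(matrix, path) {
  s <- scoreMatrix(matrix)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %s log-odds substitution matrix", matrix@name), con)
  writeLines(sprintf("# scale: %g bits per unit; blocks: %d; positions: %d",
                     matrix@scale, matrix@nBlocks, matrix@nPositions), con)
  writeLines(paste(c(" ", colnames(s)), collapse = " "), con)
  for (i in seq_len(nrow(s)))
    writeLines(paste(c(rownames(s)[i], s[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read a scoring matrix written by \code{\link{writeScoringMatrix}}
#'
#' @param path input file
#' @return integer score matrix with residue dimnames
#' @export
readScoringMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  s <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(hdr))))
  rownames(s) <- vapply(rows, `[[`, "", 1)
  colnames(s) <- hdr
  s
}

# --- core-orthologue database ------------------------------------------------

#' Build the core-orthologue database
#'
#' One orthogroup per cluster that contains the reference taxon: the profile
#' comes from the cluster alignment (see \code{\link{buildProfile}}) and the
#' reference protein is the cluster's reference-taxon member (longest if
#' several), stored ungapped. The reference proteome defaults to the union of
#' all reference members across clusters.
#'
#' @param clusters list of clusters (typically after \code{\link{filterClusters}})
#' @param referenceTaxon reference taxon id
#' @param proteome optional named character vector of reference proteins; when
#'   NULL it is assembled from the clusters
#' @param background background residue frequencies for profiles (default
#'   uniform 1/20)
#' @return a \linkS4class{CoreOrthologueSet}
#' @export
buildCoreOrthologueDb <- function(clusters, referenceTaxon, proteome = NULL,
                                  background = NULL) {
  ogs <- list()
  refSeqs <- character(0)
  for (cl in clusters) {
    hit <- which(cl$taxa == referenceTaxon)
    if (length(hit) == 0L) next
    degapped <- gsub("[-.]", "", cl$seqs[hit])
    best <- hit[which.max(nchar(degapped))]
    refId <- cl$seqIds[best]
    refProt <- gsub("[-.]", "", cl$seqs[best])
    ogs[[cl$id]] <- list(id = cl$id,
                         profile = buildProfile(cl$seqs, background = background),
                         refProteinId = refId, refProtein = unname(refProt),
                         nMembers = length(cl$seqs))
    refSeqs[refId] <- unname(refProt)
  }
  if (length(ogs) == 0L)
    stop("no cluster contains the reference taxon '", referenceTaxon, "'")
  if (is.null(proteome)) {
    proteome <- refSeqs
  } else {
    # an explicit proteome may use its own ids: re-point each orthogroup's
    # refProteinId at the proteome entry with the identical sequence
    for (ogId in names(ogs)) {
      if (ogs[[ogId]]$refProteinId %in% names(proteome)) next
      hit <- which(proteome == ogs[[ogId]]$refProtein)
      if (length(hit) == 0L)
        stop("reference protein of ", ogId, " is absent from the proteome")
      ogs[[ogId]]$refProteinId <- names(proteome)[hit[1]]
    }
  }
  new("CoreOrthologueSet", referenceTaxon = referenceTaxon,
      orthogroups = ogs, proteome = proteome)
}
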