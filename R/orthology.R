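# Orthology assignment: six-frame translation, position-specific profile
# search with empirically calibrated E-values, top-quartile filtering, and
# reciprocal-best-hit confirmation against the reference proteome.

# --- six-frame translation ---------------------------------------------------

#' Translate a transcript in all six reading frames
#'
#' Frames +1/+2/+3 read the forward strand at offsets 0/1/2; frames
#' -1/-2/-3 read the reverse complement likewise. Peptides are split at stop
#' codons (the stop is not emitted) and codons containing N or other
#' ambiguity translate to X unless the code is unambiguous. Each peptide
#' records, per residue, the 0-based nucleotide offset of its codon on the
#' frame's own strand (for '-' frames, coordinates on the reverse
#' complement).
#'
#' @param transcript nucleotide sequence (character scalar)
#' @param id transcript id recorded on every peptide
#' @param minPeptideLength drop peptides shorter than this many residues
#' @param geneticCode named character vector codon -> residue
#' @param revcomp optional precomputed reverse complement of
#'   \code{transcript} (uppercase), to avoid per-call overhead in batch use
#'   (default standard code)
#' @return data.frame: transcript, frame (+1..-3 as integer +-1,2,3),
#'   peptide, ntStart (0-based codon offset of the first residue on the
#'   frame's strand); attribute "strandSeqs" holds the two strand sequences
#' @export
sixFrameTranslate <- function(transcript, id = "tx",
                              minPeptideLength = 1L,
                              geneticCode = Biostrings::GENETIC_CODE,
                              revcomp = NULL) {
  transcript <- toupper(unname(transcript))
  strands <- c(`+` = transcript,
               `-` = if (is.null(revcomp)) .revcomp(transcript)
                     else unname(revcomp))
  frames <- integer(0); peptides <- character(0); ntStarts <- integer(0)
  for (sgn in c(1L, -1L)) {
    s <- strands[[if (sgn > 0) "+" else "-"]]
    n <- nchar(s)
    for (off in 0:2) {
      nCodon <- (n - off) %/% 3L
      if (nCodon < 1L) next
      starts <- off + 3L * (seq_len(nCodon) - 1L)
      codons <- substring(s, starts + 1L, starts + 3L)
      aa <- unname(geneticCode[codons])
      aa[is.na(aa)] <- "X"   # ambiguity / N-containing codons
      stop <- aa == "*"
      grp <- cumsum(stop)
      for (g in split(seq_len(nCodon)[!stop], grp[!stop])) {
        if (length(g) < minPeptideLength) next
        frames <- c(frames, sgn * (off + 1L))
        peptides <- c(peptides, paste0(aa[g], collapse = ""))
        ntStarts <- c(ntStarts, starts[g[1]])
      }
    }
  }
  out <- data.frame(transcript = rep_len(id, length(frames)), frame = frames,
                    peptide = peptides, ntStart = ntStarts,
                    stringsAsFactors = FALSE)
  attr(out, "strandSeqs") <- strands
  out
}

# --- profiles ----------------------------------------------------------------

#' Build a position-specific scoring profile from an aligned cluster
#'
#' Columns with more than 50 percent gaps are excluded from the profile
#' (their indices are recorded). Per retained column the score of residue a
#' is \code{log2(((n_a + pseudocount * bg_a) / (n + pseudocount)) / bg_a)}
#' where n_a counts occurrences among non-gap residues, n is the non-gap
#' total, and bg the background frequencies. A 21st row scores X (and any
#' non-standard residue) as 0.
#'
#' @param alignment named character vector or character matrix of aligned
#'   protein sequences
#' @param pseudocount total pseudocount mass (default 1)
#' @param background named residue frequencies (default uniform 1/20)
#' @param maxGapFraction columns with a gap fraction above this are dropped
#' @return list of class "ProfileModel": scores (21 x width matrix, rows
#'   AMINO_ACIDS + "X"), columns (source column indices), width, background,
#'   calibration (NULL until calibrated)
#' @export
buildProfile <- function(alignment, pseudocount = 1,
                         background = NULL, maxGapFraction = 0.5) {
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AMINO_ACIDS)
  mat <- if (is.matrix(alignment)) alignment else .seqsToMatrix(alignment)
  gapFrac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gapFrac <= maxGapFraction)
  if (length(keep) == 0L) stop("profile has no columns below the gap threshold")
  scores <- matrix(0, nrow = 21L, ncol = length(keep),
                   dimnames = list(c(AMINO_ACIDS, "X"), NULL))
  for (jj in seq_along(keep)) {
    col <- mat[, keep[jj]]
    col <- col[col %in% AMINO_ACIDS]
    n <- length(col)
    cnt <- table(factor(col, levels = AMINO_ACIDS))
    p <- (as.numeric(cnt) + pseudocount * background[AMINO_ACIDS]) /
      (n + pseudocount)
    scores[seq_len(20L), jj] <- log2(p / background[AMINO_ACIDS])
  }
  structure(list(scores = scores, columns = keep, width = length(keep),
                 background = background, calibration = NULL),
            class = "ProfileModel")
}

# map a peptide to 1-based row indices of a 21-row profile/score matrix
.pepIdx <- function(peptide) {
  i <- match(strsplit(peptide, "")[[1]], c(AMINO_ACIDS, "X"))
  i[is.na(i)] <- 21L
  i
}

# 0-based variant for the C++ batch kernels
.pepIdx0 <- function(peptide) .pepIdx(peptide) - 1L

# --- k-mer seed prefilter ----------------------------------------------------
# Exact-rescoring heuristic screen: a full Smith-Waterman is run only for
# (query, target) pairs sharing at least `minSeeds` exact k-mers; unseeded
# pairs are treated as no-hit. Any pair capable of reaching a significant
# local-alignment score shares exact k-mers, so reported scores are exact.

.kmers <- function(seq, k = 4L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# env mapping kmer -> integer indices of target sequences containing it
.kmerIndex <- function(targets, k = 4L) {
  env <- new.env(parent = emptyenv(), size = 4096L)
  for (i in seq_along(targets)) {
    for (km in .kmers(targets[[i]], k)) {
      env[[km]] <- c(env[[km]], i)
    }
  }
  env
}

# indices of targets sharing >= minSeeds distinct k-mers with the query
.seedCandidates <- function(query, index, k = 4L, minSeeds = 1L) {
  hits <- unlist(lapply(.kmers(query, k), function(km) index[[km]]),
                 use.names = FALSE)
  if (is.null(hits)) return(integer(0))
  tab <- tabulate(hits)
  which(tab >= minSeeds)
}

# consensus residue string of a profile (argmax score per column)
.profileConsensus <- function(profile) {
  paste0(AMINO_ACIDS[apply(profile$scores[seq_len(20L), , drop = FALSE],
                           2L, which.max)], collapse = "")
}

#' Score a peptide against a profile
#'
#' Smith-Waterman local alignment of the peptide against the profile
#' columns with affine gaps (defaults: open 11, extend 1, so a gap of
#' length k costs 11 + k). Returns the best local score and, optionally,
#' the aligned spans.
#'
#' @param peptide character scalar
#' @param profile a ProfileModel
#' @param gapOpen,gapExtend affine gap penalties (positive numbers)
#' @param align when TRUE also return the traceback spans
#' @return list(score, and when align: qstart/qend/tstart/tend 1-based
#'   inclusive, pairs (matrix of matched peptide/profile positions))
#' @export
profileSearch <- function(peptide, profile, gapOpen = 11, gapExtend = 1,
                          align = FALSE) {
  idx <- .pepIdx(peptide)
  if (!align) {
    sc <- .profile_score_batch(list(idx - 1L), profile$scores, gapOpen, gapExtend)
    return(list(score = sc[1]))
  }
  S <- profile$scores[idx, , drop = FALSE]
  .sw_align_scores(S, gapOpen, gapExtend)
}

# --- E-value calibration -----------------------------------------------------

#' Calibrate a Gumbel E-value model for a profile
#'
#' Scores random decoy peptides (drawn i.i.d. from the profile's background
#' frequencies) against the profile and fits a Gumbel (type-I extreme value)
#' distribution to the local-alignment scores by maximum likelihood. The
#' E-value of a hit with score s in a search of \code{searchSpace} sequences
#' is \code{searchSpace * exp(-(s - mu) / beta)} (the Gumbel upper tail).
#'
#' @param profile a ProfileModel
#' @param nDecoys number of decoys (default 200)
#' @param decoyLength decoy length in residues (default 150)
#' @param gapOpen,gapExtend affine gap penalties
#' @param seed integer seed
#' @return the profile with \code{calibration = list(mu, beta, nDecoys,
#'   decoyLength)}
#' @export
calibrateEvalue <- function(profile, nDecoys = 200L, decoyLength = 150L,
                            gapOpen = 11, gapExtend = 1, seed = 1L) {
  bg <- profile$background
  decoys <- withr::with_seed(seed, lapply(seq_len(nDecoys), function(i)
    match(sample(AMINO_ACIDS, decoyLength, replace = TRUE, prob = bg),
          c(AMINO_ACIDS, "X")) - 1L))
  scores <- .profile_score_batch(decoys, profile$scores, gapOpen, gapExtend)
  profile$calibration <- c(.fitGumbel(scores),
                           list(nDecoys = nDecoys, decoyLength = decoyLength))
  profile
}

# maximum-likelihood Gumbel fit; moment start, Nelder-Mead refinement
.fitGumbel <- function(x) {
  if (length(unique(x)) < 3L)
    stop("degenerate decoy score distribution; cannot calibrate")
  beta0 <- sqrt(6) * sd(x) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0
  nll <- function(p) {
    beta <- exp(p[2])
    z <- (x - p[1]) / beta
    length(x) * log(beta) + sum(z + exp(-z))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  list(mu = fit$par[1], beta = exp(fit$par[2]))
}

#' E-value of a profile-search score
#'
#' @param score local alignment score(s)
#' @param profile calibrated ProfileModel
#' @param searchSpace number of sequences searched (linear scaling)
#' @return numeric E-value(s)
#' @export
profileEvalue <- function(score, profile, searchSpace = 1) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated; run calibrateEvalue()")
  searchSpace * exp(-(score - cal$mu) / cal$beta)
}

# --- provisional assignment --------------------------------------------------

#' Provisional orthogroup assignment by profile search
#'
#' Every peptide is scored against every orthogroup profile. Hits are first
#' filtered to E-value <= \code{evalueCutoff}; then, per orthogroup, only
#' the top-scoring quartile survives: with n retained hits the
#' \code{ceiling(n * quartile)} best scores are kept, and hits tied with the
#' boundary score are kept as well. When several reading frames of the same
#' transcript hit the same orthogroup, only the best-scoring frame is kept.
#'
#' @param peptides data.frame from \code{\link{sixFrameTranslate}} (columns
#'   transcript, frame, peptide, ntStart) plus a unique \code{peptide_id}
#'   column (added when absent)
#' @param db a \linkS4class{CoreOrthologueSet} with calibrated profiles
#' @param evalueCutoff E-value threshold (default 1e-5)
#' @param quartile fraction of hits kept per orthogroup (default 0.25)
#' @param gapOpen,gapExtend affine gap penalties
#' @param searchSpace search-space size for E-values (default: number of
#'   peptides)
#' @param seedFilter run the full alignment only for peptide/profile pairs
#'   sharing at least \code{minSeeds} exact k-mers with the profile's
#'   consensus sequence. The prefilter trades a little sensitivity on very
#'   divergent pairs for speed; reported scores stay exact Smith-Waterman.
#'   Set \code{seedFilter = FALSE} for an exhaustive search.
#' @param seedK,minSeeds prefilter parameters
#' @return data.frame of provisional hits: peptide_id, transcript, frame,
#'   orthogroup, score, evalue
#' @export
assignProvisional <- function(peptides, db, evalueCutoff = 1e-5,
                              quartile = 0.25, gapOpen = 11, gapExtend = 1,
                              searchSpace = NULL, seedFilter = TRUE,
                              seedK = 5L, minSeeds = 2L) {
  if (nrow(peptides) == 0L) return(.emptyHits())
  if (is.null(peptides$peptide_id))
    peptides$peptide_id <- sprintf("p%05d", seq_len(nrow(peptides)))
  if (is.null(searchSpace)) searchSpace <- nrow(peptides)
  idxList <- lapply(peptides$peptide, .pepIdx0)
  ogIds <- names(db@orthogroups)
  if (seedFilter) {
    cons <- vapply(db@orthogroups, function(g) .profileConsensus(g$profile),
                   character(1))
    index <- .kmerIndex(cons, seedK)
    candOf <- lapply(peptides$peptide, .seedCandidates, index = index,
                     k = seedK, minSeeds = minSeeds)
    pepOfOg <- split(rep(seq_along(candOf), lengths(candOf)),
                     factor(unlist(candOf), levels = seq_along(ogIds)))
  } else {
    pepOfOg <- rep(list(seq_len(nrow(peptides))), length(ogIds))
  }
  hits <- list()
  for (oi in seq_along(ogIds)) {
    ogId <- ogIds[oi]
    cand <- pepOfOg[[oi]]
    if (length(cand) == 0L) next
    prof <- db@orthogroups[[ogId]]$profile
    if (is.null(prof$calibration))
      stop("profile for ", ogId, " is not calibrated")
    sc <- .profile_score_batch(idxList[cand], prof$scores, gapOpen, gapExtend)
    ev <- profileEvalue(sc, prof, searchSpace)
    keep <- which(ev <= evalueCutoff)
    if (length(keep) == 0L) next
    rows <- cand[keep]
    h <- data.frame(peptide_id = peptides$peptide_id[rows],
                    transcript = peptides$transcript[rows],
                    frame = peptides$frame[rows],
                    orthogroup = ogId, score = sc[keep], evalue = ev[keep],
                    stringsAsFactors = FALSE)
    # top quartile with boundary ties
    n <- nrow(h)
    kTop <- ceiling(n * quartile)
    boundary <- sort(h$score, decreasing = TRUE)[kTop]
    h <- h[h$score >= boundary, , drop = FALSE]
    # per transcript keep the best frame only
    h <- h[order(-h$score, h$peptide_id), , drop = FALSE]
    h <- h[!duplicated(h$transcript), , drop = FALSE]
    hits[[ogId]] <- h
  }
  if (length(hits) == 0L) return(.emptyHits())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

.emptyHits <- function() {
  data.frame(peptide_id = character(), transcript = character(),
             frame = integer(), orthogroup = character(), score = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

# --- reciprocal best hit -----------------------------------------------------

#' Calibrate E-values for proteome-wide best-hit scores
#'
#' Decoy peptides are aligned against every reference protein; the per-decoy
#' best score is fitted with a Gumbel distribution. Because the maximum is
#' taken over the whole proteome, the resulting E-value needs no further
#' search-space scaling.
#'
#' @param db a \linkS4class{CoreOrthologueSet}
#' @param matrix a \linkS4class{SubstitutionMatrix}
#' @param nDecoys,decoyLength decoy parameters
#' @param gapOpen,gapExtend affine gap penalties
#' @param seed integer seed
#' @return list(mu, beta, nDecoys, decoyLength)
#' @export
calibrateProteomeEvalue <- function(db, matrix, nDecoys = 200L,
                                    decoyLength = 150L, gapOpen = 11,
                                    gapExtend = 1, seed = 1L) {
  bg <- matrix@margFreqs
  decoys <- withr::with_seed(seed, vapply(seq_len(nDecoys), function(i)
    paste0(sample(AMINO_ACIDS, decoyLength, replace = TRUE, prob = bg),
           collapse = ""), character(1)))
  sc <- .swScoresVsProteome(decoys, db@proteome, matrix, gapOpen, gapExtend)
  best <- apply(sc, 1L, max)
  c(.fitGumbel(best), list(nDecoys = nDecoys, decoyLength = decoyLength))
}

# score matrix queries x proteome via the batch C++ kernel; the 21st
# row/column scores X as 0. With seedFilter, only proteins sharing at least
# minSeeds exact k-mers with the query are aligned; others score 0.
.swScoresVsProteome <- function(queries, proteome, matrix, gapOpen, gapExtend,
                                seedFilter = FALSE, seedK = 4L, minSeeds = 1L) {
  M <- rbind(cbind(scoreMatrix(matrix), X = 0L), X = 0L)
  t <- lapply(proteome, .pepIdx0)
  if (!seedFilter) {
    q <- lapply(queries, .pepIdx0)
    sc <- .sw_score_batch(q, t, M, gapOpen, gapExtend, TRUE)
    return(matrix(sc, nrow = length(q), byrow = TRUE,
                  dimnames = list(names(queries), names(proteome))))
  }
  index <- .kmerIndex(proteome, seedK)
  out <- matrix(0, nrow = length(queries), ncol = length(proteome),
                dimnames = list(names(queries), names(proteome)))
  for (i in seq_along(queries)) {
    cand <- .seedCandidates(queries[[i]], index, seedK, minSeeds)
    if (length(cand) == 0L) next
    out[i, cand] <- .sw_score_batch(list(.pepIdx0(queries[[i]])), t[cand],
                                    M, gapOpen, gapExtend, TRUE)
  }
  out
}

#' Reciprocal-best-hit confirmation
#'
#' Each provisionally assigned peptide is aligned (Smith-Waterman, affine
#' gaps, custom substitution matrix) against the entire reference proteome.
#' The hit is confirmed when the best-scoring reference protein is the
#' assigned orthogroup's reference protein and the best-hit E-value is at
#' most \code{evalueCutoff}. Score ties for the best protein count as
#' confirmation only if the orthogroup's protein is among the tied best.
#'
#' @param hits data.frame from \code{\link{assignProvisional}}
#' @param peptides the peptide table the hits refer to
#' @param db a \linkS4class{CoreOrthologueSet}
#' @param matrix a \linkS4class{SubstitutionMatrix}
#' @param evalueCutoff E-value threshold (default 1e-5)
#' @param gapOpen,gapExtend affine gap penalties
#' @param calibration optional precomputed result of
#'   \code{\link{calibrateProteomeEvalue}} (computed on the fly otherwise)
#' @param seed seed for on-the-fly calibration
#' @return hits with added columns best_protein, rbh_score, rbh_evalue,
#'   confirmed (logical)
#' @export
reciprocalBestHit <- function(hits, peptides, db, matrix, evalueCutoff = 1e-5,
                              gapOpen = 11, gapExtend = 1, calibration = NULL,
                              seed = 1L) {
  if (nrow(hits) == 0L) {
    hits$best_protein <- character(0); hits$rbh_score <- numeric(0)
    hits$rbh_evalue <- numeric(0); hits$confirmed <- logical(0)
    return(hits)
  }
  if (is.null(calibration))
    calibration <- calibrateProteomeEvalue(db, matrix, gapOpen = gapOpen,
                                           gapExtend = gapExtend, seed = seed)
  peps <- setNames(peptides$peptide, peptides$peptide_id)
  uniq <- unique(hits$peptide_id)
  sc <- .swScoresVsProteome(setNames(peps[uniq], uniq), db@proteome,
                            matrix, gapOpen, gapExtend, seedFilter = TRUE,
                            seedK = 5L, minSeeds = 2L)
  bestScore <- apply(sc, 1L, max)
  hits$rbh_score <- bestScore[hits$peptide_id]
  hits$rbh_evalue <- exp(-(hits$rbh_score - calibration$mu) / calibration$beta)
  refIds <- vapply(db@orthogroups, `[[`, "", "refProteinId")
  hits$best_protein <- colnames(sc)[max.col(sc, ties.method = "first")][
    match(hits$peptide_id, rownames(sc))]
  isBest <- vapply(seq_len(nrow(hits)), function(i) {
    row <- sc[hits$peptide_id[i], ]
    ref <- refIds[[hits$orthogroup[i]]]
    ref %in% names(row)[row == max(row)]
  }, logical(1))
  hits$confirmed <- isBest & hits$rbh_evalue <= evalueCutoff
  hits
}

# --- orchestration -----------------------------------------------------------

#' Assign transcript fragments to orthogroups
#'
#' Runs the full assignment chain: six-frame translation of every transcript
#' at least \code{minContigBp} long, profile search with E-value and
#' top-quartile filters, and reciprocal-best-hit confirmation. When a
#' transcript's confirmed hits cover several orthogroups, the hit with the
#' smallest profile E-value wins (ties: higher score, then orthogroup id).
#'
#' @param transcripts named character vector of nucleotide sequences
#' @param db a \linkS4class{CoreOrthologueSet} with calibrated profiles
#' @param matrix a \linkS4class{SubstitutionMatrix}
#' @param minContigBp minimum transcript length in bp (default 200)
#' @param minPeptideLength minimum translated peptide length (default 30)
#' @param evalueCutoff profile E-value cutoff (default 1e-5)
#' @param rbhEvalueCutoff reciprocal-best-hit E-value cutoff (default 1e-5)
#' @param quartile top-score fraction kept per orthogroup (default 0.25)
#' @param gapOpen,gapExtend affine gap penalties (defaults 11, 1)
#' @param seed integer seed (proteome calibration decoys)
#' @param calibration optional precomputed
#'   \code{\link{calibrateProteomeEvalue}} result, reused across calls
#' @return list: assignments (one row per confirmed transcript: transcript,
#'   orthogroup, frame, peptide_id, score, evalue, rbh columns), peptides
#'   (full peptide table with ntStart and strand sequences context),
#'   provisional (pre-RBH hit table)
#' @export
assignOrthologs <- function(transcripts, db, matrix, minContigBp = 200L,
                            minPeptideLength = 30L, evalueCutoff = 1e-5,
                            rbhEvalueCutoff = 1e-5, quartile = 0.25,
                            gapOpen = 11, gapExtend = 1, seed = 1L,
                            calibration = NULL) {
  transcripts <- transcripts[nchar(transcripts) >= minContigBp]
  if (length(transcripts) == 0L)
    return(list(assignments = .emptyHits(), peptides = NULL,
                provisional = .emptyHits()))
  rcs <- .revcomp(toupper(transcripts))  # one vectorised call for all
  pepList <- lapply(names(transcripts), function(id)
    sixFrameTranslate(transcripts[[id]], id = id,
                      minPeptideLength = minPeptideLength,
                      revcomp = rcs[[id]]))
  peptides <- do.call(rbind, pepList)
  if (nrow(peptides) == 0L)
    return(list(assignments = .emptyHits(), peptides = peptides,
                provisional = .emptyHits()))
  peptides$peptide_id <- sprintf("p%06d", seq_len(nrow(peptides)))
  prov <- assignProvisional(peptides, db, evalueCutoff = evalueCutoff,
                            quartile = quartile, gapOpen = gapOpen,
                            gapExtend = gapExtend)
  conf <- reciprocalBestHit(prov, peptides, db, matrix,
                            evalueCutoff = rbhEvalueCutoff, gapOpen = gapOpen,
                            gapExtend = gapExtend, seed = seed,
                            calibration = calibration)
  conf <- conf[conf$confirmed, , drop = FALSE]
  # one orthogroup per transcript: smallest E, then highest score, then og id
  conf <- conf[order(conf$transcript, conf$evalue, -conf$score,
                     conf$orthogroup), , drop = FALSE]
  conf <- conf[!duplicated(conf$transcript), , drop = FALSE]
  rownames(conf) <- NULL
  list(assignments = conf, peptides = peptides, provisional = prov)
}

#' Assign orthologs one taxon's transcriptome at a time
#'
#' Runs \code{\link{assignOrthologs}} separately per taxon, mirroring the
#' one-transcriptome-per-search workflow the quartile filter assumes: the
#' top-quartile retention then selects among one taxon's redundant
#' transcripts per orthogroup rather than discarding whole taxa. The
#' proteome E-value calibration is computed once and shared.
#'
#' @param transcriptsByTaxon named list: per taxon a named character vector
#'   of transcripts
#' @param db,matrix,... forwarded to \code{\link{assignOrthologs}}
#' @param seed master seed (one child seed per taxon, one for calibration)
#' @return list(assignments, peptides, provisional) with per-taxon
#'   peptide-id prefixes and an added \code{taxon} column
#' @export
assignOrthologsPerTaxon <- function(transcriptsByTaxon, db, matrix, ...,
                                    seed = 1L) {
  calibration <- calibrateProteomeEvalue(db, matrix,
                                         seed = childSeed(seed, 999L))
  parts <- lapply(seq_along(transcriptsByTaxon), function(i) {
    tx <- names(transcriptsByTaxon)[i]
    a <- assignOrthologs(transcriptsByTaxon[[i]], db, matrix, ...,
                         seed = childSeed(seed, i), calibration = calibration)
    for (nm in c("assignments", "provisional"))
      if (nrow(a[[nm]])) {
        a[[nm]]$peptide_id <- paste0(tx, ":", a[[nm]]$peptide_id)
        a[[nm]]$taxon <- tx
      }
    if (!is.null(a$peptides) && nrow(a$peptides)) {
      a$peptides$peptide_id <- paste0(tx, ":", a$peptides$peptide_id)
      a$peptides$taxon <- tx
    }
    a
  })
  bindNonEmpty <- function(nm) {
    tabs <- Filter(function(x) !is.null(x) && nrow(x) > 0L,
                   lapply(parts, `[[`, nm))
    if (length(tabs)) do.call(rbind, tabs) else .emptyHits()
  }
  out <- list(assignments = bindNonEmpty("assignments"),
              peptides = bindNonEmpty("peptides"),
              provisional = bindNonEmpty("provisional"))
  rownames(out$assignments) <- NULL
  out
}

#' Calibrate every profile in a database
#'
#' @param db a \linkS4class{CoreOrthologueSet}
#' @param nDecoys,decoyLength,gapOpen,gapExtend see \code{\link{calibrateEvalue}}
#' @param seed master seed; each profile uses a derived child seed
#' @return the database with calibrated profiles
#' @export
calibrateDatabase <- function(db, nDecoys = 200L, decoyLength = 150L,
                              gapOpen = 11, gapExtend = 1, seed = 1L) {
  ids <- names(db@orthogroups)
  for (i in seq_along(ids)) {
    og <- db@orthogroups[[ids[i]]]
    og$profile <- calibrateEvalue(og$profile, nDecoys = nDecoys,
                                  decoyLength = decoyLength, gapOpen = gapOpen,
                                  gapExtend = gapExtend,
                                  seed = childSeed(seed, i))
    db@orthogroups[[ids[i]]] <- og
  }
  db
}
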