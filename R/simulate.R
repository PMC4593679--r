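# Synthetic-data generator: species trees, gene families with duplication
# and loss, protein-coding sequences with synonymous/non-synonymous dynamics
# and among-site rate heterogeneity, transcript fragmentation, and reference
# cluster sets -- all with recorded ground truth.

#' SimulationConfig: parameters of the synthetic transcriptome world
#'
#' Defaults describe a 20-taxon study: one reference-like taxon plus 19
#' ingroup taxa, moderate divergence, occasional duplication/loss, and
#' per-taxon missingness that yields sparse supermatrices.
#'
#' @slot nTaxa number of taxa (>= 3)
#' @slot birthRate pure-birth (Yule) speciation rate
#' @slot treeHeight root-to-tip height of the species tree, in expected
#'   non-synonymous substitutions per amino-acid site
#' @slot dupRate,lossRate per-lineage per-unit-height duplication/loss rates
#'   on the species tree
#' @slot nOrthogroups number of gene families
#' @slot geneLength gene length in codons
#' @slot gtrRates,baseFreqs nucleotide model used to describe the data (the
#'   generator evolves amino acids plus synonymous codon resampling; these
#'   feed the model used for inference defaults)
#' @slot gammaShape shape of the gamma distribution of site rates
#' @slot pInvariant probability a site is invariant
#' @slot synonymousRateMultiplier rate multiplier of synonymous codon
#'   resampling relative to the site's non-synonymous rate
#' @slot fragmentLengthRange min/max fragment length (bp) drawn per transcript
#' @slot minFragmentLength assembled-contig floor (bp, >= 200)
#' @slot utrLength length of random non-coding padding on each transcript end
#' @slot taxonDropout probability that a (taxon, orthogroup) pair is missing
#'   from the transcript set altogether
#' @slot shortGenePolicy "whole" emits genes shorter than the fragment draw
#'   in full; "skip" drops them (flag recorded either way)
#' @slot seed master seed; per-stage child seeds derive from it
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nTaxa = "integer", birthRate = "numeric", treeHeight = "numeric",
                 dupRate = "numeric", lossRate = "numeric",
                 nOrthogroups = "integer", geneLength = "integer",
                 gtrRates = "numeric", baseFreqs = "numeric",
                 gammaShape = "numeric", pInvariant = "numeric",
                 synonymousRateMultiplier = "numeric",
                 fragmentLengthRange = "integer", minFragmentLength = "integer",
                 utrLength = "integer", taxonDropout = "numeric",
                 shortGenePolicy = "character", seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@nTaxa < 3L) msgs <- c(msgs, "nTaxa must be >= 3")
    if (abs(sum(object@baseFreqs) - 1) > 1e-12)
      msgs <- c(msgs, "baseFreqs must sum to 1 within 1e-12")
    if (object@minFragmentLength < 200L)
      msgs <- c(msgs, "minFragmentLength must be >= 200 bp")
    if (any(c(object@birthRate, object@treeHeight, object@gammaShape,
              object@synonymousRateMultiplier) <= 0))
      msgs <- c(msgs, "rates and scales must be positive")
    if (object@dupRate < 0 || object@lossRate < 0)
      msgs <- c(msgs, "dupRate/lossRate must be non-negative")
    if (object@pInvariant < 0 || object@pInvariant >= 1)
      msgs <- c(msgs, "pInvariant must lie in [0, 1)")
    if (object@taxonDropout < 0 || object@taxonDropout >= 1)
      msgs <- c(msgs, "taxonDropout must lie in [0, 1)")
    if (length(msgs)) msgs else TRUE
  })

#' @rdname SimulationConfig-class
#' @param nTaxa,birthRate,treeHeight,dupRate,lossRate,nOrthogroups,geneLength
#'   see slots
#' @param gtrRates,baseFreqs,gammaShape,pInvariant,synonymousRateMultiplier
#'   see slots
#' @param fragmentLengthRange,minFragmentLength,utrLength,taxonDropout see slots
#' @param shortGenePolicy,seed see slots
#' @export
simulationConfig <- function(nTaxa = 20L, birthRate = 1.0, treeHeight = 0.4,
                             dupRate = 0.02, lossRate = 0.02,
                             nOrthogroups = 100L, geneLength = 300L,
                             gtrRates = c(1, 2, 1, 1, 2, 1),
                             baseFreqs = c(0.3, 0.2, 0.2, 0.3),
                             gammaShape = 0.8, pInvariant = 0.2,
                             synonymousRateMultiplier = 5,
                             fragmentLengthRange = c(300L, 900L),
                             minFragmentLength = 200L, utrLength = 30L,
                             taxonDropout = 0.15,
                             shortGenePolicy = c("whole", "skip"),
                             seed = 1L) {
  new("SimulationConfig", nTaxa = as.integer(nTaxa), birthRate = birthRate,
      treeHeight = treeHeight, dupRate = dupRate, lossRate = lossRate,
      nOrthogroups = as.integer(nOrthogroups), geneLength = as.integer(geneLength),
      gtrRates = gtrRates, baseFreqs = baseFreqs, gammaShape = gammaShape,
      pInvariant = pInvariant,
      synonymousRateMultiplier = synonymousRateMultiplier,
      fragmentLengthRange = as.integer(fragmentLengthRange),
      minFragmentLength = as.integer(minFragmentLength),
      utrLength = as.integer(utrLength), taxonDropout = taxonDropout,
      shortGenePolicy = match.arg(shortGenePolicy), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nTaxa, "taxa,", object@nOrthogroups,
      "orthogroups of", object@geneLength, "codons; height", object@treeHeight,
      "; dup/loss", object@dupRate, "/", object@lossRate,
      "; dropout", object@taxonDropout, "; seed", object@seed, "\n")
})

#' Simulate a species tree
#'
#' Pure-birth (Yule) tree, made ultrametric by construction, rescaled to the
#' requested root-to-tip height. Tip labels are t01, t02, ...
#'
#' @param nTaxa number of taxa (>= 3)
#' @param birthRate speciation rate
#' @param seed integer seed (same seed, same Newick string)
#' @param height root-to-tip height after rescaling
#' @return rooted ultrametric phylo tree
#' @export
simulateSpeciesTree <- function(nTaxa, birthRate = 1.0, seed = 1L, height = 0.4) {
  if (nTaxa < 3L) stop("nTaxa must be >= 3")
  tr <- withr::with_seed(seed, {
    t0 <- ape::rphylo(nTaxa, birth = birthRate, death = 0)
    # Respace the speciation events: keep the birth-process topology and the
    # relative order of divergences, but place node ages on a jittered grid
    # between 0.15*height and height.  This guarantees every internal branch
    # a minimum length (about 0.7 * 0.85*height/(nTaxa-2)), so the ground
    # truth is identifiable: a benchmark tree with a near-zero internal
    # branch cannot be recovered by any method and would only measure noise.
    m <- nTaxa - 1L                       # internal nodes, rooted ultrametric
    depth <- ape::node.depth.edgelength(t0)
    h0 <- max(depth)
    age <- h0 - depth[(nTaxa + 1L):(nTaxa + m)]
    rk <- rank(age, ties.method = "first")
    lo <- 0.15
    step <- if (m > 1L) (1 - lo) * height / (m - 1L) else 0
    newAge <- lo * height + (rk - 1L) * step +
      if (m > 1L) runif(m, -0.15, 0.15) * step else 0
    newAge[rk == m] <- height              # root sits exactly at `height`
    allAge <- c(rep(0, nTaxa), newAge)
    t0$edge.length <- allAge[t0$edge[, 1]] - allAge[t0$edge[, 2]]
    t0
  })
  tr$tip.label <- sprintf("t%02d", seq_len(nTaxa))
  tr
}

# --- gene families with duplication and loss --------------------------------

# One copy entering a branch of length t; returns a list-tree:
# list(kind = "leaf"/"node", len, children = list(...), taxon)
.evolveCopy <- function(tree, node, tIn, dup, loss, state) {
  # events on the remaining branch above `node` of length tIn
  tLeft <- tIn
  consumed <- 0
  total <- dup + loss
  while (total > 0) {
    dt <- rexp(1, total)
    if (dt >= tLeft) break
    consumed <- consumed + dt
    tLeft <- tLeft - dt
    if (runif(1) < dup / total) {
      left <- .evolveCopy(tree, node, tLeft, dup, loss, state)
      right <- .evolveCopy(tree, node, tLeft, dup, loss, state)
      kids <- Filter(Negate(is.null), list(left, right))
      if (length(kids) == 0L) return(NULL)
      if (length(kids) == 1L) {
        kids[[1]]$len <- kids[[1]]$len + consumed
        return(kids[[1]])
      }
      return(list(kind = "node", len = consumed, children = kids, event = "dup"))
    } else return(NULL) # loss
  }
  # reached the node
  nTip <- length(tree$tip.label)
  if (node <= nTip) {
    taxon <- tree$tip.label[node]
    state$counts[[taxon]] <- (state$counts[[taxon]] %||% 0L) + 1L
    return(list(kind = "leaf", len = tIn - consumed + consumed, # = tIn
                taxon = taxon, label = sprintf("%s__%d", taxon, state$counts[[taxon]])))
  }
  kidsIdx <- which(tree$edge[, 1] == node)
  kids <- list()
  for (ki in kidsIdx) {
    ch <- .evolveCopy(tree, tree$edge[ki, 2], tree$edge.length[ki], dup, loss, state)
    if (!is.null(ch)) kids <- c(kids, list(ch))
  }
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) {
    kids[[1]]$len <- kids[[1]]$len + tIn
    return(kids[[1]])
  }
  list(kind = "node", len = tIn, children = kids, event = "spec")
}

.listTreeToNewick <- function(x) {
  if (x$kind == "leaf") return(sprintf("%s:%.8f", x$label, x$len))
  inner <- paste(vapply(x$children, .listTreeToNewick, character(1)), collapse = ",")
  sprintf("(%s):%.8f", inner, x$len)
}

#' Simulate a gene family along a species tree
#'
#' A single gene copy enters at the root; along every branch each copy
#' duplicates at rate \code{dupRate} and is lost at rate \code{lossRate}
#' (per unit branch length). Leaves are labelled \code{taxon__copy}. With
#' both rates zero the gene tree is topologically identical to the species
#' tree.
#'
#' @param speciesTree rooted phylo species tree
#' @param dupRate,lossRate non-negative event rates
#' @param seed integer seed
#' @return a phylo gene tree, or NULL if every copy was lost
#' @export
simulateGeneFamily <- function(speciesTree, dupRate = 0.1, lossRate = 0.1,
                               seed = 1L) {
  if (dupRate < 0 || lossRate < 0) stop("rates must be non-negative")
  withr::with_seed(seed, {
    state <- new.env()
    state$counts <- list()
    root <- length(speciesTree$tip.label) + 1L
    lt <- .evolveCopy(speciesTree, root, 0, dupRate, lossRate, state)
    if (is.null(lt)) return(NULL)
    if (lt$kind == "leaf") return(NULL) # single surviving copy, no tree
    nwk <- paste0(.listTreeToNewick(lt), ";")
    tr <- ape::read.tree(text = nwk)
    tr
  })
}

.leafTaxon <- function(labels) sub("__.*$", "", labels)

# --- coding-sequence evolution ----------------------------------------------

.codonTable <- local({
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  fam <- split(names(sense), sense)          # AA -> codons
  list(code = gc, sense = sense, families = fam,
       aas = names(fam))
})

#' Evolve protein-coding sequences along a gene tree
#'
#' Sites are codons. Each site draws a rate: 0 with probability
#' \code{pInvariant}, otherwise Gamma(shape, rate = shape). Along a branch of
#' length t a site experiences Poisson(t * r) non-synonymous events (the
#' amino acid jumps to a random different residue and a random codon of that
#' residue is chosen) and Poisson(t * r * synonymousRateMultiplier)
#' synonymous events (codon resampled within the current residue's family).
#' No internal stop codons can arise.
#'
#' @param geneTree phylo tree with branch lengths (leaf labels become
#'   sequence names)
#' @param config a \linkS4class{SimulationConfig}
#' @param seed integer seed
#' @return list(sequences = named character CDS vector, siteRates = numeric,
#'   rootProtein = character)
#' @export
evolveCodingSequences <- function(geneTree, config, seed = 1L) {
  L <- config@geneLength
  if (L < 10L) stop("geneLength must be >= 10 codons")
  fam <- .codonTable$families
  aas <- .codonTable$aas
  withr::with_seed(seed, {
    rates <- ifelse(runif(L) < config@pInvariant, 0,
                    rgamma(L, shape = config@gammaShape, rate = config@gammaShape))
    rootAA <- sample(aas, L, replace = TRUE)
    rootCodon <- vapply(rootAA, function(a) sample(fam[[a]], 1L), character(1))
    tr <- reorder(geneTree, "cladewise")
    nNode <- max(tr$edge)
    aaState <- vector("list", nNode)
    cdState <- vector("list", nNode)
    root <- length(tr$tip.label) + 1L
    aaState[[root]] <- rootAA; cdState[[root]] <- unname(rootCodon)
    sm <- config@synonymousRateMultiplier
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
      aa <- aaState[[par]]; cd <- cdState[[par]]
      nNon <- rpois(L, t * rates)
      nSyn <- rpois(L, t * rates * sm)
      for (i in which(nNon > 0L)) {
        for (k in seq_len(nNon[i])) aa[i] <- sample(setdiff(aas, aa[i]), 1L)
        cd[i] <- sample(fam[[aa[i]]], 1L)
      }
      for (i in which(nSyn > 0L)) cd[i] <- sample(fam[[aa[i]]], 1L)
      aaState[[ch]] <- aa; cdState[[ch]] <- cd
    }
    seqs <- vapply(seq_along(tr$tip.label),
                   function(i) paste0(cdState[[i]], collapse = ""), character(1))
    names(seqs) <- tr$tip.label
    list(sequences = seqs, siteRates = rates,
         rootProtein = paste0(rootAA, collapse = ""))
  })
}

# --- transcript fragmentation -----------------------------------------------

.randomDna <- function(n, freqs = rep(0.25, 4)) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
         collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Fragment transcripts into assembled-contig-like pieces
#'
#' Each coding sequence is padded with random UTR on both ends, then one
#' contiguous fragment is drawn: length uniform in
#' \code{fragmentLengthRange} (capped at the transcript length), uniform
#' start, random strand. Every emitted fragment is at least
#' \code{minFragmentLength} bp; genes shorter than that are emitted whole or
#' skipped per \code{shortGenePolicy}, with the choice flagged.
#'
#' @param sequences named character vector of coding sequences
#' @param config a \linkS4class{SimulationConfig}
#' @param seed integer seed
#' @param idPrefix prefix for fragment ids
#' @return data.frame: fragment_id, source, strand, start, end (0-based
#'   half-open on the forward transcript), flag, sequence
#' @export
fragmentTranscripts <- function(sequences, config, seed = 1L, idPrefix = "fr") {
  if (length(sequences) == 0L) stop("sequences must be non-empty")
  lo <- config@fragmentLengthRange[1]; hi <- config@fragmentLengthRange[2]
  mfl <- config@minFragmentLength
  withr::with_seed(seed, {
    rows <- lapply(seq_along(sequences), function(i) {
      utr5 <- .randomDna(config@utrLength)
      utr3 <- .randomDna(config@utrLength)
      tx <- paste0(utr5, sequences[[i]], utr3)
      n <- nchar(tx)
      flag <- ""
      if (n < mfl) {
        if (config@shortGenePolicy == "skip")
          return(NULL)
        flag <- "short_gene_whole"
        start <- 0L; len <- n
      } else {
        len <- min(n, sample(seq(max(lo, mfl), max(hi, mfl, lo)), 1L))
        start <- sample.int(n - len + 1L, 1L) - 1L
      }
      frag <- substr(tx, start + 1L, start + len)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") frag <- .revcomp(frag)
      data.frame(fragment_id = NA_character_, source = names(sequences)[i],
                 strand = strand, start = start, end = start + len,
                 flag = flag, sequence = frag, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out)) return(data.frame())
    out$fragment_id <- sprintf("%s%04d", idPrefix, seq_len(nrow(out)))
    out
  })
}

# --- reference clusters ------------------------------------------------------

# mutate a protein: each residue replaced (by a different residue) w.p. m
.mutateProtein <- function(aa, m) {
  idx <- which(runif(length(aa)) < m)
  for (i in idx) aa[i] <- sample(setdiff(AMINO_ACIDS, aa[i]), 1L)
  aa
}

#' Build a synthetic reference cluster set
#'
#' Clusters of aligned protein sequences with a controlled mean pairwise
#' identity: members derive independently from a cluster ancestor with a
#' per-site substitution probability solved from
#' identity = (1-m)^2 + m^2/19. A stated fraction of clusters are
#' singletons.
#'
#' @param nClusters number of clusters
#' @param taxa candidate taxon ids; each cluster samples a subset
#' @param identityTarget target mean pairwise identity in (0, 1]
#' @param singletonFraction fraction of single-member clusters
#' @param seed integer seed
#' @param length protein length (columns)
#' @param membersRange min/max members of non-singleton clusters
#' @return list of clusters, each list(id, taxa, seqIds, seqs)
#' @export
buildReferenceClusters <- function(nClusters, taxa, identityTarget = 0.8,
                                   singletonFraction = 0.1, seed = 1L,
                                   length = 120L, membersRange = c(3L, 6L)) {
  stopifnot(identityTarget > 0, identityTarget <= 1)
  # solve (1-m)^2 + m^2/19 = identity for m in [0,1]
  m <- if (identityTarget >= 1) 0 else
    uniroot(function(m) (1 - m)^2 + m^2 / 19 - identityTarget, c(0, 0.97))$root
  withr::with_seed(seed, {
    lapply(seq_len(nClusters), function(ci) {
      anc <- sample(AMINO_ACIDS, length, replace = TRUE)
      single <- runif(1) < singletonFraction
      nm <- if (single) 1L else sample(membersRange[1]:membersRange[2], 1L)
      memberTaxa <- sample(taxa, nm, replace = nm > base::length(taxa))
      seqs <- vapply(seq_len(nm), function(j)
        paste0(.mutateProtein(anc, m), collapse = ""), character(1))
      ids <- sprintf("cl%03d_s%d", ci, seq_len(nm))
      names(seqs) <- ids
      list(id = sprintf("cl%03d", ci), taxa = memberTaxa, seqIds = ids,
           seqs = seqs)
    })
  })
}

# --- the full synthetic world ------------------------------------------------

#' Simulate a complete synthetic dataset with ground truth
#'
#' Generates the species tree, per-orthogroup gene trees (duplication/loss),
#' coding sequences, transcript fragments per taxon, a cluster set derived
#' from the orthogroup proteins (reference taxon planted in every cluster so
#' it is the most abundant), and the reference proteome. The returned ground
#' truth maps every fragment to its orthogroup and records per-taxon copy
#' numbers and paralogy classes on the true gene trees.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param outdir optional directory; when given, FASTA/Newick/TSV files are
#'   written (per-taxon transcripts, per-cluster alignments, reference
#'   proteome, ground truth, true trees)
#' @param referenceTaxon which taxon anchors the cluster set (default t01)
#' @param clusterTaxaPerGroup how many non-reference taxa join each cluster
#' @return list: config, speciesTree, geneTrees, cds (per orthogroup),
#'   transcripts (data.frame), clusters, refProteome, truth (data.frame)
#' @export
simulateDataset <- function(config, outdir = NULL, referenceTaxon = "t01",
                            clusterTaxaPerGroup = 4L) {
  seed <- config@seed
  spTree <- simulateSpeciesTree(config@nTaxa, config@birthRate,
                                seed = childSeed(seed, 1L),
                                height = config@treeHeight)
  stopifnot(referenceTaxon %in% spTree$tip.label)
  nOG <- config@nOrthogroups
  geneTrees <- vector("list", nOG)
  cds <- vector("list", nOG)
  truthRows <- list()
  transcripts <- list()
  for (g in seq_len(nOG)) {
    sg <- childSeed(seed, 10L + g)
    gt <- simulateGeneFamily(spTree, config@dupRate, config@lossRate, seed = sg)
    if (is.null(gt) || length(gt$tip.label) < 4L) {
      # enforce a usable family: fall back to the loss-free tree
      gt <- spTree
      gt$tip.label <- paste0(spTree$tip.label, "__1")
    }
    # the reference taxon must be present for DB construction
    if (!referenceTaxon %in% .leafTaxon(gt$tip.label)) {
      gt <- ape::bind.tree(gt, structure(list(
        edge = matrix(c(2L, 1L), 1), tip.label = paste0(referenceTaxon, "__1"),
        edge.length = config@treeHeight / 2, Nnode = 1L), class = "phylo"),
        where = length(gt$tip.label) + 1L)
    }
    geneTrees[[g]] <- gt
    ev <- evolveCodingSequences(gt, config, seed = childSeed(seed, 20000L + g))
    cds[[g]] <- ev
  }
  names(geneTrees) <- names(cds) <- sprintf("og%04d", seq_len(nOG))
  # dropout and fragmentation
  drop <- withr::with_seed(childSeed(seed, 2L), {
    m <- matrix(runif(nOG * config@nTaxa) < config@taxonDropout,
                nrow = nOG, dimnames = list(names(cds), spTree$tip.label))
    m[, referenceTaxon] <- FALSE  # reference proteome stays complete
    m
  })
  frags <- list()
  for (g in seq_len(nOG)) {
    og <- names(cds)[g]
    seqs <- cds[[g]]$sequences
    keep <- !drop[og, .leafTaxon(names(seqs))]
    seqs <- seqs[keep]
    if (!length(seqs)) next
    fr <- fragmentTranscripts(seqs, config, seed = childSeed(seed, 40000L + g),
                              idPrefix = sprintf("%s_f", og))
    if (!nrow(fr)) next
    fr$orthogroup <- og
    fr$taxon <- .leafTaxon(fr$source)
    frags[[og]] <- fr
  }
  truth <- do.call(rbind, frags)
  rownames(truth) <- NULL
  # clusters: orthogroup proteins of the reference plus sampled other taxa
  clusters <- lapply(seq_len(nOG), function(g) {
    og <- names(cds)[g]
    seqs <- cds[[g]]$sequences
    taxa <- .leafTaxon(names(seqs))
    prot <- as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs)))
    refIdx <- which(taxa == referenceTaxon)[1]
    others <- withr::with_seed(childSeed(seed, 60000L + g), {
      pool <- setdiff(seq_along(seqs), refIdx)
      pool[sample.int(length(pool), min(clusterTaxaPerGroup, length(pool)))]
    })
    idx <- c(refIdx, others)
    memberSeqs <- prot[idx]
    names(memberSeqs) <- sprintf("%s_m%d", og, seq_along(idx))
    list(id = og, taxa = taxa[idx], seqIds = names(memberSeqs),
         seqs = memberSeqs)  # equal lengths: generator is indel-free
  })
  names(clusters) <- names(cds)
  refCds <- vapply(seq_len(nOG), function(g) {
    seqs <- cds[[g]]$sequences
    seqs[[which(.leafTaxon(names(seqs)) == referenceTaxon)[1]]]
  }, character(1))
  refProteome <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(refCds)))
  names(refProteome) <- sprintf("%s_ref", names(cds))
  out <- list(config = config, speciesTree = spTree, geneTrees = geneTrees,
              cds = cds, transcripts = truth, clusters = clusters,
              refProteome = refProteome, referenceTaxon = referenceTaxon,
              truth = truth[, c("fragment_id", "taxon", "source", "orthogroup",
                                "strand", "start", "end", "flag")])
  if (!is.null(outdir)) .writeDataset(out, outdir)
  out
}

.writeDataset <- function(ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "clusters"), showWarnings = FALSE)
  dir.create(file.path(outdir, "transcripts"), showWarnings = FALSE)
  for (cl in ds$clusters)
    writeFasta(cl$seqs, file.path(outdir, "clusters", paste0(cl$id, ".fasta")), "AA")
  for (tx in split(ds$transcripts, ds$transcripts$taxon)) {
    seqs <- setNames(tx$sequence, tx$fragment_id)
    writeFasta(seqs, file.path(outdir, "transcripts",
                               paste0(tx$taxon[1], ".fasta")), "DNA")
  }
  writeFasta(ds$refProteome, file.path(outdir, "ref_proteome.fasta"), "AA")
  ape::write.tree(ds$speciesTree, file.path(outdir, "species_tree.nwk"))
  ape::write.tree(do.call(c, unname(ds$geneTrees)),
                  file.path(outdir, "gene_trees.nwk"))
  write.table(ds$truth, file.path(outdir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
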