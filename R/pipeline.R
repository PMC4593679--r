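# End-to-end pipeline: one configuration object, one entry point running
# simulation, matrix construction, database build, orthology assignment,
# gene-tree paralogy filtering, supermatrix variants, and tree inference,
# with a run manifest for reproducibility.

#' @include simulate.R AllClasses.R
NULL

#' PipelineConfig: end-to-end run parameters
#'
#' Defaults follow the pipeline's canonical settings: profile and
#' reciprocal-best-hit E-value cutoffs of 1e-5, top-quartile retention of
#' 0.25, cluster filters of at least 2 members and at least 70 percent
#' identity, a 200 bp contig floor, the standard occupancy-variant ladder,
#' 10 tree-search replicates and 1000 bootstrap replicates.
#'
#' @slot simulation a \linkS4class{SimulationConfig}
#' @slot hmmEvalue profile-search E-value cutoff
#' @slot rbhEvalue reciprocal-best-hit E-value cutoff
#' @slot quartile top-score fraction kept per orthogroup
#' @slot minClusterIdentity cluster identity floor (fraction)
#' @slot minMembers minimum cluster members
#' @slot minContigBp minimum transcript length (bp)
#' @slot minBlockWidth,minColumnConservation conserved-block parameters
#' @slot occupancyLevels named integer vector of minimum-taxa thresholds
#'   (NA entries mean "all taxa", resolved at run time)
#' @slot analyses names of the matrix variants to run tree inference on
#' @slot searchReplicates number of ML search replicates
#' @slot bootstrapReps number of bootstrap replicates
#' @slot geneTreeMethod "nj" (default) or "ml" for per-orthogroup gene trees
#' @slot seed master seed
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(simulation = "SimulationConfig", hmmEvalue = "numeric",
                 rbhEvalue = "numeric", quartile = "numeric",
                 minClusterIdentity = "numeric", minMembers = "integer",
                 minContigBp = "integer", minBlockWidth = "integer",
                 minColumnConservation = "numeric",
                 occupancyLevels = "integer", analyses = "character",
                 searchReplicates = "integer", bootstrapReps = "integer",
                 geneTreeMethod = "character", seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@quartile <= 0 || object@quartile > 1)
      msgs <- c(msgs, "quartile must lie in (0, 1]")
    if (object@minContigBp < 200L)
      msgs <- c(msgs, "minContigBp must be >= 200")
    if (any(object@hmmEvalue <= 0, object@rbhEvalue <= 0))
      msgs <- c(msgs, "E-value cutoffs must be positive")
    if (!object@geneTreeMethod %in% c("nj", "ml"))
      msgs <- c(msgs, "geneTreeMethod must be 'nj' or 'ml'")
    if (length(msgs)) msgs else TRUE
  })

#' @rdname PipelineConfig-class
#' @param simulation a \linkS4class{SimulationConfig}
#' @param hmmEvalue,rbhEvalue,quartile,minClusterIdentity,minMembers see slots
#' @param minContigBp,minBlockWidth,minColumnConservation see slots
#' @param occupancyLevels,analyses,searchReplicates,bootstrapReps see slots
#' @param geneTreeMethod,seed see slots
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           hmmEvalue = 1e-5, rbhEvalue = 1e-5,
                           quartile = 0.25, minClusterIdentity = 0.70,
                           minMembers = 2L, minContigBp = 200L,
                           minBlockWidth = 10L, minColumnConservation = 0.5,
                           occupancyLevels = c(unfiltered = 0L, nt123 = 4L,
                                               min16 = 16L, min18 = 18L,
                                               complete = NA_integer_),
                           analyses = "nt123",
                           searchReplicates = 10L, bootstrapReps = 1000L,
                           geneTreeMethod = c("nj", "ml"), seed = 1L) {
  new("PipelineConfig", simulation = simulation, hmmEvalue = hmmEvalue,
      rbhEvalue = rbhEvalue, quartile = quartile,
      minClusterIdentity = minClusterIdentity,
      minMembers = as.integer(minMembers), minContigBp = as.integer(minContigBp),
      minBlockWidth = as.integer(minBlockWidth),
      minColumnConservation = minColumnConservation,
      occupancyLevels = as.integer(occupancyLevels) |>
        setNames(names(occupancyLevels)),
      analyses = analyses, searchReplicates = as.integer(searchReplicates),
      bootstrapReps = as.integer(bootstrapReps),
      geneTreeMethod = match.arg(geneTreeMethod), seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: E <=", object@hmmEvalue, "(profile) /",
      object@rbhEvalue, "(RBH), quartile", object@quartile,
      ", identity >=", object@minClusterIdentity,
      ",", object@searchReplicates, "replicates /", object@bootstrapReps,
      "bootstraps; analyses:", paste(object@analyses, collapse = ", "),
      "; seed", object@seed, "\n")
})

# --- per-orthogroup alignment assembly ---------------------------------------

# codon of residue i of a peptide: ntStart + 3*(i-1) on the frame's strand
.fragmentCodons <- function(transcript, frame, ntStart, nResidues) {
  s <- if (frame > 0L) transcript else .revcomp(transcript)
  starts <- ntStart + 3L * (seq_len(nResidues) - 1L)
  substring(s, starts + 1L, starts + 3L)
}

#' Assemble per-orthogroup codon alignments from confirmed assignments
#'
#' Every confirmed fragment is threaded onto its orthogroup's reference
#' protein and backtranslated with its source codons. Rows are labelled
#' \code{taxon__k} so multiple fragments of one taxon remain distinct for
#' paralogy filtering.
#'
#' @param assignment result of \code{\link{assignOrthologs}}
#' @param transcripts the searched transcripts (named nucleotide vector)
#' @param db a \linkS4class{CoreOrthologueSet}
#' @param matrix a \linkS4class{SubstitutionMatrix}
#' @param taxonOf transcript id -> taxon mapping (default: text before the
#'   first "_f" separator is the orthogroup tag; taxon from the truth table
#'   convention \code{ogXXXX_fNNNN} does not apply here, so the default
#'   expects transcript names carrying the taxon before "__")
#' @param gapOpen,gapExtend affine gap penalties
#' @return named list of character matrices (rows = taxon__k fragments)
#' @export
buildOrthogroupAlignments <- function(assignment, transcripts, db, matrix,
                                      taxonOf, gapOpen = 11, gapExtend = 1) {
  hits <- assignment$assignments
  peps <- assignment$peptides
  out <- list()
  if (nrow(hits) == 0L) return(out)
  for (og in unique(hits$orthogroup)) {
    h <- hits[hits$orthogroup == og, , drop = FALSE]
    ref <- db@orthogroups[[og]]$refProtein
    rows <- list(); maps <- list(); codons <- list()
    taxCount <- list()
    for (i in seq_len(nrow(h))) {
      p <- peps[peps$peptide_id == h$peptide_id[i], ]
      th <- threadFragment(p$peptide, ref, matrix, gapOpen, gapExtend)
      tx <- taxonOf(h$transcript[i])
      taxCount[[tx]] <- (taxCount[[tx]] %||% 0L) + 1L
      lab <- sprintf("%s__%d", tx, taxCount[[tx]])
      rows[[lab]] <- th$row
      maps[[lab]] <- th$map
      codons[[lab]] <- .fragmentCodons(transcripts[[h$transcript[i]]],
                                       p$frame, p$ntStart, nchar(p$peptide))
    }
    out[[og]] <- backtranslate(rows, maps, codons)
  }
  out
}

# gene tree for one orthogroup alignment (rows = fragments)
.geneTree <- function(aln, method = "nj", model = NULL, seed = 1L) {
  n <- nrow(aln)
  if (n < 4L) return(NULL)
  if (method == "nj") {
    bin <- ape::as.DNAbin(tolower(aln))
    d <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
    d[!is.finite(d)] <- max(d[is.finite(d)], 0.75) + 0.5
    tr <- ape::njs(d)
    tr$edge.length <- pmax(tr$edge.length, 0)
    tr
  } else {
    if (is.null(model)) model <- gtrParams(alpha = 1, k = 4L)
    res <- mlTreeSearch(aln, model = model, nReplicates = 1L, nBootstrap = 0L,
                        seed = seed, fitModel = FALSE, verbose = FALSE)
    bestTree(res)
  }
}

#' Filter all orthogroups for paralogy
#'
#' Builds a gene tree per orthogroup (skipped when every taxon has a single
#' fragment), discards orthogroups containing out-paralogues, collapses
#' in-paralogues to consensus rows, and renames rows to plain taxon ids.
#'
#' @param alignments named list of fragment alignments (rows "taxon__k")
#' @param method "nj" or "ml" gene trees
#' @param seed master seed (ml method only)
#' @param verbose print progress
#' @return list(alignments (kept, rows = taxa), report (data.frame:
#'   orthogroup, kept, reason), trees (gene trees, NULL where skipped))
#' @export
filterParalogues <- function(alignments, method = "nj", seed = 1L,
                             verbose = FALSE) {
  kept <- list(); trees <- list()
  rep <- data.frame(orthogroup = character(), kept = logical(),
                    reason = character(), stringsAsFactors = FALSE)
  for (og in names(alignments)) {
    aln <- alignments[[og]]
    taxa <- .leafTaxon(rownames(aln))
    if (!anyDuplicated(taxa)) {
      rownames(aln) <- taxa
      kept[[og]] <- aln
      trees[og] <- list(NULL)
      rep <- rbind(rep, data.frame(orthogroup = og, kept = TRUE,
                                   reason = "single_copy"))
      next
    }
    tr <- .geneTree(aln, method, seed = childSeed(seed, match(og, names(alignments))))
    if (is.null(tr)) {
      # too few rows for a tree: collapse duplicates by consensus directly
      merged <- do.call(rbind, lapply(unique(taxa), function(tx) {
        sub <- aln[taxa == tx, , drop = FALSE]
        if (nrow(sub) == 1L) sub[1, ] else
          strsplit(consensusSequence(sub, "DNA"), "")[[1]]
      }))
      rownames(merged) <- unique(taxa)
      kept[[og]] <- merged
      trees[og] <- list(NULL)
      rep <- rbind(rep, data.frame(orthogroup = og, kept = TRUE,
                                   reason = "too_small_for_tree_consensus"))
      next
    }
    trees[[og]] <- tr
    fo <- filterOrthogroup(tr, aln, alphabet = "DNA")
    if (fo$keep) {
      kept[[og]] <- fo$alignment
      rep <- rbind(rep, data.frame(orthogroup = og, kept = TRUE,
                                   reason = "in_paralogue_consensus"))
    } else {
      rep <- rbind(rep, data.frame(orthogroup = og, kept = FALSE,
                                   reason = "out_paralogue"))
    }
    .msg("  ", og, ": ", tail(rep$reason, 1), verbose = verbose)
  }
  list(alignments = kept, report = rep, trees = trees)
}

# --- run manifest ------------------------------------------------------------

#' Summarise a run manifest
#'
#' @param manifest the manifest list returned by \code{\link{runAll}}
#' @return invisibly, the formatted lines (also printed)
#' @export
report <- function(manifest) {
  lines <- c(sprintf("run seed: %d", manifest$seed),
             sprintf("stages: %s", paste(names(manifest$stages), collapse = ", ")),
             vapply(names(manifest$stages), function(s)
               sprintf("  %-12s %6.1fs  %s", s, manifest$stages[[s]]$seconds,
                       manifest$stages[[s]]$note), character(1)),
             sprintf("outputs: %d files", nrow(manifest$files)))
  cat(lines, sep = "\n")
  invisible(lines)
}

.manifestFiles <- function(outdir) {
  files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  data.frame(file = sub(paste0("^", outdir, "/?"), "", files),
             md5 = unname(tools::md5sum(files)),
             bytes = file.size(files), stringsAsFactors = FALSE)
}

# --- the full run ------------------------------------------------------------

#' Run the complete pipeline
#'
#' Simulates a dataset, builds the substitution matrix and core-orthologue
#' database, assigns fragments, filters paralogy, assembles all supermatrix
#' variants, runs tree inference on the configured analyses, and writes
#' everything (plus a manifest with MD5 checksums) under \code{outdir}.
#'
#' @param config a \linkS4class{PipelineConfig}
#' @param outdir output directory (created)
#' @param verbose print stage progress
#' @return list: dataset, matrix, db, assignment, paralogy, variants,
#'   results (per analysis, \linkS4class{TreeSearchResult}), manifest
#' @export
runAll <- function(config, outdir, verbose = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config@seed
  stages <- list()
  tick <- function(expr, name, note = "") {
    t0 <- proc.time()[3]
    val <- force(expr)
    stages[[name]] <<- list(seconds = unname(proc.time()[3] - t0), note = note)
    .msg(sprintf("[%s] %.1fs %s", name, stages[[name]]$seconds, note),
         verbose = verbose)
    val
  }

  simCfg <- config@simulation
  simCfg@seed <- childSeed(seed, 1L)
  ds <- tick(simulateDataset(simCfg, outdir = file.path(outdir, "data")),
             "simulate", sprintf("%d taxa, %d orthogroups",
                                 simCfg@nTaxa, simCfg@nOrthogroups))

  subMat <- tick(buildSubstitutionMatrix(
    ds$clusters, minMembers = config@minMembers,
    minIdentity = config@minClusterIdentity,
    minBlockWidth = config@minBlockWidth,
    minColumnConservation = config@minColumnConservation), "matrix")
  writeScoringMatrix(subMat, file.path(outdir, "substitution_matrix.txt"))

  db <- tick({
    kept <- filterClusters(ds$clusters, config@minMembers,
                           config@minClusterIdentity)
    d <- buildCoreOrthologueDb(kept, ds$referenceTaxon,
                               proteome = ds$refProteome)
    calibrateDatabase(d, seed = childSeed(seed, 2L))
  }, "database")

  transcripts <- setNames(ds$transcripts$sequence, ds$transcripts$fragment_id)
  byTaxon <- lapply(split(seq_len(nrow(ds$transcripts)), ds$transcripts$taxon),
                    function(i) transcripts[i])
  assignment <- tick(assignOrthologsPerTaxon(
    byTaxon, db, subMat, minContigBp = config@minContigBp,
    evalueCutoff = config@hmmEvalue, rbhEvalueCutoff = config@rbhEvalue,
    quartile = config@quartile, seed = childSeed(seed, 3L)),
    "assign", sprintf("%d transcripts", length(transcripts)))
  write.table(assignment$assignments,
              file.path(outdir, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  taxonOf <- local({
    map <- setNames(ds$transcripts$taxon, ds$transcripts$fragment_id)
    function(id) unname(map[id])
  })
  ogAlns <- tick(buildOrthogroupAlignments(assignment, transcripts, db,
                                           subMat, taxonOf), "thread",
                 sprintf("%d orthogroups", length(
                   unique(assignment$assignments$orthogroup))))

  paralogy <- tick(filterParalogues(ogAlns, method = config@geneTreeMethod,
                                    seed = childSeed(seed, 4L)), "paralogy",
                   sprintf("%d kept", NA_integer_))
  stages$paralogy$note <- sprintf("%d of %d kept",
                                  sum(paralogy$report$kept),
                                  nrow(paralogy$report))
  write.table(paralogy$report, file.path(outdir, "paralogy_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  variants <- tick({
    sm <- concatenateAlignments(paralogy$alignments,
                                taxa = ds$speciesTree$tip.label)
    lv <- config@occupancyLevels
    lv[is.na(lv)] <- nrow(superMatrixSeqs(sm))
    supermatrixVariants(sm, occupancyLevels = lv)
  }, "supermatrix")
  dir.create(file.path(outdir, "matrices"), showWarnings = FALSE)
  for (nm in names(variants)) {
    writePhylip(variants[[nm]], file.path(outdir, "matrices",
                                          paste0(nm, ".phy")))
    writePartitions(variants[[nm]], file.path(outdir, "matrices",
                                              paste0(nm, ".partitions")))
  }
  write.table(attr(variants, "summary"),
              file.path(outdir, "matrix_variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  results <- list()
  for (an in config@analyses) {
    if (!an %in% names(variants)) stop("unknown analysis variant: ", an)
    sm <- variants[[an]]
    res <- tick(mlTreeSearch(sm, nReplicates = config@searchReplicates,
                             nBootstrap = config@bootstrapReps,
                             seed = childSeed(seed, 100L + match(an, config@analyses)),
                             verbose = FALSE),
                paste0("infer_", an),
                sprintf("%d cols", ncol(superMatrixSeqs(sm))))
    results[[an]] <- res
    ape::write.tree(bestTree(res), file.path(outdir, paste0("best_", an, ".nwk")))
    if (length(bootstrapTrees(res))) {
      ape::write.tree(do.call(c, bootstrapTrees(res)),
                      file.path(outdir, paste0("bootstrap_", an, ".nwk")))
      ape::write.tree(res@supportTree,
                      file.path(outdir, paste0("support_", an, ".nwk")))
      ape::write.tree(res@consensus,
                      file.path(outdir, paste0("consensus_", an, ".nwk")))
    }
  }

  manifest <- list(seed = seed, stages = stages, files = .manifestFiles(outdir))
  write.table(manifest$files, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(dataset = ds, matrix = subMat, db = db, assignment = assignment,
       paralogy = paralogy, variants = variants, results = results,
       manifest = manifest)
}
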