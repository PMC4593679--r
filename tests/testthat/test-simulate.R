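test_that("simulation config validates its parameters", {
  expect_s4_class(simulationConfig(), "SimulationConfig")
  expect_error(simulationConfig(minFragmentLength = 150L), "200")
  expect_error(simulationConfig(taxonDropout = 1.2))
  cfg <- simulationConfig(nTaxa = 8L, seed = 5L)
  expect_identical(cfg@nTaxa, 8L)
})

test_that("species tree has the requested tips and height", {
  tr <- simulateSpeciesTree(12L, seed = 3L, height = 0.4)
  expect_identical(sort(tr$tip.label), sprintf("t%02d", 1:12))
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(max(depths[seq_len(12)]), 0.4, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  # deterministic in the seed
  tr2 <- simulateSpeciesTree(12L, seed = 3L, height = 0.4)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("gene families label leaves taxon__copy and respect rates", {
  sp <- simulateSpeciesTree(10L, seed = 1L)
  gf <- simulateGeneFamily(sp, dupRate = 0, lossRate = 0, seed = 2L)
  # no duplication/loss: exactly one copy per taxon
  expect_setequal(cladophylo:::.leafTaxon(gf$tip.label), sp$tip.label)
  expect_identical(length(gf$tip.label), 10L)
  # with duplication, some taxon gains a second copy eventually
  nCopies <- vapply(1:20, function(s) {
    g <- simulateGeneFamily(sp, dupRate = 0.8, lossRate = 0, seed = s)
    length(g$tip.label)
  }, 0L)
  expect_true(any(nCopies > 10L))
})

test_that("evolved coding sequences translate without internal stops", {
  cfg <- simulationConfig(nTaxa = 6L, geneLength = 60L, seed = 9L)
  sp <- simulateSpeciesTree(6L, seed = 9L)
  seqs <- evolveCodingSequences(sp, cfg, seed = 4L)$sequences
  expect_identical(unname(nchar(seqs)), rep(180L, length(seqs)))
  for (s in seqs) {
    cod <- substring(s, seq(1, 178, 3), seq(3, 180, 3))
    aa <- Biostrings::GENETIC_CODE[cod]
    expect_false(any(aa == "*"))
  }
})

test_that("fragments respect length bounds, UTRs and strand truth", {
  cfg <- simulationConfig(nTaxa = 6L, geneLength = 200L,
                          fragmentLengthRange = c(300L, 450L),
                          utrLength = 25L, seed = 2L)
  sp <- simulateSpeciesTree(6L, seed = 2L)
  seqs <- evolveCodingSequences(sp, cfg, seed = 3L)$sequences
  fr <- fragmentTranscripts(seqs, cfg, seed = 7L)
  expect_true(all(nchar(fr$sequence) >= 300L | fr$flag == "short_gene_whole"))
  expect_true(all(nchar(fr$sequence) <= 450L))
  expect_true(all(fr$strand %in% c("+", "-")))
  # fragment coordinates address the padded transcript: end - start = length
  expect_identical(fr$end - fr$start, nchar(fr$sequence))
  expect_true(all(fr$end <= 200L * 3L + 2L * 25L))
  # short-gene policy: a gene below the floor is emitted whole and flagged
  cfgShort <- simulationConfig(nTaxa = 6L, geneLength = 50L,
                               utrLength = 10L, seed = 2L)
  short <- evolveCodingSequences(sp, cfgShort, seed = 3L)$sequences
  frShort <- fragmentTranscripts(short, cfgShort, seed = 7L)
  expect_true(all(frShort$flag == "short_gene_whole"))
  expect_identical(unname(nchar(frShort$sequence)), rep(170L, nrow(frShort)))
  cfgSkip <- simulationConfig(nTaxa = 6L, geneLength = 50L, utrLength = 10L,
                              shortGenePolicy = "skip", seed = 2L)
  expect_identical(nrow(fragmentTranscripts(short, cfgSkip, seed = 7L)), 0L)
})

test_that("simulated datasets are complete, consistent and seeded", {
  cfg <- simulationConfig(nTaxa = 8L, nOrthogroups = 10L, geneLength = 80L,
                          seed = 31L)
  ds <- simulateDataset(cfg)
  expect_identical(length(ds$clusters), 10L)
  # the reference taxon anchors every cluster (planted first)
  expect_true(all(vapply(ds$clusters, function(cl) cl$taxa[1] == "t01",
                         logical(1))))
  expect_true(all(grepl("^og", names(ds$refProteome))))
  # truth rows match the emitted transcript table one to one
  expect_setequal(ds$truth$fragment_id, ds$transcripts$fragment_id)
  expect_true(all(ds$truth$orthogroup %in% names(ds$clusters)))
  # the reference taxon is never dropped
  expect_true(all(names(ds$clusters) %in%
                    ds$truth$orthogroup[ds$truth$taxon == "t01"]))
  # species tree carries the configured taxa
  expect_setequal(ds$speciesTree$tip.label, sprintf("t%02d", 1:8))
  expect_identical(length(ds$geneTrees), 10L)
  # determinism
  ds2 <- simulateDataset(cfg)
  expect_identical(ds$transcripts, ds2$transcripts)
  expect_identical(ds$truth, ds2$truth)
})

test_that("dataset writer emits the documented text files", {
  cfg <- simulationConfig(nTaxa = 6L, nOrthogroups = 4L, geneLength = 60L,
                          seed = 13L)
  dir <- withr::local_tempdir()
  ds <- simulateDataset(cfg, outdir = dir)
  expect_true(file.exists(file.path(dir, "species_tree.nwk")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  expect_true(file.exists(file.path(dir, "ref_proteome.fasta")))
  expect_true(file.exists(file.path(dir, "transcripts", "t01.fasta")))
  expect_true(file.exists(file.path(dir, "clusters", "og0001.fasta")))
  tr <- ape::read.tree(file.path(dir, "species_tree.nwk"))
  expect_setequal(tr$tip.label, sprintf("t%02d", 1:6))
  truth <- read.delim(file.path(dir, "ground_truth.tsv"))
  expect_true(all(c("fragment_id", "taxon", "orthogroup", "strand") %in%
                    names(truth)))
})
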