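---
title: "cladophylo: methods behind the pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cladophylo: methods behind the pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical and algorithmic choices behind each
stage of the pipeline. Code blocks are illustrative and not evaluated; the
same calls appear, executed, in the package tests and in
`scripts/acceptance.R`.

## 1. Custom log-odds substitution matrix

Protein clusters are aligned; maximal gap-free blocks at least 10 columns
wide in which every column has at least 50% conservation are extracted
(`extractConservedBlocks`). Within a block, sequences are grouped by
single-linkage clustering at 50% identity and each group's contribution is
down-weighted by its size, exactly as in the BLOSUM construction: a column
with $n_g$ members of group $g$ contributes pair counts weighted by
$1/(n_g n_h)$ between groups $g \ne h$. Observed pair frequencies $q_{ij}$
and marginals $p_i$ give integer scores

$$ s_{ij} = \mathrm{round}\!\left(\frac{1}{\lambda}
   \log_2 \frac{q_{ij}}{p_i p_j}\right), $$

with half-bit scaling ($\lambda = 0.5$). The test suite checks the weighted
pair counts and the rounded scores against an independent brute-force
implementation on random block sets.

```{r}
m <- buildSubstitutionMatrix(clusters)
scoreMatrix(m)["W", "W"]
```

## 2. Core-orthologue database and E-value calibration

Clusters with at least 2 members and at least 70% mean pairwise identity
become orthogroups. Each orthogroup stores a position-specific scoring
profile: per retained column (gap fraction ≤ 0.5) the score of residue $a$
is $\log_2 \frac{(n_a + \tau\, b_a)/(n + \tau)}{b_a}$ with pseudocount mass
$\tau = 1$ and background $b$. Profile scores of random-sequence decoys are
fitted with a Gumbel (type-I extreme value) distribution by maximum
likelihood, so a raw alignment score $S$ converts to

$$ E(S) = N \cdot \exp\!\left(-\frac{S - \mu}{\beta}\right), $$

where $N$ is the search-space size. The same machinery calibrates
proteome-wide best-hit scores for the reciprocal-best-hit step, where the
null already incorporates the maximum over the proteome.

## 3. Orthology assignment

Each transcript at least 200 bp long is translated in all six reading
frames; open reading frames of at least 30 residues are searched against
every profile (exact Smith-Waterman with affine gaps 11/1; a k-mer seed
prefilter skips pairs that share fewer than two exact 5-mers with the
profile consensus — a speed/sensitivity trade-off that leaves reported
scores exact). Hits are filtered at E ≤ 1e-5; per orthogroup only the
top-scoring quartile survives, keeping $\lceil n q \rceil$ hits plus any
hit tied with the boundary score; per transcript only the best frame is
kept. A hit is confirmed when the transcript's peptide, aligned against the
entire reference proteome, finds the assigned orthogroup's reference
protein as its best hit with E ≤ 1e-5. Assignment runs one transcriptome at
a time so the quartile filter selects among a taxon's redundant transcripts
rather than across taxa.

## 4. Clan-based paralogy filtering

For each orthogroup a gene tree is built (neighbour joining by default) and
treated as unrooted. For a taxon with $k$ leaves, the leaves form a *clan*
if some edge of the unrooted tree has exactly that leaf set on one side
(sets of size $\ge n-1$ are clans trivially via pendant edges). Taxa whose
leaves form a clan are in-paralogues and are merged into one row by
majority-rule consensus; any taxon whose leaves do not form a clan is an
out-paralogue and the whole orthogroup is discarded. The acceptance tests
compare this classification against exhaustive edge enumeration on 1,000
random gene trees.

## 5. Supermatrix assembly and degeneracy coding

Confirmed fragments are threaded onto their orthogroup's reference coding
sequence via the protein alignment, backtranslated to nucleotides, and
concatenated into a supermatrix with per-column orthogroup and
codon-position labels. Variants: occupancy filters keep columns with data
for at least $m$ taxa (e.g. 4, 16, 18), codon-position selections extract
positions {1,2} or {1,2,3}, and degeneracy coding rewrites every codon to
its synonymous family's IUPAC pattern (Leu/Arg/Ser six-codon families
merged), so that synonymous differences become invisible:

```{r}
nt123  <- filterByOccupancy(sm, 4L)
degen1 <- degenEncode(nt123)
```

## 6. Maximum-likelihood inference

The likelihood engine implements GTR+I+G via directed-edge message passing
in C++. Site likelihoods mix an invariant class with $k = 4$ discrete gamma
categories; following the standard I+G convention the category rates are
divided by $(1 - p_{\mathrm{inv}})$ so the mixture's mean rate is 1 and
$p_{\mathrm{inv}}$ stays decoupled from the global branch-length scale.
The engine is verified against a closed-form two-sequence Jukes-Cantor
likelihood, exhaustive summation over all internal state assignments on
small trees, re-rooting invariance, and an independent R implementation.

The search uses random-order stepwise-addition starting trees, hill
climbing by nearest-neighbour interchange alternated with single-taxon
reinsertion passes, and Brent optimisation of branch lengths on cached
edge messages. Replicate searches run on a weight-proportional subsample
of site patterns for speed; replicate ranking, final refinement and all
reported likelihoods use the full data. Nonparametric bootstrap replicates
resample columns, re-search from the best tree, and support values are the
fraction of replicates containing each bipartition; a majority-rule
consensus and Robinson-Foulds distances complete the picture.

```{r}
res <- mlTreeSearch(nt123, nReplicates = 10L, nBootstrap = 1000L, seed = 1L)
rfDistance(bestTree(res), otherTree)
```

## 7. Synthetic data with ground truth

`simulateDataset` simulates a birth-process species tree (node ages
respaced onto a jittered grid so every internal branch is resolvable at
realistic data sizes), gene family trees with duplication and loss, codon
sequences evolved under GTR+gamma with third-position rate multipliers,
random taxon dropout, and UTR-padded fragmenting of transcripts — along
with the true orthogroup and coordinates of every fragment. All
end-to-end claims in the tests (assignment precision/recall, topology
recovery, bootstrap support on true clades) are measured against this
ground truth.
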