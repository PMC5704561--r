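---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the procedures
it implements, the tunable parameters and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The analysis pipeline

The package targets diverse prokaryotic protein families — the motivating
case is the Cas4 nuclease family of CRISPR–Cas adaptation modules — whose
members are too divergent for a single multiple alignment. The pipeline
is:

1. **Clustering.** Greedy single-linkage clustering on the graph whose
   edges are sequence pairs with global-alignment identity at or above an
   identity threshold and both alignment coverages at or above a coverage
   threshold. Defaults: 0.5/0.8 for family proteins, 0.9/0.9 for 16S
   rRNA. Identity counts matches over aligned columns excluding
   terminal-gap columns, with internal gaps scored as mismatches;
   coverage of a sequence is the fraction of its residues inside the
   terminal-gap-trimmed region. Single linkage and a symmetric
   min-of-both-coverages rule are used because the classic clustering
   tools of this field behave that way and because connected components
   are exactly testable against a brute-force oracle.

2. **Alignment and column filtering.** Progressive alignment inside each
   cluster: a UPGMA guide tree on (1 − identity) distances, then
   profile–profile Needleman–Wunsch merges with frequency-weighted
   sum-of-pairs BLOSUM62 column scores. Columns are then masked when gap
   fraction exceeds 0.5 **or** homogeneity falls below 0.1. Homogeneity
   is not a standard quantity; here it is the fraction of identical
   unordered residue pairs among the column's non-gap residues (1.0 when
   fewer than two residues). This definition is parameter-free, ranges
   over [0, 1], and drops exactly the hypervariable columns the 0.1
   threshold is meant to remove. Whether a class-based (rather than
   identity-based) statistic was originally intended is unknowable; the
   statistic is isolated in one function so it can be swapped.

3. **Iterative cluster merging.** Each cluster is summarized by a profile
   (per-column residue frequencies on kept columns, gaps excluded, plus
   an add-1/20 pseudocount). Cluster-to-cluster similarity is the best
   local profile–profile alignment score under the column score
   S(c₁,c₂) = Σₐ Σ_b f₁(a) f₂(b) B(a,b) with BLOSUM62 B and affine gaps.
   This scorer is an in-package stand-in for an HMM–HMM search tool: it
   keeps the same interface (symmetric score, self-score normalization)
   while remaining dependency-free and deterministic. Pairs whose score
   divided by the smaller of the two self-scores exceeds 0.1 are merged,
   best ratio first with recomputation after every merge, until a fixed
   point; the merge count is bounded by the initial cluster count minus
   one, so termination is guaranteed. The normalization uses the minimum
   self-score because the original procedure's normalization is not
   documented; the minimum is the conservative choice (it can only raise
   ratios, never hide a mergeable pair).

4. **Trees and grafting.** Per merged cluster, neighbor joining on
   corrected distances from kept columns — protein
   d = −ln(1 − p − 0.2p²) (a scoredist-style correction), nucleotide
   Jukes–Cantor d = −(3/4)ln(1 − 4p/3) — with saturated or incomparable
   pairs capped at 12, deliberately the same value as the coherence
   sentinel so that within-tree saturation and cross-cluster
   incomparability are treated alike downstream. NJ replaces approximate
   maximum likelihood as the one intentional algorithmic substitution:
   everything downstream consumes only tree distances and supports, and
   NJ is exactly testable (it reproduces any additive matrix). Support
   values are bipartition frequencies over bootstrap resamplings of kept
   columns. Cluster trees are midpoint rooted and grafted onto the tips
   of a UPGMA dendrogram built from d = 1 − ratio (floored at 0) over the
   final clusters; dendrogram-internal attachment points carry support 0,
   marking joins that were never supported by a joint alignment.

5. **Coherence with the species tree.** For every unordered genome pair
   with family members in both genomes, the protein distance is the
   minimum over all cross-genome member pairs of the patristic distance
   when both members lie in one cluster tree, else a sentinel of 12; the
   minimum is taken after sentinel substitution, so a single in-tree pair
   beats any sentinel (the "shortest distance" rule for multi-copy
   genomes). The 16S side is computed the same way with sentinel 3.
   Genomes lacking the gene are omitted, not sentineled. The coherence
   statistic is the Spearman rank correlation between the two distance
   columns, with average ranks for ties — sentinel rows form large tie
   blocks, and average ranking is the one convention that treats both
   sides symmetrically; it is configurable because with many sentinel
   rows the convention materially affects ρ.

6. **Selection.** Pairwise dN/dS by Nei–Gojobori (1986): per-codon
   synonymous site counts from the fraction of synonymous single-nucleotide
   changes (mutations to stop codons count as nonsynonymous, so
   S + N = 3 × codons exactly); observed differences averaged uniformly
   over mutational pathways, excluding pathways that cross a stop codon;
   Jukes–Cantor correction of both proportions; the ratio is reported
   only when both proportions are below the correction's domain limit
   (0.75) and dS > 0. NG86 was chosen over ML codon fitting for exact
   testability; the implementation was validated against an independent
   Biopython oracle, whose values are frozen in the test suite. For group
   summaries, pairs are drawn within clusters at protein identity in
   [0.5, 0.95] (configurable) to avoid both saturated and uninformative
   near-identical pairs.

7. **Genomic context.** A family gene is CAS if any cas1/cas2/cas6,
   effector-subtype or CRISPR-array feature lies within a window
   (default 10 genes) on its contig, or if the gene itself is a cas4/cas1
   fusion (fusion precedence holds even on viral replicons); otherwise
   MGE if the replicon is viral/plasmid or an MGE marker is in the
   window; otherwise solo. The window default is a judgment call — no
   published cutoff separates "associated" from "solo" — and is exposed
   as a parameter. Adaptation-module arrangements (cas4–cas1–cas2,
   fusion–cas2, cas4–cas1–cas2–cas6, two-cas4) are matched on adjacency
   in either reading direction. Presence summaries weight each genome
   inversely to the number of genomes of its species, and
   one-per-species counts keep the lexicographically smallest genome as
   the deterministic species representative.

## The synthetic world

The generator states one fixed world; its defaults were chosen once, for
realism, and are not tuned against test outcomes.

| parameter | default | rationale |
|---|---|---|
| `n_genomes` | 50 | large enough for 1225 genome pairs, small enough for desk-scale runs |
| `birth_rate` | 1 | Yule pure-birth species tree; any shape serves calibration |
| `tree_height` | 1 | root-to-tip length in expected nucleotide substitutions per site at ω = 1; deep-family divergence without saturating the amino-acid distance correction |
| `seq_len_codons` | 200 | typical length of a Cas4-sized protein |
| `rrna_len` / `rrna_rate` | 1500 / 0.1× | real 16S length; a 0.1× clock keeps maximum 16S divergence near 20%, as observed between distant prokaryotes |
| `omega` | 0.1 | genome-wide median dN/dS for bacteria and archaea is near 0.1 |
| `kappa` | 2 | canonical transition/transversion ratio |
| `locus_mix` | 0.85 / 0.11 / 0.04 | the family's observed proportions of CRISPR-associated, solo and MGE members |

Transfers are replacement events: at Poisson(rate × height) uniformly
random times, the subtree below a random recipient lineage is pruned and
re-attached as sister to a random contemporaneous donor — the standard
subtree-prune–regraft model of gene displacement. Duplications copy the
lineage below a branch midpoint; losses delete a branch's subtree.
Codon sequences evolve by a Muse–Gaut model with HKY exchange and uniform
codon frequencies over the 61 sense codons; the rate matrix is scaled at
ω = 1, so ω rescales only the nonsynonymous flow and branch lengths keep
one meaning across ω values; stop codons are unreachable by construction.
The 16S-like marker evolves by Jukes–Cantor on the species tree. Random
draws come from labeled substreams of one master seed, so adding a stage
never perturbs earlier outputs and identical configurations reproduce
byte-identical files.

**What the generator does not emulate:** insertions/deletions in coding
sequences (so simulated families need no alignment step to be comparable
— alignment quality is tested on constructed fixtures instead), rate
heterogeneity across sites and lineages, codon usage bias, prophages
hidden inside chromosomal replicons, and CRISPR arrays as sequence
(arrays are feature-table labels only). A green round-trip therefore
establishes the correctness of the bookkeeping and the statistics, not
robustness to alignment error or rate variation.

## What a green coherence test establishes

The HGT-recovery check applies the coherence statistic to the simulated
family's true trees: the gene tree (with its transfer history) against
the species tree that the 16S marker evolves on. With no transfers the
two trees are identical and ρ = 1; transfers push ρ down, and the check
asserts the ordering across transfer rates. This isolates the statistic's
response to transfer from tree-estimation noise — deliberately so,
because the two effects cannot be separated otherwise at realistic
sequence lengths. In an ultrametric Yule world roughly half of all genome
pairs coalesce at or near the root and so have nearly identical true
distances; independent estimation noise on the protein and rRNA sides
breaks those near-ties in unrelated ways, which caps the rank correlation
of sequence-estimated distances well below 1 no matter which (monotone)
distance correction is used — rank correlation is invariant to monotone
transforms, so only noise, not estimator calibration, matters. The
pipeline's reported ρ on sequence-estimated trees (the worked example in
the README) accordingly sits far below the true-tree value even without
transfer, and should be read comparatively (CAS vs solo, rate 0 vs rate
2), never as an absolute fraction of vertical descent. Real published
coherence values for vertically evolving gene sets are themselves well
below 1 for the same reason.

## Numerical choices

- **Gap costs:** a length-k gap costs 11 + (k − 1) with BLOSUM62
  (BLAST's convention); nucleotide alignment uses +1/−1 match/mismatch
  with gap open 5, extend 2. One compiled Gotoh kernel serves
  residue–residue, profile–profile global, and profile–profile local
  alignment; its scores are checked against an independent
  implementation in the test suite.
- **Distance caps:** corrected distances are capped at 12 (the protein
  sentinel) when the correction's argument leaves its domain.
- **Negative NJ branch lengths** are clamped to 0, the usual practice.
- **Tie-breaks:** cluster ordering by size then lexicographically
  smallest member; merge candidates by highest ratio, then smallest
  cluster index; UPGMA joins by smallest index (via stats::hclust);
  species representatives by smallest genome id. All choices are
  deterministic so identical inputs give identical outputs.
- **Degenerate inputs:** empty sequences, zero-column alignments,
  all-masked profiles, non-symmetric matrices, fewer than 3 NJ rows, and
  zero-variance correlations all raise errors rather than returning
  silently wrong values; unknown feature annotations are mapped to
  "other" with a warning (the single documented repair).

## Known limitations

- The profile scorer is a frequency-profile stand-in, not an HMM–HMM
  aligner; merge decisions near the 0.1 ratio threshold can differ from
  tools that use posterior-probability scores.
- MGE assignment uses only replicon class and MGE-marker proximity;
  prophages integrated in chromosomes are out of scope (originally a
  manual, tree-informed call).
- Pairwise NW co-optimal alignments are resolved by a fixed traceback
  preference; identity values on deliberately ambiguous pairs may differ
  from other implementations even when scores agree.
- The pipeline is single-threaded and desk-scale; the published analyses
  it mirrors ran on tens of thousands of genomes.
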