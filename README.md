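# phyloscope

Phylogenomic analysis of large, diverse prokaryotic gene families — built
around the questions raised by the Cas4 nucleases of CRISPR–Cas adaptation
modules, which occur inside CRISPR–cas loci (CAS), as stand-alone genes
(solo), and on mobile genetic elements (MGE).

The package answers three questions for a family of protein sequences
drawn from many genomes:

1. **How is the family structured?** Greedy single-linkage clustering by
   global-alignment identity and coverage (identity ≥ 0.5, coverage ≥ 0.8
   for proteins; 0.9/0.9 for 16S rRNA), progressive profile alignment
   within clusters, removal of alignment columns with gap fraction > 0.5
   or homogeneity < 0.1, then an iterative procedure that merges clusters
   whenever their profile–profile score to self-score ratio exceeds 0.1,
   builds neighbor-joining trees per merged cluster (bootstrap support on
   kept columns), and grafts them onto a UPGMA dendrogram of the
   remaining cluster dissimilarities — one comprehensive family tree.

2. **How vertical is its evolution?** For every genome pair, the shortest
   patristic distance between family members is compared with the 16S
   rRNA distance; pairs whose sequences sit in clusters that were never
   aligned together receive sentinel distances (12 for proteins, 3 for
   rRNA). The Spearman rank correlation ρ of the two distance columns
   measures coherence with the species tree: vertically inherited genes
   give high ρ, horizontally transferred ones low ρ.

3. **What is the selective regime and genomic context?** Pairwise dN/dS by
   the Nei–Gojobori (1986) counting method with Jukes–Cantor correction,
   summarized as per-group medians; and a per-gene classification into
   CAS / solo / MGE from the annotated gene neighborhood (cas1/cas2/cas6,
   effector, CRISPR-array and MGE-marker features within a configurable
   window, replicon class, cas4/cas1-fusion precedence), with
   species-weighted presence summaries.

A synthetic-data generator (Yule species tree; gene family evolving with
subtree-prune–regraft transfers, duplications and losses; Muse–Gaut/HKY
codon sequences with tunable dN/dS; a slow 16S-like marker; feature tables
with realistic adaptation-module arrangements) provides ground truth so
every stage is testable by parameter recovery.

## Worked example

```r
library(phyloscope)

cfg <- simulation_config(n_genomes = 20, hgt_rate = 0.5, dup_rate = 0.05,
                         seq_len_codons = 150, rrna_len = 800,
                         locus_mix = c(cas_operon = 0.5, solo = 0.3,
                                       mge = 0.2),
                         seed = 7)
report <- run_all(cfg, out_dir = "run1")
print(report)
```

prints

```
pipeline report
  sequences: 24  clusters: 1 -> 1 after merging
  transfers simulated: 1
  coherence rho (gene vs 16S): 0.704 over 190 genome pairs
  dN/dS medians: CAS=0.080, MGE=0.067, solo=0.085
  categories: CAS=13, MGE=5, solo=6
  context label recovery vs truth: 100.0%
```

Reading this: the 20 genomes carry 24 family genes (duplications made a
few genomes multi-copy); at this divergence all genes fall in one cluster,
so no sentinel distances arise. ρ = 0.70 reflects mostly vertical descent
(one transfer) blurred by tree-estimation noise from 150-codon sequences —
see the methods vignette for why estimated ρ sits well below 1 even
without transfer. The dN/dS medians near 0.08 recover the simulated
ω = 0.1 (moderate purifying selection), and the context classifier
recovers every simulated locus label. Stage outputs (FASTA, feature TSV,
Newick trees, genome-pair table, JSON report) are written to `run1/`.

A command-line wrapper with `simulate`, `run-all` and `classify`
subcommands is in `inst/cli/phyloscope.R`.

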