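# repbiophys

Integrated biophysical characterization of immune repertoires in R.

Adaptive immune recognition is carried by a handful of hypervariable
segments — the CDR loops of T cell receptors and antibodies, the short
peptides presented on MHC — embedded in otherwise rigidly conserved
scaffolds. `repbiophys` analyzes repertoires of such sequences without
structures and without black-box classifiers: sequences are aligned by
simple pseudo-structural rules, expanded into per-position biophysical
property vectors, and then characterized with ordinary, inspectable tools —
clustering, entropy, permutation tests, Euclidean distances, linear
discriminants. Every result decodes back to "this property, at this
position".

It is aimed at immunologists and bioinformaticians comparing receptor or
peptide subsets: antigen-sorted vs unsorted TCRs, peptides eluted from two
HLA alleles, paired- vs single-chain data, or synthetic benchmarks with
planted signal.

## The core encoding and model

Each molecule is an ordered set of feature strings (e.g. `cdr3a`, `cdr3b`,
or one peptide column). Each feature is placed independently in a
fixed-width window, under one of four schemes:

- **central** — the central residue (for even length `L`, the residue at
  `L/2 - 1`, i.e. preceding the midway point) is anchored at the window
  center, so loops of different lengths overlap at their apex;
- **left / right** — N- or C-terminal anchoring;
- **bulge** — `pad_len/2` residues are pinned to each window edge and the
  remainder centrally aligned, mimicking how class-I peptides bury terminal
  anchors and bulge in the middle.

This yields an integer matrix with codes 1–20 (residues, alphabetical
one-letter order) and 0 (pad). A residue dictionary then attaches 62 values
per amino acid (1 positional-visualization value + 61 biophysical
properties, each Z-scored across the 20 residues), giving a
sequences × positions × properties tensor. Flattened, stripped of empty and
mutually correlated columns (|r| > 0.75), and optionally re-weighted by
per-column Shannon entropy `H/log2(20)`, this is the feature space for:

- UMAP / PCA / t-SNE projection and DBSCAN / OPTICS / k-means /
  hierarchical clustering, scored by **cluster purity** against metadata;
- position-sensitive statistics: residue frequencies, Shannon entropy
  `H(X) = -Σ p(x) log2 p(x)` (ceiling `log2(20) = 4.32` bits), mutual
  information `I(X;Y) = H(X) - H(X|Y)`, ordered N-gram distributions;
- nonparametric inference: bootstrapped means and the two-sided permutation
  test `p = (1 + #(z² ≥ z0²)) / (R + 1)` on differences of means;
- raw Euclidean distances in the high-dimensional space, with hierarchical
  cutoff clustering and correlation harnesses against external metrics;
- interpretable LDA whose largest weights decode to (position, property).

A V(D)J-style simulator generates labeled CDR3 benchmarks (V prefix →
biased insertions → J suffix) for end-to-end evaluation.

## Worked example

Generate the three-subset synthetic benchmark (insertions drawn uniformly,
positively charged-biased, or negatively charged-biased) and run the
standard pipeline:

```r
library(repbiophys)

bm <- preset_benchmark(n_per_subset = 1000, seed = 1)
bm
#> Repertoire: 3000 sequences, 1 feature(s) [cdr3]
#>   metadata: subset
#>   source: simulated benchmark (3 x 1000, seed 1)

ev <- evaluate_benchmark(bm)   # central encoding -> tensor -> parse ->
ev$purity                      # UMAP(3) -> DBSCAN -> purity vs subset
#> Cluster purity vs 'subset': 0.753 +/- 0.191 over 100 clusters (82% clustered)
```

On average 75% of each recovered cluster's members share one generating
subset — unsupervised clustering in the biophysical space re-separates the
three insertion biases. The planted signal is visible directly as net
charge per subset:

```r
tens <- build_tensor(ev$encoded)
sapply(c("KRQN", "Random", "DEHY"), function(l)
  net_average(tens, "charge", group = bm$metadata$subset == l)$mean)
#>   KRQN Random   DEHY
#>  0.418 -0.028 -0.456
```

Positional entropy peaks mid-loop where insertions land and collapses at
the conserved V/J stems, and cluster motifs summarize what a cluster
conserves (letters), prefers as a property class (`X(class)`), or leaves
free (`.`):

```r
round(shannon_entropy(ev$encoded)$H, 2)
#> 0 1.32 2.2 3.37 3.7 3.9 3.92 3.9 3.81 3.64 3.49 2.56 1.21 0

iso <- isolate_clusters(ev$encoded, ev$assignment, 0:2)
cluster_motif(iso$enc, rows = seq_len(iso$boundaries[1]))
#> C C X(small) X(small) . . . X(nonpolar) X(nonpolar) E Q Y F F
```

A command-line wrapper with `encode`, `cluster`, `profile`, `info`,
`compare`, `dist`, `lda`, and `simulate` subcommands ships in
`inst/cli/repbiophys`.

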