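---
title: "Position-sensitive biophysical repertoire analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-sensitive biophysical repertoire analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repbiophys)
```

This vignette explains what the package computes, the assumptions behind
each stage, the tunable parameters and their defaults, and the design
decisions taken where more than one reasonable construction existed. The
worked numbers in the README are produced by the same code paths; nothing
here asserts a result the tests or the acceptance script do not themselves
compute.

## The pseudo-structural encoding

Immune molecules pair extreme local sequence diversity with rigid global
structure: CDR loops sit on conserved stems, class-I MHC peptides bury
their termini as anchors and bulge in the middle. Instead of predicting
structure per sequence, the encoder exploits these regularities as
*alignment rules*. Each structural feature (a CDR loop, a peptide) is
placed independently into a fixed-width window:

- `central`: the central residue is pinned to the window center. For a
  sequence of even length $L$ the center is the residue *preceding* the
  midway point (0-based index $L/2-1$); the same rule positions the center
  of an even-width window, a symmetry choice that keeps the two rules
  consistent.
- `left` / `right`: N- or C-terminal anchoring, used to check that
  conclusions are not artifacts of the central alignment.
- `bulge`: `pad_len/2` residues are pinned to each edge and the remainder
  centrally aligned in the interior. `pad_len` must be even; 6 is a
  sensible default for class-I peptides (three anchor-side residues per
  terminus). A sequence shorter than `pad_len` fills the N-terminal block
  first, then the C-terminal block from the right — an arbitrary but
  deterministic rule for a degenerate case real peptide data rarely hits.

Residues map to codes 1–20 in alphabetical one-letter order (A=1 … Y=20);
0 is pad; 21 is reserved for a non-standard placeholder and never emitted
for validated input. Window widths default to the per-feature dataset
maximum, which makes matrices dataset-dependent; whenever two datasets are
compared positionally (difference reports, co-parsed distances) their
widths must be pinned to a shared grid via `feature_widths`. Gap characters
in pre-aligned MSA input encode as pad in place ("as-aligned" mode), so
alignment columns survive into every downstream position-sensitive figure;
a strip mode removes gaps and lets the encoder re-align instead.

The encoding is lossless within a window: reading a row's non-zero codes
left-to-right reproduces the feature string. This is tested as a
round-trip property and is what makes cluster re-visualization and motif
extraction trustworthy.

## The property dictionary

Each residue carries 62 values: one positional-visualization value plus 61
biophysical properties. Every property is Z-scored across the 20 residues
of the dictionary — never across a dataset — using the population standard
deviation (divisor 20, fixed for reproducibility; the choice is
immaterial up to a constant factor that normalization-invariance tests
confirm changes nothing downstream). Pad cells are exactly 0, i.e. at the
dictionary mean of every property; this is what lets sparsely covered stem
columns dilute toward neutrality rather than toward an arbitrary residue.

The bundled table (`inst/extdata/aa_properties_synthetic.csv`) is an
authored stand-in, flagged *synthetic* in its filename: 14 canonical
published scales (Kyte–Doolittle hydropathy, Eisenberg hydrophobicity,
Hopp–Woods hydrophilicity, residue volume and weight, isoelectric point,
flexibility, Zimmerman bulkiness, Grantham polarity, Chou–Fasman
helix/sheet/turn propensities, Miller accessible surface area), net charge
at pH 7, class indicators, hydrogen-bond donor/acceptor counts, and
deterministic pairwise products of the z-scored core scales as
hotspot-style composite descriptors. Any 20-row CSV with the same layout
replaces it at run time (`load_property_table(path)`); all package
behavior that matters — normalization identities, filtering, distances,
discriminants — is independent of the specific scales chosen. Constant
(zero-variance) properties are dropped with a warning rather than
producing NaNs. A 20×20 pairwise interaction chart of textbook propensities
(salt bridges +, like charges −, hydrophobic packing, aromatic stacking,
donor–acceptor hydrogen bonds), equally synthetic and replaceable, backs
the optional position-pair interaction report.

## Parsing: the analysis feature space

The $n \times W \times 62$ tensor flattens position-major to
$n \times 62W$. Biophysical summaries (position and net averages, masks,
significance overlays) always use the full tensor; projection, distance,
and LDA use the *parsed* matrix:

1. all-zero columns (pure pad, forced gaps) are dropped;
2. scanning columns in index order, any column with |Pearson r| > 0.75
   against an earlier retained column is dropped. Keeping the earlier
   column of a violating pair is the deterministic tie-break; zero-variance
   columns correlate with nothing and are retained.
3. optionally, each retained column is multiplied by the Shannon entropy of
   its source alignment column divided by $\log_2 20 = 4.3219$ bits. The
   re-weighting formula is this package's construction for a step that is
   usually described only by name; it has the two properties one wants —
   invariant positions are silenced entirely, maximally diverse positions
   are untouched — and the 0.75 threshold above is applied before it so the
   weighting cannot rescue a redundant column.

Averaging conventions: `position_average` includes pad cells in the
denominator by default, so a property trace decays toward 0 where coverage
decays — length variation reads as signal dilution at the stems, which is
the intended emphasis on loop centers. A `coverage_norm` mode divides by
occupied counts instead. `net_average` is per-sequence first (sum over
occupied cells / occupied count), then averaged over the group, so long and
short sequences weigh equally.

## Projection and clustering

Defaults follow the conventions of the field: 3 components for UMAP and
PCA, `n_neighbors = 25` for UMAP, full-SVD PCA, DBSCAN at `eps = 0.15`
with `min_pts = 5`, OPTICS at `min_pts = 10`. The projection seed defaults
to 617 and UMAP runs single-threaded, which makes coordinates bit-identical
across runs; determinism is tested, not assumed. DBSCAN and OPTICS are
implemented inside the package (grid-binned fixed-radius neighbor search;
O(n²) OPTICS ordering), keeping the density-clustering semantics fully
under the package's control; DBSCAN is validated against a brute-force
reference on random geometries. OPTICS flat clusters are extracted
DBSCAN-equivalently at `eps_cl` (default 0.15) from the reachability
ordering — the ξ-based extraction of some libraries is not reproduced, a
deliberate simplification since density clustering here feeds purity
scoring, not reachability-plot analysis.

Cluster purity is the majority-label fraction per cluster, summarized as
an *unweighted* mean ± SD over clusters, with noise points (label −1)
excluded; both choices match how such summaries are conventionally
reported, and an inclusive mode exists. Note a statistical caveat the
tests encode: with many minimum-size clusters the *null* purity of
shuffled labels sits well above $1/k$ (order statistics of small
multinomials), so purity comparisons should always be read against a
shuffled-label baseline, which `purity()` makes cheap to compute.

## Information theory

Frequencies, entropy, and mutual information are plug-in estimators over
the encoded matrix, *conditional on occupancy*: pad cells never enter
$p(x)$, and per-column coverage is reported alongside so that low-coverage
artifacts stay visible rather than masquerading as conservation. Zero
coverage yields zero entropy by convention. MI uses pairwise-complete rows
and no small-sample bias correction; on tiny instances it is tested
against exhaustive joint-count computation, and its matrix is symmetric,
non-negative, with per-column entropy on the diagonal. N-grams deliberately
run on the raw feature strings, not encoded columns, so alignment pads can
never fabricate grams, and windows never cross feature boundaries.

## Statistics

Position-sensitive averages of discrete residue properties are not normal,
so summaries are bootstrapped (1000 resamples by default) and significance
comes from a two-sided nonparametric permutation test on the difference of
means: $p = (1 + \#(z^2 \ge z_0^2))/(R+1)$ with $R = 1000$ by default.
When the number of distinct relabelings is at most 10,000 the test
enumerates them exhaustively instead of sampling — the 2-vs-2 case with
disjoint values then gives exactly $p = 3/7$, which the tests pin down.
The identity $p(R+1) - 1 = \#$ holds exactly on every run, the p-value is
floored at $1/(R+1)$, and the empirical type-I error at $\alpha = 0.05$ is
checked over 500 null replicates. Per-position p-values are reported raw
(per-position flags, with maximal runs of ≥ 2 flagged columns annotated as
regions), matching how such overlays are conventionally drawn; a
Benjamini–Hochberg mode exists and is off by default. A studentized
bootstrap alternative (groups recentered to the pooled mean, resampled
within group, pivot $t$) is provided for users who prefer it.

## Distances and discriminants

Because nonlinear projections do not preserve distances, the distance
module works in the parsed high-dimensional space directly: plain Euclidean
distances, optionally restricted to the columns of a feature subset
(CDR3-only vs all loops) taken as sub-blocks of one joint parse so that the
two scopes stay comparable. All-zero columns provably do not move
distances. Hierarchical clustering cuts an average-linkage dendrogram (the
linkage is configurable) at a distance cutoff, and a correlation harness
compares against any externally produced distance matrix in the same CSV
shape, overall and restricted to near pairs where metrics are expected to
agree best.

LDA is kept deliberately interpretable: a univariate pre-selection
(F-statistic by default, quantile-binned mutual information as an option)
caps the feature count at $\min(50, n/10)$ against overfitting, the
discriminant is fitted with `MASS::lda`, and a ridge-regularized
eigen-fallback handles singular within-class scatter. The reported output
is the magnitude-sorted weight table decoded to (position, property),
which on simulator output recovers the planted charge signal — the
parameter-recovery test that anchors the module.

## The simulator and what passing it shows

Synthetic CDR3s are built as V prefix (0–2 junctional deletions, uniform) +
i.i.d. insertions + J suffix (0–2 leading deletions). The bundled pool —
8 V prefixes of 4–6 residues starting with C, 6 J suffixes of 4–6 residues
ending with F, selection weights drawn once from a seeded uniform — is
deliberately pseudo-random rather than biological. Insertion presets:
`Random` = 1/18 on each residue except C and P (excluded everywhere);
`KRQN` = weights 20 on K,R and 10 on Q,N over unit weights (so
$P(K) = 20/74$); `DEHY` symmetric with D,E and H,Y. Per sequence a target
length is drawn uniformly from 11–14 and the insertion count makes up the
difference, floored at zero, so all lengths land in 11–14. The benchmark is
three subsets of 5,000 (15,000 total).

The standard evaluation pipeline is: central encoding → tensor → parse
with re-weighting → 3-component UMAP (seed 617) → DBSCAN(0.15) → purity
against the generating subset. At full scale this recovers mean purity in
the low-to-mid 0.7s across seeds (logged by `scripts/acceptance.R`), with
most impurity contributed by the unbiased `Random` subset whose sequences
can wander into either charged cluster — exactly the failure mode one
should expect of a biophysically faithful clustering, since a "Random"
sequence enriched in K by chance *is* biophysically a KRQN-like sequence.

What passing these tests does **not** show: the simulator has no germline
V/J usage structure, no nucleotide-level junctional machinery, no
hypermutation, and planted effect sizes far stronger than typical
antigen-specificity signal; real repertoires will cluster less cleanly,
and purity against real metadata should be compared against the
shuffled-label baseline discussed above. Tests on the simulator validate
the *machinery*, not effect sizes in real data.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at 3 × 1,000 benchmark scale
and the acceptance script at the full 3 × 5,000, sizes chosen to keep a
complete run in the minutes range on a single core while preserving the
density regime DBSCAN's `eps = 0.15` expects; density clustering at a few
hundred points is below that regime and mostly labels points noise, which
is why the small-scale unit tests score geometry with planted blobs
instead. Other numerical conventions collected in one place: $0 \log 0
\equiv 0$ throughout; MI values are clipped at 0 against floating-point
negatives; permutation ties are counted with a $10^{-12}$ tolerance on
$z^2$; correlation of a zero-variance column is treated as 0; bootstrap SD
of a constant vector is exactly 0; all RNG-dependent routines take explicit
seeds and the package never consumes global RNG state silently.
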