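---
title: "Motif discovery from promoter alignments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif discovery from promoter alignments: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifforge)
```

`motifforge` predicts transcription factor binding motifs (TFBMs) from
multi-species promoter alignments by learning intrinsic properties of
known binding sites, and then mines the combinatorial patterns the
predicted motifs form across promoters. This vignette explains the
statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical and design decisions a maintainer should know about.

## 1. The data model

The unit of input is a multiple-alignment block per promoter: one
reference (human) row and aligned rows for the other species, read and
written in MAF. All internal coordinates are 0-based half-open, so BED
export is lossless. The alphabet is uppercase `A,C,G,T,N,-`;
soft-masked lowercase is uppercased on read, and any window whose
reference bases include `N` or a gap is skipped at word extraction.
IUPAC degeneracy codes are deliberately not used anywhere: motifs are
represented as position weight matrices (PWMs), 4 × m column-stochastic
matrices, which retain the full base-frequency information.

A **DNA word** is a length-n window of the reference row. Identical
words are collapsed into one dictionary entry that accumulates, over
all its loci:

* `a` — the number of appearances (loci);
* `c` — the number of (locus, species) pairs whose aligned subsequence
  equals the word exactly. The reference row counts, so in the
  zero-mutation limit `c = a * n_species`;
* the conservation curve — per-base counts of species matching the
  reference base — and the per-species Hamming distances that define
  the species-similarity permutation.

Word-level aggregation has a consequence that matters at small n: a
short word recurs by chance in background sequence, so its aggregated
profile is a mixture of conserved (site) and unconserved (background)
loci. The pipeline therefore builds its *learning set* from the
dictionary entries of the known site words, not from site-locus-only
statistics, keeping queries and references in the same representation
(a known word then always passes its own filter).

## 2. Dictionary filters

**Permutation-prefix filter.** For each word the non-reference species
are ordered by ascending Hamming distance to the word (gaps count as
mismatches; ties resolve to the canonical species order of the
alignment; the reference row is excluded because its distance is
identically zero). The first k species form the prefix; a word passes
iff its prefix was seen among known binding-site words. Default
`k = 5`, clamped to the number of non-reference species. The intuition
is that genuine sites are conserved in characteristic species subsets,
while a full permutation would be essentially unique per locus.

**Conservation-curve filter.** Profiles are normalised to [0, 1] by
dividing by `a * n_species`; a word passes iff its minimum Euclidean
distance to any learned profile is at most a tolerance. The tolerance
is calibrated on the learning set as the 95th percentile of
leave-one-out nearest-neighbour distances, so roughly 95 % of held-out
true sites would pass. Both filters are contractions (output ⊆ input)
and the dictionary is their intersection.

## 3. Clustering and ranking

The **conglomerate distance** between equal-length sequences is
`d = L − (1/L) Σ l_i²` over the lengths of maximal matching runs. It
is zero on identity, maximal (L) when nothing matches, symmetric, and
at fixed Hamming distance it increases as matches fragment into more
runs — contiguous "chunks" of agreement are rewarded. It is used as a
dissimilarity only; no triangle inequality is assumed. Neighbour search
is an exact full scan (a batch kernel in C); approximate indexing is a
scale optimisation this package does not need.

Each dictionary word seeds a cluster of its `k_members = 32` nearest
words. A greedy refinement then removes, one at a time, the member
whose removal most reduces the minimum Euclidean distance between the
cluster's per-column entropy curve and the entropy curves of known
motifs, stopping at distance `tau` or at `min_size = 5` members. `tau`
is calibrated like the curve-filter tolerance (95th percentile of
leave-one-out distances among the learned curves; 0.1·√n if only one
curve is available). The entropy computation is incremental over count
matrices, so refinement costs O(members² · n) per cluster.

Clusters are ranked by `S = P_c + P_a` with
`P_c = Σc_i / (n_species Σa_i)` (fraction of instances conserved) and
`P_a = Σa_i / (n_members · a_max)` (appearance mass against the
dictionary-wide maximum `a_max`), each in [0, 1]. At equal S the
cluster with *lower* average entropy ranks first: the ordering is meant
to surface specific motifs, and between two equally conserved and
equally frequent candidates the sharper one is the more credible
binding model.

## 4. The DDS one-class filter

Each cluster maps to a fingerprint of dimension `2n + 4`: n entropy
components, an n-bin histogram of pairwise Hamming distances among
member sequences, and four scalars — an over-conservation z-score
(`Σc` against `Binomial(n_species·Σa, p₀)` with `p₀` the background
per-species word-conservation rate, estimated from the unfiltered
dictionary), the number of loci conserved in at least one non-reference
species, the mean conserved-species count per base, and the average
entropy. The z-score stands in for an external conservation statistic
in the same one-dimensional role; any other over-conservation score
can be plugged into that slot.

These components have wildly different scales, which is exactly why
DDS never combines them metrically. For a query, the database is
sorted along every component by closeness; the D rank lists are walked
round-robin, one element per list per iteration (ties broken by
database order), until some object has been sighted in `h` lists or
`t_max = 64` iterations pass. The components that sighted the stopping
object form a binary mask — the dimensions that matter *for this
query*. Training computes one mask per known motif with that object
removed from the database; a query is accepted iff its mask is within
Hamming distance θ of some training mask. Because everything is
rank-based, rescaling any component across the database changes
nothing.

Two defaults here deviate from naive choices, for reasons the
implementation makes visible. A quorum mask has exactly `h` set bits,
so mask distances live on [0, 2h]; any θ > 2h accepts everything.
Conversely very sparse masks (h = 3 in a D = 20 space) make the
acceptance region saturate once a few dozen masks are learned. The
defaults `h = 4`, `θ = h` ("share more than half of your informative
components with some known motif") were chosen by characterising
held-out versus random-cluster acceptance on simulation designs; both
remain configurable. The model database should contain the whole
collection being screened (training plus queries, self excluded at
query time) so that spurious clusters localise among their own kind
rather than being force-matched to the nearest known motif.

## 5. Post-processing and validation

Predictions sharing more than 80 % of member sites (overlap measured
relative to the smaller cluster) are redundant;
a deterministic sweep in descending rank keeps the better one.
Surviving predictions with PWM Pearson correlation ≥ 0.85 are merged
by single linkage, and the merged PWM is rebuilt from pooled member
sites at their best relative offsets and strands, not by averaging
matrices.

PWM comparison slides the two matrices over all ungapped offsets, on
both strands, and correlates the flattened overlapping sub-matrices.
The floor overlap is 4 columns, but a *claim* — merging two
predictions, or declaring a known motif rediscovered — requires the
correlation over at least 3/4 of the shorter motif. This matters: two
sharp 8-column PWMs agree on a 4-column fragment by chance with
probability ≈ 4⁻⁴ per configuration, so fragment-level matching at
r ≥ 0.85 would merge distinct motifs into chains and let shuffled
control PWMs "match" constantly, which is inconsistent with a
random-control match rate on the order of 1 %.

The random control shuffles each known PWM within columns (column
order preserved), which keeps the per-column value multisets and hence
per-column entropies while destroying base identity.

## 6. Combinatorial binding patterns

Motif occurrences along a promoter are grouped with a 1000 bp maximum
gap (end-to-start, boundary inclusive). A motif and its reverse-strand
occurrence are distinct symbols. Pattern assembly is greedy: candidate
groups sharing at least 3 distinct motifs with the seed are added in
shared-count order while the realigned pattern retains at least 3
shared aligned motifs; the multiple alignment is center-star over
symbol strings with Smith–Waterman pairwise alignments (match +1,
mismatch −5, gap open/extend 0 — with these costs a gap is always
preferred to a mismatch; the positive match reward is the minimal
choice the published cost set leaves open). Pairwise scores are cached
and grown incrementally during assembly. Columns supported by fewer
than 3 groups are dropped; a pattern is emitted only if at least two
distinct genes remain. Duplicate patterns keep the highest-AL copy.

`SIG` is the z-score of the observed generality under a null that
permutes motif labels across all occurrence slots genome-wide,
preserving every promoter's occurrence count and positions. This null
isolates combinatorial co-occurrence from occurrence density; "shuffle
the promoters" admits several readings, and this is the one that keeps
group structure intact. A zero null standard deviation is reported as
±Inf with a degenerate flag rather than silently as zero.

The pipeline exports as binding sites only member loci conserved in at
least one non-reference species: an unconserved chance occurrence of a
member word is not a site call. This keeps the CBP stage's input
track at a realistic density.

## 7. Target prediction and enrichment

Gene targets of a motif are predicted with log-ratio-to-consensus
weights `W(w) = Σ_j ln((p_{b_j,j}+ε)/(p_max,j+ε))` (ε = 0.01 guards
log 0); the consensus scores 0 and a gene is a target when its best
window on either strand reaches a threshold placed a fraction
θ = 0.8 up the score range from the minimum toward 0. GO annotations
are propagated to ancestor closure over the DAG (cycles are an error),
enrichment is upper-tail hypergeometric per term with
Benjamini–Hochberg q-values, and ontology maps link each object to its
`top_n = 5` nearest neighbours under the Jaccard distance
`1 − |O₁∩O₂|/|O₁∪O₂|` plus its q < 0.05 terms.

## 8. The synthetic-data generator

The generator emulates the structure the pipeline needs and nothing
more: a star phylogeny (every species an independently mutated copy of
the reference row), uniform background composition, planted sites
drawn per column from their PWMs and mutated at a lower rate than
background, optional planted CBPs at fixed spacings, and no indels —
the dictionary consumes fixed-length gapless words, so indel realism
adds no testing power for the implemented mathematics. Defaults mirror
the real study geometry (5000 bp upstream regions, 45 species); the
bundled validation study uses 50 promoters × 2000 bp × 8 species with
five planted 8-bp motifs of per-column dominance 0.85 and substitution
rates 0.3 (background) / 0.02 (sites), sizes at which the whole
pipeline runs in minutes on one core. Per-species rates may be vectors
so the species-similarity ordering is controllable.

What passing tests on this generator do *not* show: robustness to
alignment artifacts and indels, to non-uniform background composition
(CpG islands, repeats), to a real phylogeny in which species errors
are correlated, or to motifs whose information content is concentrated
in a few columns. Conclusions about real promoter data need the real
alignments.

## 9. Numerical choices and degenerate inputs

* PWM pseudocount 0.01 per cell (configurable) prevents log 0 in
  entropy and scanning; probability columns must sum to 1 within 1e-9.
* Zero-variance PWM overlaps correlate as 0 with a warning (once per
  comparison).
* Singleton clusters have an all-zero distance histogram, with a
  warning.
* All tie-breaks are deterministic: canonical species order in
  permutations, lexicographic word order in neighbour lists, database
  order in DDS scans, id order in cluster sorting, earliest-cell
  preference in alignment traceback. Identical configuration and seed
  reproduce a run directory byte for byte; output files carry no
  timestamps.
* Per-stage result caching was considered and dropped: at the scales
  this package targets a full rerun is cheaper than cache invalidation,
  and byte-reproducibility makes reruns equivalent.

## 10. Known limitations

The dictionary stage aggregates by word, so at n ≤ 8 chance
recurrences of true site words dilute their conservation statistics;
the learning-set construction compensates, but very short motifs in
very large promoter sets remain the hardest case. The conglomerate
distance is not a metric, so no index structure is used. The CBP
assembler's greedy candidate order is by shared-motif count only; an
adversarial ordering could miss a better pattern. Enrichment assumes
the annotation universe is the background of interest; no
composition-matched gene sampling is provided.
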