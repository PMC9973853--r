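---
title: "Scoring biosynthetic novelty: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring biosynthetic novelty: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biniR)
```

## The problem and the statistic

Microbial natural-product discovery is throttled by rediscovery: most
strains picked at random re-deliver known chemistry. A cheap way to rank
candidate strains before any wet-lab work is to ask, for each biosynthetic
gene cluster (BGC) a genome encodes, how far that cluster sits from every
known gene cluster family (GCF), and to summarize a strain by the
biosynthetic novelty index

$$\mathrm{BiNI} = \frac{\sum_i d_i}{n},$$

where $d_i$ is the distance of cluster $i$ to its nearest GCF centroid and
$n$ the number of clusters the annotation tool reports for that genome.
Strains whose repertoires sit far from all known families score high and
are prioritized for isolation work.

Two readings of the defining formula are possible: either every $d_i$
enters the numerator (a plain mean), or only distances above the novelty
threshold do. Published genus-level scores in the low hundreds on a scale
whose novelty line is 900 are consistent with the plain mean, so
`mean_all` is this package's default, but `thresholded_sum` is implemented
as well and every result object records which mode produced it. The same
holds for the choice of $n$: `all_regions` counts every reported region
(the default), `complete_only` restricts to clusters not truncated by a
contig edge, and the scope is always recorded.

## Distances and the two tau regimes

When scores are computed from an ingested distance table (an external GCF
database query export), distances arrive on that platform's scale and the
conventional novelty line is $d > 900$; `score_from_distance_table()` with
`bini_config(tau = 900)` reproduces that pipeline, and the classification
is strict (`d = 900` is still a member).

When no external platform is available, the package builds its own
reference: BGCs become vectors of domain counts over a vocabulary
(`featurize()`), families are formed by greedy centroid clustering
(`build_reference()`), and $d$ is the Euclidean distance to the nearest
centroid. Counts are capped at 5 by default (`scaling = "capped"`) so a
single giant multi-module PKS cannot dominate every distance; domains
absent from the vocabulary accumulate in one reserved bin, so
unrecognized content raises rather than hides novelty. On this local
scale the 900 line is meaningless, so tau is calibrated as a percentile
(default 95, nearest-rank) of member-to-centroid distances.

One statistical subtlety matters here. After the refinement pass each
centroid is the mean of its members, so a member's distance to its own
centroid *understates* the distance a fresh query from the same family
would see. For mean centroids the correction is exact: the distance of
member $i$ to the centroid of the remaining members is
$d_i \cdot n/(n-1)$. `calibrate_tau()` applies this leave-one-out scaling
before taking the percentile. Without it, roughly a third of genuinely
familiar clusters in a new genome land above tau and the measured novel
fraction is badly inflated; with it, the false-novel rate sits at the
nominal $1 - 0.95$.

The greedy builder processes records in a deterministic order (descending
domain count, then lexicographic id), joins the nearest existing centroid
within `build_threshold`, and otherwise opens a new family; one
refinement pass recomputes centroids as member means. This is
deliberately not a full k-means: it is deterministic, order-stabilized by
the sort, and adequate for a reference stand-in. Ties in nearest-centroid
queries break toward the lexicographically smallest family id, purely for
reproducibility.

## The synthetic landscape and what it does (and does not) emulate

All pipeline stages are exercised against generated data with planted
ground truth. The landscape generator draws `n_gcfs = 20` centroid domain
sets of 14–28 domains from a 300-domain vocabulary, plus, by default, 4
small "common" families of 3 domains each — the ubiquitous short clusters
most genomes share. Members are centroids with one random domain
substitution. In capped-count space one substitution displaces a vector
by exactly $\sqrt 2$, so two members of one family are at most distance 2
apart; centroids are resampled until ordinary families are at least 5.1
apart (small families only need disjointness, and their size asymmetry
against large families keeps them separate anyway). With the default
`build_threshold = 2.2` sitting strictly between the within-family bound
(2.0) and the worst-case cross-family bound (≥ 2.27), family recovery is
exact by construction, which is what makes the adjusted-Rand checks
meaningful rather than lucky. Members of the 3-domain families are copied
verbatim: substituting one of three domains would change a third of the
cluster, which in practice is a different family, not a variant.

Strain repertoires draw 15–35 clusters per genome (bracketing the ~25
clusters typical actinobacterial genomes carry). A configured fraction
per strain is novel: random domain sets rejection-sampled until they sit
at least 5 feature-space units from every centroid, comfortably above the
calibrated tau (≈ 1.4–1.5), so planted novelty is unambiguous. Small
families are oversampled threefold in member draws, making them common
across strains.

The fragmentation experiment models assembly quality loss as
$k \sim \mathrm{Poisson}(1.5)$ contig breaks per cluster at random
positions between domains, each break splitting the domain list in order
and flagging the pieces incomplete. The mechanism that reproduces the
empirical direction — novelty is *underestimated* on fragmented
assemblies — is geometric: a fragment of a far-from-everything cluster
has few domains and a short count vector, and short vectors are
necessarily close to the small common centroids, while fragments of
familiar clusters drift moderately *away* from their own family. The net
effect at the repertoire level is a drop in median BiNI, and the
experiment reports per-seed medians plus a one-sided sign test of
(fragmented < intact). This is a modelling choice that reproduces the
qualitative phenomenon; it makes no claim about the quantitative size of
the drop in real assemblies.

What the generators do *not* emulate: real Pfam domain grammars (domains
are exchangeable tokens), nucleotide-level sequence, read sets, biased
GC, or the heavy-tailed family-size distribution of real GCF databases.
A test suite that passes on this landscape demonstrates the pipeline's
internal correctness and calibration, not the accuracy of any specific
published score — absolute published BiNI values depend on a live,
continuously growing external database and are not reproducible at desk
scale.

## Similarity networks

The network stage mirrors the common practice of drawing an edge between
two complete BGCs when their raw distance is at or below 0.3 and reading
connected components as families, with degree-0 nodes as singletons —
the candidate novel clusters. The distance is
$1 - (0.7\,J + 0.3\,\mathrm{AI})$, where $J$ is the Jaccard similarity of
the domain sets and AI the Jaccard similarity of the sets of adjacent
ordered domain pairs. The domain sequence similarity (DSS) term used by
the full BiG-SCAPE raw distance requires per-domain alignments and is
deliberately omitted; the remaining weights are renormalized. Two
empty-domain records are at distance 1 by convention, and a single-domain
record has no adjacency pairs, so AI contributes 0 against anything. The
edge rule is inclusive (`distance <= cutoff`). Component annotation
against a reference collection (MIBiG-style) labels a component when any
member is within the cutoff of any reference record, taking the nearest
on ties. Note that singletons here are defined by having *no* neighbor
within the cutoff; descriptions that phrase singletons as "distance lower
than the cutoff" invert this convention and are not followed.

## Pan-genome stage

Proteins are clustered into families by usearch-style greedy centroid
clustering: records in descending length order, each joining the first
centroid whose global-alignment identity reaches 0.5, else founding a new
family. Identity is matches divided by alignment length under a
Needleman–Wunsch alignment with match +1, mismatch 0, and a linear gap
penalty of 1 (computed with `Biostrings::pairwiseAlignment`). A word
filter skips alignments against centroids sharing fewer than four 4-mers
with the query — the same candidate-pruning idea usearch uses — because
sequences below that overlap cannot plausibly reach 0.5 identity;
sequences shorter than 12 residues are always aligned. First-fit joining
(rather than best-fit) follows the greedy convention and keeps the
procedure order-deterministic.

Families present in every genome are core, in exactly one genome unique,
otherwise accessory; the three sets partition the family universe and
per-genome unique counts are reported alongside totals, since "mean
accessory genome" phrasings in the literature are ambiguous between
per-genome means and totals. Rarefaction permutes genome order (default
500 permutations, seeded) and records pan and core curve quantiles.
Heaps' law $\mathrm{pan}(N) = \kappa N^\gamma$ is fit by least squares on
the log-log scale; the confidence interval for $\gamma$ comes from a
bootstrap over the stored permutations, and the pan-genome is called open
when the lower CI bound exceeds 0.02 — a small positive floor chosen
because openness is conventionally asserted without a printed criterion,
and a CI bound just above zero is indistinguishable from sampling noise.

The simulated pan-genome uses 8 genomes with 30 core families, 20
accessory families at presence probability 0.5 (redrawn if a draw is
degenerate, so planted accessory families are truly accessory), 10
private families per genome, and 200-residue proteins mutated at 10% per
residue per copy (substitutions only). Within-family identity then
concentrates near $0.9^2 \approx 0.81$ and unrelated proteins near the
random-alignment floor (≈ 0.3), so the 0.5 threshold separates them with
wide margins; the open-pan-genome checks scale up to 12 genomes and 20
private families per genome. These sizes give a structured, non-trivial
pan-genome while keeping the whole suite quick to run.

## Degenerate inputs and numerical conventions

* A strain with zero in-scope clusters raises a typed
  `bini_undefined_score` condition — never a silent 0, which would
  mis-rank.
* N50 is the length at which the descending cumulative contig length
  first reaches half the assembly; G+C excludes Ns and ambiguity codes
  from the denominator and is reported to one decimal.
* GenBank coordinates (1-based inclusive) convert to 0-based half-open
  internally; percentiles use the nearest-rank convention; all
  serialization orders rows lexicographically so outputs are
  byte-deterministic.
* Every generator is a pure function of its config and seed (RNG state is
  restored around each call), and every stochastic result records its
  seed.

## Known limitations

The domain-composition feature space is a stand-in for vectorized pHMM
features of real GCF engines; local distances are not numerically
comparable to any external platform's scale, which is exactly why tau is
percentile-calibrated rather than fixed at 900. The greedy reference
builder is sensitive in principle to pathological geometries (chains of
families spaced just at the threshold) that the generator deliberately
avoids; on real data the intended use is scoring against an external
distance export, with the local reference as a self-contained fallback.
KEGG-style functional annotation of core/accessory/unique families is out
of scope — the partition export carries family ids so users can annotate
externally.
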