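---
title: "Methods: graph-semantic fusion for gene-set clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-semantic fusion for gene-set clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pagfusion)
```

This vignette is the package's own account of its models and the choices
behind them: what is computed, which parameters matter, what the synthetic
generators do and do not emulate, and where the method's known limits are.

## 1. The overlap network

A PAG (pathway / annotated gene list / gene signature) is a named gene set
with a free-text description. Gene identifiers are opaque strings: the
mathematics never depends on identifier semantics, so no species or
identifier-type normalization is attempted.

The co-membership ("m-type") network connects two sets whose gene overlap
is larger than chance. For sets of sizes $n_a$, $n_b$ in a universe of $N$
genes with observed overlap $k$, the edge test is the one-sided enrichment
tail $P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, n_a, n_b)$ — depletion is
meaningless for this purpose. Edges with $p \le$ `p_cutoff` (default 0.05)
and overlap $\ge$ `min_overlap` (default 1) receive weight $-\log_{10} p$,
which is nonnegative and grows with evidence strength. Both cutoffs are
exposed because public PAG databases do not publish theirs; no
multiple-testing adjustment is applied by default for the same reason. The
universe defaults to the union of member genes and can be overridden with
an explicit background. Isolated sets stay in the node list: downstream
stages guarantee full coverage of the collection.

## 2. Graph embeddings

`embed_graph()` learns one vector per network node from biased
second-order random walks fed to skip-gram with negative sampling.
Defaults (walk length 80, 10 walks per node, context window 10, 5
negative samples, return parameter $p = 1$, in–out parameter $q = 0.25$)
follow common practice for community-sensitive node embeddings; $q < 1$
pushes walks outward, emphasizing mesoscale structure. The embedding
dimension defaults to 64, with 256 the preferred setting for larger
collections; skip-gram runs 5 epochs at initial learning rate 0.025 with
linear decay (epoch count and learning rate are conventional defaults —
no external source prescribes them). Edge weights act as unnormalized
transition preferences; an unweighted toggle exists because it is
equally defensible to walk the thresholded skeleton.

Three deliberate contracts:

* **Isolated nodes get zero vectors.** They carry no connection evidence,
  and a zero row is the honest encoding (it also survives L2
  normalization unchanged). Applied to every dataset, not only those
  where the convention is forced.
* **Rows are L2-normalized**, making cosine geometry the shared currency
  of both embedding channels.
* **Bitwise determinism for a fixed seed.** Walk generation and training
  run single-threaded on a self-contained RNG; each walk derives its own
  stream from (seed, walk index), so results are independent of
  scheduling.

## 3. Semantic embeddings

Descriptions pass through a *text-encoder port*: any function mapping a
character vector to a numeric matrix. The built-in offline encoder hashes
tokens (lowercase, split on non-alphanumerics) to fixed pseudo-random
Gaussian directions and sums them with counts — a deterministic
random-projection bag-of-words. It needs no model files or network and is
the encoder used by every quantitative test. Remote sentence encoders
plug into the same port; nothing in the package requires them.

`pca_align()` projects the (typically higher-dimensional) semantic matrix
down to the graph dimension. Two constraints can conflict: the blend
needs *equal dimensions*, while one would also like to retain ~95% of
the text variance. Dimension match wins — it is structural — and a
shortfall below 95% becomes a recorded warning instead. Projected rows
are L2-normalized.

## 4. Fusion

$$D_f = (1 - \alpha)\,D_g + \alpha\,D_s, \qquad \alpha \in [0, 1]$$

Blend mode is the authoritative formula; `concat` mode
($[\sqrt{1-\alpha}\,D_g,\ \sqrt{\alpha}\,D_s]$) is kept because its inner
products reproduce exactly the same $\alpha$-weighted similarity
structure, which some back-ends prefer. $\alpha$ defaults to 0.8
(semantic-leaning); `grid_search_alpha()` tunes it on labeled groups by
mean ARI over a 0–1 grid in steps of 0.1, breaking ties toward the larger
(more semantic) $\alpha$. Fused rows are not re-normalized by default (a
flag exists): the blend of two unit vectors already lies in the unit
ball, and renormalizing would distort the relative confidence that the
row norms encode.

## 5. Clustering back-ends and agreement metrics

Embedding methods: k-means (fixed-seed initialization, 10 restarts),
agglomerative (Ward linkage on Euclidean distances — the common library
default), and HDBSCAN (implemented in-package: core distances with
`min_samples = min_cluster_size` (default 5), mutual-reachability
single-linkage hierarchy, condensed tree, excess-of-mass selection; points
never captured by a selected cluster are noise, label −1). Graph methods:
spectral, Louvain, Girvan–Newman (cut at the first split reaching the
requested k).

Spectral clustering runs k-means on the k eigenvectors of the symmetric
normalized adjacency $D^{-1/2} A D^{-1/2}$ with **largest absolute
eigenvalue**. Large positive eigenvalues capture assortative (community)
structure; large negative ones capture disassortative, bipartite-like
structure. Both kinds of planted two-block partition are therefore
recoverable — important below, where spectral recovery defines the
clusterability ground truth and dense anti-community regimes genuinely
are clusterable.

ARI is the chance-corrected pair-counting index; NMI normalizes mutual
information by the arithmetic mean of the label entropies (the common
default), with a zero-entropy partition scoring 0 by convention. Noise
labels (−1) pass through to the metrics as an ordinary label. Both are
implemented from the contingency table and tested against brute-force
pair-enumeration and hand-computed-entropy oracles, plus an independent
library implementation.

## 6. Consensus selection of k

For each candidate k, the inner clusterer runs on `n_resamples = 100`
random 80% subsamples; entry $(i,j)$ of the consensus matrix is the
fraction of co-sampled runs in which the pair co-clustered (pairs never
co-sampled are imputed 0, with a logged count). The area under the CDF of
consensus values grows as k increases; the *relative* gain (Δ area)
collapses once added clusters stop carving real structure.

Two operational choices required genuine design decisions:

* **Plateau rule.** A fixed "Δ below 5%" threshold is not scale-free: on
  clean data the area still grows by 5–20% per extra k from the mere
  fragmentation of stable clusters, with the size of that floor depending
  on cluster sizes. What is invariant is the *collapse*: the package
  selects the k with the largest drop in Δ area (ties within
  `stability_tolerance = 0.05` break toward smaller k, preferring the
  smaller k that already achieves high consensus). A no-structure guard
  precedes this: if no candidate k reaches a proportion of ambiguous
  consensus values (PAC) ≤ 0.1, the floor of the range is returned with a
  flag — structureless data should not get an elbow read into them.
* **Inner clusterer.** Ward hierarchical clustering (the consensus
  literature's canonical inner engine, and the more stable choice in our
  calibration runs on blob fixtures); k-means remains the default *final*
  clusterer and is available inside the consensus loop as an option.

Scope: the rule is calibrated for the small-k regime this package
operates in (the benchmarks cluster two to a handful of parent terms).
On four or more equally sized clusters the elbow can under-read by one —
a documented limitation, not a supported use.

## 7. Clusterability and the CDI

Whether a PAG network should be clustered at all is itself a prediction
problem. Training data: two-block SBMs sweeping intra- and inter-block
connection probabilities over $\{0.1, \dots, 1.0\}$ in steps of 0.1, 10
replicates per cell, $n = 200$ nodes, equal blocks (proportions 0.7/0.3
and 0.9/0.1 are available options). The 200/10 choice gives 1000 graphs
per sweep — enough for stable held-out metrics in minutes on one CPU.
Each graph is labeled clusterable iff spectral clustering (k = number of
planted blocks, known during training) recovers the planted partition
with ARI ≥ τ = 0.7; the raw ARI is clipped to [0,1]. Features are the
mean and standard deviation of the local clustering-coefficient
distribution (triangles over wedges, 0 for degree < 2); "std" is used
where a variance parameterization is also accepted. Candidates — logistic
regression, SVM, random forest, k-NN — are fitted on a 75% split and
compared on the held-out 25%; the best-by-F1 model's probability output
is the CDI. No extra calibration layer is added beyond the classifier's
native probability estimate. Retraining at τ = 0.65 or 0.75 moves
held-out accuracy by well under 0.1.

A **CDI-β** variant extends the features (density, degree mean/sd/skew,
global transitivity, degree assortativity, largest-component fraction)
and the model menu (gradient boosting, MLP) for degree-heterogeneous
networks generated by the degree-corrected SBM (edge probability scaled
by endpoint weight products, clipped to [0,1]; unit weights reduce
exactly to the plain SBM).

**Known limitation.** The sweep never produces disconnected perfect
cliques or graphs denser than their block structure implies, so a network
of near-cliques (clustering coefficient ≈ 1, spread ≈ 0) sits in a
feature region the training data populate mostly with unclusterable
near-complete graphs — and scores low despite being trivially
clusterable. In-distribution probes behave correctly (a 0.9/0.05 blocked
graph scores ≈ 0.99, an Erdős–Rényi p = 0.2 graph ≈ 0.4). This is why
the pipeline's CDI gate *warns* rather than aborts by default
(`cdi_hard_gate` turns it into an error), and why the CDI is reported
alongside results rather than silently filtering them.

## 8. Benchmarks from ontology hierarchies

Ground truth comes from is-a hierarchies: a parent term whose direct
children form a known cluster. Two regimes bound the direct-child count
c: 5 ≤ c < 10 and 10 ≤ c < 100 (inclusive below, exclusive above).
"Children" means direct is-a children — the bounds make no sense for
transitive descendants. Candidate pairs of parents must be
*level-matched* (equal shortest-path depth from the chosen root,
minimum over multiple parents, reversed is-a edges) and *parent-unique*
(no shared immediate parent, which would make the two clusters siblings
of a trivial common refinement). Children under both parents have no
unique ground-truth label and are excluded; pairs whose member counts
then leave the regime bounds are dropped. Absolute pair counts on any
real ontology depend on the release and are not reproduced here; the
enumerator is validated against a brute-force constraint check on a
packaged toy hierarchy.

Evaluation uses a repeated random-sampling protocol: 300 independent
trials, 2 categories drawn uniformly per trial, up to 20 members sampled
without replacement per category, agglomerative clustering with k = the
number of drawn categories, ARI/NMI against the category labels,
mean ± sd over trials with the per-trial table retained.

## 9. Summarization

Cluster descriptions are concatenated under a character budget (default
8000, a stand-in for summarizer input limits). Over budget, members are
*condensed, never truncated mid-member*: first each description reduces
to its leading sentence, then the longest contributions halve word-wise
until the join fits, every member keeping at least one word. The
summarizer itself is a port (text in, one sentence out); the offline
fallback extracts the sentence with the highest mean document-level token
frequency, deterministically. Summary quality is scored by encoder
cosine, ROUGE-1 F (clipped unigram counts) and ROUGE-L F (longest common
subsequence), with tokenization fixed bit-exactly (lowercase, split on
non-alphanumerics) because ROUGE values are tokenization-sensitive. The
concatenated source text serves as the reference. Abstractive remote
models are out of scope for the tests; their adapters share the port.

## 10. Synthetic fixtures

`make_fixture()` builds an ontology (root → branch → parent → children;
the branch layer exists so parent pairs are level-matched without sharing
an immediate parent), gene sets with *exact* within/between-parent
overlap fractions (a global core shared by all children, a parent core
shared within a parent, private remainders), and descriptions sampled
from parent vocabularies mixed with a shared vocabulary. Presets:
`clusterable` (both signals), `no_signal`, `graph_only`,
`semantic_only`. Defaults — 2 parents, 10–15 children each, 50 genes per
child, within-overlap 0.8, between-overlap 0, 30-word descriptions over
40-word vocabularies — are sized like the small ontology benchmark groups
the pipeline targets.

What the fixtures do *not* emulate: real term-description prose (the
offline encoder is bag-of-words, so bag-of-words templates are
sufficient and honest), annotation noise, multi-parent children, or
scale-free overlap structure. Passing on fixtures demonstrates the
machinery end to end — signal in, parents out; no signal in, nothing
out — not performance on any real ontology.

## 11. Problem sizes and numerics

The test suite runs fixtures of 20–30 sets, blob fixtures of 50–90
points, 120-node compact CDI sweeps (3 replicates), and one full
1000-graph protocol sweep repeated over three seeds; the acceptance
script repeats only the full sweep. Degenerate inputs are handled
explicitly: empty edge sets are legal networks, zero rows survive
normalization, constant partitions have NMI 0, equivalent partitions
return metric 1 exactly (bypassing floating-point log arithmetic), ties
in k-selection and summarization break deterministically toward the
first/smaller candidate. Consensus pairs never co-sampled are imputed 0
with a logged count rather than silently dropped.
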