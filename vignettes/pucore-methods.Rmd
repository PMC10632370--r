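---
title: "Methods: positive-unlabeled ensemble prediction of core-like genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positive-unlabeled ensemble prediction of core-like genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pucore)
```

## The problem and the model

Core genes are genes whose activity directly and mechanistically influences
a disease phenotype; peripheral genes act indirectly, through regulatory
networks that converge on core genes. Known strong disease genes provide
positive labels, but there are no verified negatives — every other gene is
merely unlabeled, and some unlabeled genes are the very core genes one wants
to find. `pucore` therefore treats the task as positive-unlabeled (PU)
classification on a gene graph, and replaces the usual arbitrary score
cutoff with a statistically selected agreement threshold inside a nested
cross-validation ensemble.

A further complication is the *probabilistic gap*: labeled and unlabeled
positives come from the same underlying distribution, but the probability of
being labeled rises toward the extreme of that distribution (the most
dramatic disease genes are the ones that got discovered). A decision
boundary tuned to recover the labeled extremes is mis-placed for the
ordinary positives. The ensemble's consensus score — how many independent
outer folds select a gene — is designed to be robust to exactly this shift,
and the synthetic-data generator plants this regime explicitly so the
behavior is testable.

## Data model

* `gene_universe` — the ordered gene set; all matrices and graphs are
  aligned to it. The universe is feature-driven: genes missing any feature
  are excluded, and network edges touching excluded genes are dropped.
* `gene_graph` — typed directed edge sets, one per source network.
  Undirected (protein-interaction) networks contribute both directions of
  every pair; directed (gene-regulatory) networks only regulator → target.
  The same gene pair may be connected by several edges of different types.
  Isolated genes stay in the graph; the layers' self-loops convolve them
  with themselves.
* `feature_matrix` — genes × features. Features are scaled robustly:
  `(x − median)/IQR` per column with linear-interpolation quantiles
  (type 7), because gene-level association statistics and expression values
  are heavy-tailed and outlier-laden; zero-IQR columns are centered only.

## Base classifiers

All trainable classifiers share the pre/message-passing/post architecture:
dense layers of width 50 with ELU activations on both sides of a stack of
two graph layers, each graph layer followed by ELU and instance
normalization (per-channel standardization across genes, no learned affine,
ε = 10⁻⁵), with a single sigmoid output unit. The message-passing cores are
GCN, TAG (K = 3 hops), RGCN and FiLM; `mp_kind = "none"` gives the plain
MLP. Two deliberate readings of the layer definitions:

* FiLM aggregates neighbor messages as a plain sum without degree
  normalization, and its inner nonlinearity is the rectifier — both follow
  the layer's defining equation rather than GCN convention; ELU appears
  only between stacked layers. With one relation and the modulation forced
  to γ = 1, β = 0, the layer reduces to an unnormalized adjacency sum (a
  documented reduction test).
* GCN and TAG are edge-type blind, so when they are given a multi-network
  graph the edge sets are merged; parallel typed edges each deliver their
  own message while degrees come from the binary union.

Every edge carries a multiplicative weight (1 by default). Weights scale
messages while degree normalizations stay fixed at the unweighted graph, so
weight 1 reproduces the textbook layer exactly and weight 0 removes the
edge — this is what makes edge attribution well-defined for every
classifier kind.

Non-graph alternatives: random-walk embeddings (unbiased walks, skip-gram
with negative sampling; the walk bias parameters are unstated in the
upstream method descriptions, so unbiased `p = q = 1` walks are used) feed
an MLP over concatenated features ("n2v+mlp"); LINKX trains separate MLPs
on adjacency rows and features joined by a third MLP, with an L1 penalty
(α = 10⁻²) on the first adjacency-branch weight matrix to curb overfitting
of its large first layer.

All forward and backward passes are written out explicitly in R (the
backward pass also yields gradients with respect to inputs and edge
weights, which the interpretation module consumes); each layer is verified
against a dense-matrix brute-force oracle on small random graphs.

## Training

Unlabeled genes are class 0 and training positives class 1 under the loss
`L = Σ_u BCE(0, ŷ_u)/d + a·Σ_p BCE(1, ŷ_p)` with dilution `d = 10` and
amplification `a = 2`: each epoch resamples `|P_train|·d` unlabeled genes
uniformly with replacement (once per epoch, not per batch — the graphs at
package scale fit in memory, so training is full-batch), and false
negatives cost `a` times false positives. Scores are clamped to
`[10⁻⁷, 1 − 10⁻⁷]` when the loss is evaluated so the cross-entropy stays
finite; gradients use the exact logit-space form `(score − label)`.

Optimization is Adam at learning rate 10⁻³, at most 1000 epochs. Because
the early-stopping holdout contains only positives, overfitting is
monitored by combining precision on the training pool with recall on the
holdout. The monitor is the standard F-measure `2·pr·rec/(pr + rec)`; a
printed shorthand of this quantity elsewhere omits the denominator, and the
standard form is used here for interpretability (the two agree as rankings
whenever `pr + rec` is constant). "Improvement" means strict increase; the
best-epoch weights are retained and training stops 100 epochs after the
last improvement. A binary call requires a score strictly above 0.7.

Method selection uses 4-fold cross-validation with 4 repeats (16 models),
each fold holding out 25% of positives and of unlabeled genes, scored by
AUROC with unlabeled treated as negative. One-tenth of the training
positives per model serve as its early-stopping holdout, a harness choice
that keeps the benchmarked training procedure identical to the ensemble's.

## The ensemble and its threshold

Positives are partitioned into `m = 11` outer test sets. Within outer fold
`j`, the remaining positives are partitioned into `n = 10` validation sets;
inner model `i` trains on `positives ∖ test_j ∖ val_{j,i}` (with 110
positives: 90 genes, 82% — while 9% sit in the outer test set and 9% in the
model's validation set). Crucially, the fold's test positives are labeled
class 0 during training (they are "unknown" to the fold), so mistakes on
them register in the loss — the more conservative of the two holdout
designs.

Per-gene concordance `c_j^g` counts inner models calling gene `g`. The
observed statistic at level `c*` is the number of held-out test positives
with concordance exactly `c*`. The null model re-draws each model's calls
uniformly without replacement within the scored universe (unlabeled genes
plus the fold's test positives), preserving each model's call count —
the minimal null matching the models' positive rates. This is repeated
`B = 1000` times; implementation-wise the draw is restricted to the test
positives through the exact hypergeometric identity (the number of test
positives a random classifier hits is hypergeometric, and those hits are a
uniform subset), which a test verifies against the naive full-universe
draw. Each bin is tested one-sidedly with a Student-t statistic of the
observation on the background scale, `t = (observed − mean(C̄))/sd(C̄)`
with `B − 1` degrees of freedom; the background standard deviation (not
the standard error of the background mean, which shrinks with `B` and
would flag any observation at all above the mean) keeps the per-bin
type-I rate nominal when the real models are themselves random — the
calibration property the threshold machinery is designed around. BH-FDR
is applied across the `n` bins. The
chosen threshold is the minimal bin with FDR < 0.05, or the minimal bin
with background mean < 0.1 — whichever is smaller. Two conventions the
upstream definitions leave open: a zero-variance background is significant
only when strictly below the observation (otherwise p = 1), and the
sparse-background branch additionally requires at least one observed test
positive in the bin, so a fold cannot promote candidates on the strength of
an empty bin. A fold that selects no threshold contributes an empty
candidate set rather than aborting.

Candidates of fold `j` are the unlabeled genes with `c_j^g ≥ c*` (bin
counting uses equality, candidate selection uses ≥ — both as defined); all
known positives, including the fold's test positives, are excluded. The
consensus score CS(g) ∈ {0..m} counts selecting folds; CS = 0 genes are
non-candidates, and known positives receive no CS at all.

## Interpretation

Integrated gradients attribute the query gene's score to input coordinates
against a zero baseline, approximated by a midpoint Riemann sum with 64
steps (the technique fixes the path, not the resolution; 64 steps keep the
completeness residual below 10⁻³ on the package's trained test models, and
doubling the resolution moves attributions by less than that). Edge
attributions differentiate the score with respect to the multiplicative
edge weights on the path from 0 (edge absent) to 1 (edge present). Per
model, absolute attributions are minmax-scaled — across the full edge set
for edges, across genes for per-neighbor importance (a gene's feature
attributions are summed into one per-node magnitude; attribution per
node-feature pair would also be defensible, but per-node matches how
neighbor influence is read) — and averaged over all `n·m` models, so values
land in [0, 1] with 1 meaning "top-ranked in every model". The query gene's
own feature attributions keep their sign: |x| is minmax-scaled and the sign
reapplied, landing in [−1, 1] with the least important feature at 0. A
degenerate minmax (zero range) maps to 0.

## Validation statistics

Enrichment uses Fisher's exact test; the reported effect is the sample
(cross-product) odds ratio `(a·d)/(b·c)` with Haldane 0.5 correction when
any cell is empty — closed-form, testable, and what enrichment plots
conventionally show — while the p-value is the two-sided exact conditional
one. Per consensus-score bin `k`, the test set is `CS ≥ k` against
non-positive genes with `CS < k` (cumulative bins; at the top bin the test
set coincides with `CS = m`), BH-corrected across bins. Group comparisons
of constraint scores use Tukey's HSD (studentized-range adjustment,
simultaneous 95% intervals); drug-targeting degrees use pairwise Wilcoxon
rank-sum tests restricted to genes with at least one drug interaction, with
the candidate/non-candidate median ratio reported; validation rates are
compared with pooled two-proportion z-tests; all multiplicity correction is
Benjamini–Hochberg.

## The synthetic-data generator

The generator emulates the full input contract so that every downstream
stage is testable without external downloads. A standard-normal latent
coreness `z` drives everything: informative features are
`effect_size · z + N(0,1)` (noise features pure N(0,1)) — linear-Gaussian,
the simplest structure under which both the classifiers and the enrichment
statistics have analyzable behavior; the top `core_fraction` of genes are
true cores; each core is labeled with probability
`plogis(slope · (z − threshold))`, a logistic realization of the
probabilistic gap chosen because no functional form is prescribed and a
single slope parameter spans uniform labeling (slope 0 labels cores at rate
1/2) to a sharp cut (slope → ∞, capped at 10⁶). Networks are Erdős–Rényi
or preferential-attachment (the latter because real interactome degree
distributions are heavy-tailed); network topology is deliberately
independent of coreness, so feature-driven classifiers carry the recovery
burden and graph layers are exercised structurally. A validation gene set
is drawn with membership odds multiplied by `validation_or` among cores
(non-core base rate 0.1). Everything is deterministic given the seed.

What the generator does not emulate: tissue-specific co-expression
structure, SNP-level association signals, network-coreness correlation, or
inspection bias in curated networks. Passing the recovery tests therefore
shows that the machinery finds planted signal of the stated form at the
stated strength — not that any particular real network modality carries
such signal.

## Problem sizes and defaults

The package defaults mirror the method's canonical settings (m = 11,
n = 10, B = 1000, d = 10, a = 2, threshold 0.7, hidden width 50, two graph
layers, K = 3, embedding dimension 100 / walk length 100 / context 5 / 500
epochs). The test-suite and acceptance runs shrink the *problem*, not the
method: the planted-truth recovery study uses 2000 genes, 5% cores, effect
size 2, labeling slope 3, an MLP base classifier and an m = 5 × n = 5
ensemble with B = 1000 — sizes chosen so a complete run is a desk-scale
computation while every code path (training, thresholding, consensus,
enrichment) is exercised at its real settings. Embedding tests use reduced
dimensions and epochs on purpose-built community graphs where the expected
geometry is known.

## Known limitations

* Training is full-batch and single-threaded; genome-scale graphs
  (≳10⁵ genes, 10⁷ edges) would need mini-batching or sparse-optimized
  backends that are out of scope here.
* The random-walk embedding is a faithful but compact skip-gram
  implementation; at the default 500 epochs on large graphs it is slow, and
  users with big inputs should reduce epochs or precompute embeddings.
* The probabilistic-gap generator plants a one-dimensional latent; real
  disease architectures are multi-factorial, and CS calibration on real
  data should be judged by external validation, not by the synthetic
  recovery numbers.
* LINKX materializes dense adjacency rows (n × n memory).
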