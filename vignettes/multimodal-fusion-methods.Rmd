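---
title: "Multimodal fusion for interaction prediction: models, assumptions, and design choices"
author: "moltriad maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion for interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Predicting whether a drug binds a protein target (DTI), whether a molecule
has a property (DP), whether two drugs interact (DDI), or which relation
types hold between two proteins (PPI) are all binary (or multi-label
binary) prediction problems over biomolecules. A biomolecule carries
information in three complementary modalities:

* **structure** — a 2D molecular graph for a drug, an amino-acid sequence
  for a protein;
* **structured knowledge (SK)** — the biomolecule's position in a
  biomedical knowledge graph of typed (head, relation, tail) triplets;
* **unstructured knowledge (UK)** — a free-text description.

`moltriad` encodes each modality independently, projects and concatenates
the features per task, and predicts with a multilayer perceptron trained
end to end. Its distinguishing machinery addresses the *missing modality
problem*: most task datasets identify biomolecules only by structure, and
many structures have no entry in the knowledge store at all.

# Encoders

**Drug structure.** A graph isomorphism network (GIN). Atom features are
the sum of an atom-type and a chirality embedding (initial width 120).
Each of the 5 layers updates node $v$ as
$x_v \leftarrow \mathrm{MLP}^{(k)}\!\big(x_v + \sum_{u \in N(v)} (x_u +
e_{uv})\big)$, where $e_{uv}$ is the layer's bond-type plus
bond-direction embedding of the bond joining $u$ and $v$, and the MLP is
linear–ReLU–linear. Messages flow along both directions of every bond.
The molecule feature is the mean over node rows of the last layer. Note
the edge embeddings must live at the layer's input width for the sum to
typecheck; the raw bond featurization is the categorical (type,
direction) pair. Mean pooling makes the output invariant to atom
relabeling, which the test suite checks by explicit permutation.

**Protein structure.** A multiscale CNN. Residues are embedded
($m \times d$), three branches apply one, two and three stacked 1-D
convolutions of kernel length 3 (ReLU after each), each branch is
max-pooled over the sequence, and the concatenated branch outputs are
affinely mapped to the fixed 128-d protein feature. Sequences shorter
than the deepest receptive field (7) are right-padded with a dedicated
trainable pad symbol that participates in pooling. The "kernel size 3"
is implemented as a 1-D convolution over the embedding channels — the
only reading consistent with sequence input.

**Structured knowledge.** The knowledge graph is embedded offline:
relation types and directions are dropped, parallel edges collapse, the
adjacency is row-normalized by inverse degree, and a randomized truncated
SVD (two power iterations, deterministic sign convention, seeded probes)
yields $U\sqrt{\Sigma}$ rows. A Chebyshev band-pass polynomial in the
symmetrically normalized adjacency (order 10, $\theta = 0.5$,
$\mu = 0.2$, Bessel-weighted coefficients) then propagates the factors
over the graph. Isolated entities get zero rows but remain *present*:
being in the graph with no edges is different from being absent from the
store. An entity's SK feature is its row of this frozen matrix. By
convention, an edgeless graph short-circuits propagation to the order-0
scaling — there is no structure to propagate — which also pins down the
degenerate case exactly.

**Unstructured knowledge.** A pluggable text backbone maps tokens to
per-token vectors whose position 0 is the `[CLS]` summary; the UK feature
is a dropout-wrapped affine map of that vector. Two backbones ship: a
*toy* backbone (whitespace tokenizer, trainable embeddings, `[CLS]` =
mean of content-token embeddings) that is deterministic and CPU-fast and
is used by the entire test suite, and an adapter contract for any
pretrained transformer exposing 768-d `[CLS]` vectors. For pair tasks the
two descriptions are joined with a `[SEP]` token before encoding, so the
backbone can see cross-molecule co-occurrence. Missing text is encoded as
the empty string: the reconstruction machinery below is scoped to
structured knowledge only, and we kept that scope.

# Missing-modality machinery

The knowledge store is a dictionary keyed by canonical structure:
canonical SMILES for drugs (openbabel canonicalization; any deterministic
canonical form would do, and the choice is recorded here), the uppercased
residue string for proteins. Resolution of a biomolecule:

1. exact-match lookup; on a hit, the SK feature is the entity's embedding
   row (provenance `direct`) and the stored text is used;
2. on a miss — or when training-time *modality masking* fires — the SK
   feature is **reconstructed by top-k sparse attention**: the structure
   feature is affinely projected into KG space and used as the query;
   keys are $W_K H$ over the frozen embedding matrix $H$; values are the
   raw rows of $H$ (the value projection is the identity and is not a
   parameter, so no optimizer step can move it). Per head, only the $k$
   (default 16) largest scores survive; ties at the k-th score keep the
   lowest row index, making runs reproducible. The output per head is a
   convex combination of at most $k$ embedding rows; heads are
   concatenated. With 4 heads the per-head score scaling is
   $\sqrt{d_{\text{head}}}$, the standard multi-head generalization.

Masking discards a direct SK feature with probability $P$ (default 0.05
during training, always 0 at evaluation), independently per biomolecule
per sample, forcing the reconstruction path to train even when few true
misses exist. Masked records keep their text: masking is defined on the
structured-knowledge input only.

# Fusion, prediction, loss

Per task the structure features of the one or two biomolecules are
concatenated and affinely projected with dropout; likewise the SK
features; the UK feature comes from the single or `[SEP]`-joined text.
Pair concatenation is ordered — (A, B) and (B, A) are different inputs —
with an optional order-augmentation left to the caller. The three fused
vectors are concatenated into an MLP with sigmoid outputs, one per label
(1 for DTI/DP-per-task/DDI; one per relation type for PPI), trained with
masked binary cross-entropy (predictions clipped at $\varepsilon =
10^{-7}$; missing labels excluded). Training uses Adam with weight decay
$10^{-6}$, minibatches, a per-epoch validation metric (AUROC, or micro-F1
for PPI), best-epoch checkpointing and early stopping (patience 6 by
default; the stopping rule is ours — none is stated upstream).

**Training stability.** Two mechanisms are always on and one is
optional, all exposed in the configuration:

* the prediction head's output layer is zero-initialized, so training
  starts at exactly p = 0.5 with well-scaled gradients (overconfident
  random logits at initialization otherwise produce violent first-epoch
  updates that can kill the ReLU head);
* global gradient-norm clipping (`clipNorm`, default 1) bounds update
  sizes; without it the structure channels' magnitudes can grow without
  limit over long training runs, eventually saturating the head;
* trainable per-sample layer normalization is available behind flags
  (`ginLayerNorm` for each GIN layer, `mcnnLayerNorm` for the protein
  output; both default off, matching the bare encoder contracts). Layer
  normalization rather than batch normalization is offered so evaluation
  stays a pure per-sample function with no batch statistics.

**Channel-scale calibration.** At initialization the three channels have
wildly different natural scales: message passing amplifies graph features
while spectral KG rows live near the origin (a ~200x spread in entry
standard deviation). Three fixed, initialization-time choices make the
channels commensurate: the frozen KG matrix is scaled once to unit entry
variance; token embeddings are initialized at unit variance (so a mean
over $L$ tokens has scale $1/\sqrt{L}$); and each structure channel is
divided by a constant estimated from one probe forward pass over up to 48
stored biomolecules. These constants are part of the model and never
updated — mathematically a reparameterization of $W_S$/$W_{SK}$, not an
architecture change — but without them the planted signal in the
synthetic corpus is unlearnable in any reasonable budget.

# Evaluation protocols

* **warm** $n$-fold CV: random row partition; one rotating non-test fold
  is validation. `random_811` is the single-split 8:1:1 variant.
* **cold-drug / cold-protein** CV: the *entity* set is partitioned, so a
  fold's test drugs (proteins) never appear in training.
* **cold-cluster**: drugs and proteins are partitioned into 3 groups
  each; the 9 folds are the group products; training rows must avoid both
  of the test cell's groups. Rows sharing exactly one group are
  discarded (they contain test entities), and validation is a seeded 10%
  carve-out of training. Group assignment is random by entity; a
  similarity-based clustering can be plugged in by partitioning upstream.
* **scaffold split** (8:1:1): molecules are grouped by Bemis-Murcko
  framework — here computed by iteratively pruning terminal atoms and
  canonically labeling the remaining colored graph with elements as
  vertex colors and *bond orders ignored* (the carbon-skeleton reading;
  bond-order-sensitive keys are unstable under aromatic kekulization).
  Acyclic molecules share the empty framework. Groups are assigned whole,
  largest first, to train, then valid, then test.
* **BFS/DFS PPI splits**: traverse the protein interaction graph from a
  seeded random root collecting proteins until the rows touching the
  collected set reach the test quota (~20%); those rows are test. When a
  component is exhausted the traversal restarts from a fresh random root,
  so the quota is always reachable; the achieved ratio is reported.

Every `SplitSpec` re-validates its own disjointness guarantee in its
validity method — a violating split cannot be constructed. Before any
evaluation embedding build, every knowledge-graph connection between
test-fold entity pairs is removed (`removeTestLinks`), regardless of
relation type, with the exclusion list recorded in the embedding's
provenance.

Metrics: AUROC (rank statistic, ties one half), AUPR (step integral of
precision over recall across the descending threshold sweep), micro-F1
(all (sample, label) decisions pooled at the threshold). Each is checked
against a brute-force oracle (all-pairs counting; explicit threshold
sweep) in the tests.

# The synthetic corpus

The generator builds a corpus in which every pipeline stage has a
planted, recoverable signal:

* entities belong to one of $B = 4$ communities; the knowledge graph is a
  stochastic block model ($p_{in} = 0.2$ within, $p_{out} = 0.01$
  across) over all 300 entities (200 drugs + 100 proteins) at the
  default scale;
* each entity also carries an independent binary **motif id** expressed
  *only structurally*: drugs contain an O (bit 0) or N (bit 1) marker
  atom, proteins a `FPFP` or `WYWY` 4-mer;
* community membership is mirrored in structure **partially**
  (`structAssoc = 0.7`): a drug's ring backbone comes from its own
  community's template set with probability 0.7, otherwise from another
  community; a protein carries its community 4-mer with probability 0.7.
  Keeping this association partial is deliberate: if structure determined
  community exactly, the knowledge-graph channel would be redundant and
  ablating it would show nothing;
* texts are templated from the ground truth and name both the family and
  the motif bit, so the text channel carries the same signal through a
  different route;
* a fraction `fMiss` of entities is withheld from the store indices —
  their SK and UK are missing at resolution time — uniformly over
  communities (a chi-square p-value is recorded in the corpus
  parameters).

The default pair label is `community_xor_motif`: label 1 iff (same
community) XOR (same motif id). The XOR construction means neither the
KG/text channel (community) nor the structure channel (motif) suffices
alone — ablating either degrades performance measurably. Class balance is
~0.5 by construction ($P(\text{same community}) = 1/4$,
$P(\text{same motif}) = 1/2$). DP uses community parity; PPI stacks
same-family / same-motif / XOR into a 3-type multi-label target.

What the corpus does *not* emulate: realistic chemistry (templated alkyl
decorations, no stereochemistry in practice), realistic protein length or
composition, hub-dominated KG degree distributions, and text that is
anything but a template. A model that learns this corpus demonstrates
that the plumbing, gradients, reconstruction and evaluation machinery
work — not that the architecture will match benchmark numbers on real
data, which additionally require pretrained structure/text backbones.

# Problem sizes and numerical choices

Desk-scale defaults used by examples, tests and the acceptance script:
encoder widths 32 (GIN hidden, CNN embedding/channels, text, UK, fusion),
120-d initial atom embedding and 128-d protein feature as fixed points of
the architecture, `dKg = 32` for the 300-entity synthetic graph
(component default 256 matches the full-scale design), MLP head
(128, 64), learning rate $10^{-2}$, batch 128, at most 30 epochs. At
these sizes one end-to-end DTI training run on the default corpus takes
a couple of minutes on one CPU; the ablation study under 50% missingness
uses 2200 rows and 18 epochs per arm with common seeds across arms
(paired comparison). A caveat the ablation surfaced: with equal short
training budgets, the zero-imputation variant can match or beat
sparse-attention reconstruction on held-out AUROC — the simpler
missing-indicator inputs are learned faster, while the advantage of
reconstruction emerges only near convergence, which longer runs (about
30 epochs at this scale) approach. The directional comparison is
therefore reported as measured, not assumed. Gradients for every module
are hand-derived and are
verified against central finite differences in development; the test
suite verifies the forward paths against naive oracles instead, which is
cheaper and catches the same regressions.

Degenerate inputs are pinned down explicitly: empty graphs refuse to
encode; sequences shorter than 7 residues are pad-extended; an edgeless
graph propagates as a pure scaling; isolated KG entities embed to zero
rows; `NA` labels drop out of the loss; an all-missing label vector is a
contract error; top-k ties keep the lowest row index; SVD signs are fixed
by the largest-magnitude entry of each left singular vector. One caveat
worth knowing: for graphs whose normalized adjacency has *degenerate*
singular values, individual embedding rows are only defined up to an
orthogonal transform within the degenerate eigenspace — basis-independent
statements (Gram matrices, norms over whole eigenspaces) are what the
tests assert.

# Known limitations

* The structure encoders are trained from scratch; no pretrained 2D/3D
  contrastive weights are bundled. The checkpoint loader accepts external
  weight archives with validated names and shapes for full-scale use.
* The toy text backbone is order-invariant within a segment by design;
  it cannot represent word order. The external-backbone adapter is the
  path to a real language model.
* Reconstruction covers structured knowledge only; missing text is an
  empty string, a documented stand-in.
* The homogeneous-graph embedding discards relation types; relation-aware
  embeddings are out of scope.
* Negative sampling for positives-only tables is uniform over
  non-positive pairs; degree-matched sampling is not implemented.
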