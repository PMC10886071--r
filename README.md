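# moltriad

Multimodal fusion of molecular structure, knowledge-graph embeddings, and
text descriptions for drug-discovery prediction tasks, in pure R.

## What it does, and for whom

Computational chemists and bioinformaticians routinely predict
drug–target interactions (DTI), drug properties (DP), drug–drug
interactions (DDI) and protein–protein interaction types (PPI) from
molecular structure alone. Curated resources carry two further modalities
for many biomolecules: a **knowledge graph** of typed relations
(structured knowledge, SK) and **free-text descriptions** (unstructured
knowledge, UK). `moltriad` is an end-to-end framework that fuses all
three:

* drugs are encoded from SMILES with a 5-layer graph isomorphism network
  (GIN) over atom-type/chirality and bond-type/direction embeddings,
  mean-pooled: `z_S^D`;
* proteins are encoded from sequence with a three-branch multiscale CNN
  (kernel length 3; 1, 2 and 3 stacked layers; max-pool; affine to
  128-d): `z_S^P`;
* the knowledge graph `KB = (E, R)` is embedded offline into
  `H ∈ R^{|E| x d}` by randomized truncated SVD of the degree-normalized
  adjacency plus Chebyshev spectral propagation; an entity's SK feature
  is its row of `H`;
* a text backbone yields a `[CLS]` vector mapped by an affine head:
  `z_UK`; pair tasks join the two descriptions with `[SEP]`;
* per task, `z_S = Dropout(W_S (z_S^left ⊕ z_S^right) + b_S)` and
  analogously `z_SK`; then `ŷ = sigmoid(MLP(z_S ⊕ z_SK ⊕ z_UK))` with
  binary cross-entropy, Adam (weight decay 1e-6), and early stopping.

**Missing modality machinery.** Biomolecules are resolved against a
structure-keyed store (canonical SMILES / residue string). On a miss —
or with probability `P = 0.05` during training (*modality masking*) —
the SK feature is **reconstructed by top-k multi-head sparse attention**:
the structure feature is projected as the query against keys `W_K H`,
only the `k = 16` largest scores per head survive a softmax, and the
output is a convex combination of raw `H` rows (the value projection is
frozen to identity). This is the package's core contribution: a
trainable interpolation over the most relevant known entities.

Evaluation utilities implement warm / cold-drug / cold-protein /
cold-cluster cross-validation, Bemis–Murcko scaffold splits (8:1:1),
BFS/DFS protein-graph splits, leakage-aware removal of test-pair edges
before KG embedding, and AUROC / AUPR / micro-F1 with oracle-checked
implementations. A synthetic-corpus generator plants a recoverable
community + motif signal through all three modalities so the whole
pipeline is testable offline.

## Worked example

```r
library(moltriad)

## a synthetic corpus: 200 drugs, 100 proteins, 4 KG communities
corpus <- generateCorpus(nDrugs = 200, nProteins = 100, B = 4,
                         pIn = 0.2, pOut = 0.01, fMiss = 0, seed = 1)
corpus
#> SyntheticCorpus: 200 drugs, 100 proteins, 4 communities

## embed the knowledge graph (offline, frozen during training)
kge <- kgEmbed(storeKb(corpusStore(corpus)), dKg = 32, seed = 4)
kge
#> KgEmbedding: 300 entities x 32 dims
#>   seed: 4  propagation order: 10

## a DTI task whose labels are (same community) XOR (same motif)
tab <- generateTaskDataset(corpus, "DTI", nRows = 3000, seed = 2)
split <- makeInteractionSplit(tab, "random_811", seed = 3)
f <- folds(split)[[1]]

model <- modelInit("DTI", corpusStore(corpus), kge, nLabels = 1,
                   config = modelConfig(seed = 1))
model <- trainModel(model, subsetTaskTable(tab, f$train),
                    subsetTaskTable(tab, f$valid))
evaluateModel(model, subsetTaskTable(tab, f$test))
#> MetricReport: auroc 0.9998 aupr 0.9998 microF1 0.9902
```

The held-out AUROC near 1 says the model recovered both planted factors
— community membership (reachable only through the knowledge-graph and
text channels) and the structural motif bit — and their XOR; predicting
from either factor alone cannot exceed ~0.5 by construction.

Reconstruction for an unseen molecule:

```r
sa <- sparseAttentionParams(dStruct = 32, dKg = 32, nHeads = 4, k = 16)
g  <- parseMolecule("c1ccccc1CCN")
z  <- encodeDrug(g, ginParams(hiddenDim = 32))
rec <- resolveRecord(corpusStore(corpus), kge, sa, canonicalKey(g),
                     "drug", z)
rec
#> MultimodalRecord [drug] entity=<miss> sk=reconstructed text=absent
```

A command-line wrapper over the same workflow
(`make-fixtures`, `split`, `build-kg`, `train`, `evaluate`) ships in
`inst/cli/moltriad-cli.R`, driven by a YAML config.

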