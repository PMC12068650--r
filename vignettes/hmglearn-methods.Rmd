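---
title: "Knowledge-enhanced heterogeneous molecular graph learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-enhanced heterogeneous molecular graph learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the models implemented by `hmglearn`, the
assumptions behind them, the tunable parameters, and the design decisions
taken where the method left genuine freedom. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The three-view heterogeneous molecular graph

A molecule is represented at three granularities built from the same SMILES
string:

* **Molecule view (M).** Heavy atoms and BRICS fragments are nodes; edges
  are chemical bonds (atom–atom), *reaction* edges between fragments that
  were joined at a BRICS breakpoint, and *join* edges linking each atom to
  its fragment — two node types and three edge types. BRICS cleaves single
  acyclic bonds between synthetically meaningful link environments; a
  molecule with no cleavable bond is a single fragment.
* **Element view (EM).** The molecule view is augmented from an elemental
  knowledge graph (KG): one *element* node per distinct chemical symbol
  (AE edges to the matching atoms), one *functional-group* node per KG
  group detected in the molecule (FrFu edges to the bearing fragments),
  and knowledge edges among those nodes — EE, FuFu and EFu. A knowledge
  edge either materializes a direct element–group relation (1 hop) or a
  length-2 KG path, in which case its feature is the intermediate entity's
  attribute vector; paths longer than two hops are never materialized.
  Parallel EE/FuFu/EFu edges (one per shared intermediate) are allowed.
* **Drug view (DM).** A single hub node (DNode) carrying a drug-KG
  embedding, connected to every atom (AD) and every fragment (FrD).

Every chemistry-derived relation is stored as two directed edges, because
the encoder maintains distinct states per direction.

### Functional-group detection

Substructure matching runs through Open Babel, which reports only match
*counts*. A fragment is credited with a functional group when removing the
fragment's atoms strictly reduces the whole-molecule match count. This has
two advantages over matching inside each fragment's induced subgraph: a
group that spans a BRICS cut (an ester is *always* cut at its C–O bond) is
credited to the fragments involved, and severed subgraphs do not generate
spurious matches from the implicit hydrogens that appear at cut sites. The
cost is a rare masking case: if deleting a fragment removes one true match
while creating one artifact match of the same pattern elsewhere, the
count difference can cancel. The curated fixture patterns do not exhibit
this.

### Raw features

Feature tables are package-defined (standard molecular-GNN featurization);
dimensions may differ per type because the encoder projects each type
through its own input map:

| unit | feature | width |
|---|---|---|
| atom | element one-hot (10) ⊕ degree 0–5 ⊕ charge −2..+2 ⊕ aromatic ⊕ hybridization ⊕ ring | 27 |
| fragment | mean of member-atom features ⊕ heavy-atom count | 28 |
| element node | symbol one-hot ⊕ KG attribute vector | 18 |
| functional group | KG attribute vector | 8 |
| DNode | drug-KG embedding | `d_kg` |
| bond | order one-hot ⊕ conjugation ⊕ ring | 6 |
| reaction | BRICS link-environment two-hot (L1..L16) | 16 |
| join | constant | 1 |
| AE/FrFu/AD/FrD | relation one-hot | 4 |
| EE/FuFu | intermediate attribute vector | 8 |
| EFu | attribute vector ⊕ relation one-hot (zeros on the unused half) | 12 |

Nodes additionally carry a positional vector: the eigenvectors of the
atom-bond graph Laplacian for the 8 smallest non-trivial eigenvalues,
sign-fixed (first nonzero entry positive) and zero-padded; fragment and
KG-derived nodes get zeros. Laplacian positional encodings are the
standard graph-transformer choice; note that for molecules with symmetric
spectra the eigenbasis is not unique, so positional vectors are treated as
part of the input (permutation tests permute them together with the
nodes). Hydrogens are implicit throughout.

## The dual message-passing encoder

Initialization projects raw features type-specifically,

$$h_v^0 = \alpha_v A_{\delta(v)} + a_0 + \lambda_v C_0 + c_0, \qquad
  h_{e_{ij}}^0 = \beta_{ij} B_{\delta(e)} + b_0 + h_{v_i}^0,$$

so the two directions of an edge differ exactly by the difference of their
source-node embeddings. Each of the $L$ layers then runs multi-head
attention twice, synchronously (all messages of a layer are computed from
the previous layer's state):

* a node $v_i$ attends over its incoming directed edges $\{e_{pi}\}$;
* a directed edge $e_{ij}$ attends over $\{v_i\} \cup \{e_{pi}\}$ — its
  source node and the edges converging there, which include the reverse
  edge $e_{ji}$.

Queries come from the receiver and keys/values from the senders; before
comparison, every head projection is composed with a type-specific
transform ($q = h\,W_Q^{l,k}\,W_\delta$) so heterogeneous types meet in
one space. Scores are scaled by $\sqrt{d/K}$ (the per-head width). Head
outputs are concatenated and mixed by $W^V$ (nodes) or $W^E$ (edges), and
states update as
$h^l = \mathrm{LeakyReLU}([\,h^{l-1}\,\|\,m^l\,]\,W^l_{\delta})$ with a
type-specific update matrix. An empty sender set (isolated node) yields a
zero message.

Three points were genuinely open and resolved as follows:

* $W_\delta$ is one matrix per type, shared across layers and heads
  (the most parsimonious reading; per-layer copies would multiply
  parameters without changing the contract).
* Edges use their own $\delta(e)$-indexed transform family, separate from
  the node family.
* The per-layer, per-head $W_Q/W_K/W_V$ are shared between the node and
  edge streams; the type transforms already separate the streams.

**Readout.** Self-attention pooling over the union of final node and
directed-edge states: a shared linear+tanh scorer assigns each unit a
score in $(-1,1)$; the top $\lceil r\,(|V|+2|E|)\rceil$ units are kept
(ties broken by score, then by a stable canonical unit key); the graph
embedding is the softmax-weighted sum of the kept units scaled by their
scores. The normalized weights of the kept units (zero for dropped units)
are exported for interpretation, renormalized within each node type.

Defaults: `d = 16`, `K = 4`, `L = 2`, `r = 0.5`, LeakyReLU slope 0.01,
fan-in-scaled uniform initialization. One parameter set serves all three
views; fine-tuning instantiates only the molecule-view types.

## Cross-view contrastive objective

Embeddings pass through a 2-layer projector MLP and are L2-normalized, so
similarity is cosine. For an anchor molecule $i$ in view 1, the positive
is the same molecule in view 2; the denominator sums the anchor's
intra-view negatives (all other rows of view 1) and inter-view negatives
(all non-positive rows of view 2):

$$\mathcal{L}(\mathcal{G}^1,\mathcal{G}^2,i) =
 -\log\frac{e^{\mathrm{sim}(z^1_i, z^2_i)/\tau}}
 {\sum_{j\ne i} e^{\mathrm{sim}(z^1_i, z^1_j)/\tau}
  + \sum_{j\ne i} e^{\mathrm{sim}(z^1_i, z^2_j)/\tau}}.$$

The positive term is **not** part of the denominator: with view sizes $M
\le N$ every anchor faces exactly $N + M - 2$ negative terms ($M-1$
inter-view, $N-1$ intra-view), which the test suite audits over an
$(M,N)$ grid, and the all-identical two-row case at $\tau = 1$ has the
closed form $\log 2$. Because the drug view only covers the trailing
$\lceil 0.3N\rceil$ batch positions, anchors and positives are aligned
from the tail. The symmetric view loss averages both directions over the
$M$ shared anchors, and the total is the sum over the three view
pairings.

A consequence of excluding the positive from the denominator is that the
loss is unbounded below, so aggressive optimization on very small batch
pools can oscillate; the pre-training smoke tests therefore use a
conservative learning rate (Adam, `lr = 1e-3`). $\tau$ defaults to 0.1.
Numerical stability comes from per-anchor max-logit subtraction.

## Drug-aware batch generation

Molecules without drug ids are clustered on 1024-bit radius-2 circular
fingerprints (folded from Open Babel's ECFP4) with a size-constrained
k-means — greedy balanced assignment inside Lloyd iterations, cluster size
$\lceil 0.7N\rceil$, leftovers dropped with a warning. Each cluster is
completed, in ascending cluster order, with the $\lceil 0.3N\rceil - n$
drug molecules nearest to its centroid among those not yet consumed
(recorded in a global used set, so nearest-neighbor complements never
repeat across batches), then with $n$ drug molecules sampled uniformly
from the never-consumed remainder. Random fills are *not* added to the
used set — the generation procedure samples from the complement of the
used set but never updates it at that step — so they may recur across
batches, though never within one. The feature space for clustering and
nearest-neighbor search is unspecified in the method; fingerprints with
Euclidean distance are the package's documented substitute (a centroid
metric is required by k-means).

## Fine-tuning

The projector is discarded. Property prediction applies a 2-layer MLP head
(tanh hidden layer) to the molecule-view embedding; DDI prediction
concatenates the two embeddings in argument order (predictions are
order-sensitive by construction) and uses a head of width $2d$. The
pooling scorer is re-initialized per task; message-passing weights may be
frozen (`freeze_encoder = TRUE`, the default, cheap) or trained. With a
randomly initialized untrained encoder the frozen embeddings carry little
variance (tanh pooling scores near zero shrink the readout), so
learnability smoke tests train the encoder end-to-end; after contrastive
pre-training either mode is sensible. Losses are MSE (regression) and
element-wise sigmoid cross-entropy (binary / multilabel); the optimizer is
Adam, `lr = 1e-2` for heads, 200 epochs by default.

Gradients throughout come from a small reverse-mode differentiation tape
implemented in the package and verified against central finite
differences; the encoder forward pass is additionally verified, end to
end, against an independently coded dense attention implementation on
random graphs (tolerance 1e-5).

## What the synthetic fixtures emulate

* `gen_element_kg()` — a three-level chemical KG: class nodes
  (`Nonmetals`, `ReactiveNonmetal`, `Halogens`), chemical-level nodes (a
  curated 10-element mini periodic table and 11 functional groups with
  literature SMARTS, Acetal's being `O[CH1][OX2H0]`), and property nodes
  (atomic-weight bins, periods). Hierarchy and property triples are
  deterministic chemistry; the seed only draws the unit-norm attribute
  vectors.
* `gen_drug_kg()` — drugs plus genes, compounds, diseases, processes,
  side effects and symptoms with category-typed relations; every entity
  carries a seeded unit-norm embedding standing in for trained KG
  embeddings (`set_drug_embeddings()` accepts a real table).
* `gen_molecule_pool()` — SMILES composed from a template grammar
  (cores × substituents) spanning aromatic rings, halogens, esters,
  amides, nitriles, ethers and sulfonamides, so BRICS cleaves some
  molecules and not others; benzene and methyl acetate are always
  present. A configurable minority fraction (default 0.3) carries drug
  ids at random positions — the sparsity that motivates the batch
  generator.

These fixtures exercise every code path at desk scale. They do not
emulate the scale or chemistry of real pre-training corpora: pools repeat
templates (so batches can contain duplicate molecules), drug embeddings
are random rather than trained, and the element KG is a small curated
stand-in. Passing tests therefore demonstrate correctness of the
machinery and the qualitative behavior of the objective (loss decreases;
cross-view alignment emerges), not chemical transferability.

## Problem sizes and numerical choices

The test suite and the acceptance script run, per invocation: view-type
inventories over five representative molecules; batch audits on a
100-molecule pool (N = 10, n = 1); encoder-oracle equivalence on 20
random graphs of at most 8 nodes (d = 8, K = 2, L = 2); the contrastive
closed forms and the (M, N) accounting grid up to 8; pre-training smoke
runs of 50 steps on 24-molecule pools across seeds (d = 8, K = 2, L = 1);
one 200-step alignment run on a 30-molecule pool (d = 16); and a
20-molecule nitrogen-count regression fine-tuned for 200 epochs. These
sizes were chosen so the whole suite completes comfortably on one CPU
while still exercising multi-batch training dynamics.

Degenerate inputs are contracts, not crashes: an empty view contributes
zero loss with a warning; a single positive with no negatives
(M = N = 1) is an error; isolated nodes receive zero messages; molecules
whose elements are missing from the KG warn and skip those elements.

## Known limitations

* Stereochemistry, tautomers and 3D conformers are out of scope; the
  heavy-atom graph is the object of study.
* Aromaticity is taken from the SMILES tokens (Open Babel's SDF output is
  kekulized); fully kekulized input SMILES are handled as non-aromatic
  alternating rings, which the isomorphism tests treat via type/degree
  multisets rather than feature equality.
* The SAGPool top-k selection is treated as constant during
  backpropagation (the standard choice); gradients are exact conditional
  on the selection.
* Training at realistic scale (hundreds of thousands of molecules, wide
  encoders) is outside the package's intended envelope — the tape is
  dense R linear algebra, adequate for desk-scale study of the method.
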