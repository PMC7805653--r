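---
title: "Hierarchical decompositions, shift-aggregate-extract networks and lossless domain compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical decompositions, shift-aggregate-extract networks and lossless domain compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saen)
```

## The representation: H-decompositions

`saen` classifies whole graphs by first re-describing each graph (or a whole
collection of graphs) as a hierarchy of typed parts. An H-decomposition has
levels $S_0, \dots, S_L$ of objects; every compound object $s \in S_l$
($l \ge 1$) is made of parts $s' \in S_{l-1}$, each with a membership type
$\pi$ from a finite, ordered per-level alphabet $\Pi_l$ with
$n(l) = |\Pi_l|$ (and $n(0) = 1$ by convention, since nothing enters the
bottom level). The typed incidences are stored as sparse count matrices
$R_{l,\pi} \in \mathbb{N}^{|S_l| \times |S_{l-1}|}$; bottom objects carry a
dense attribute matrix $X \in \mathbb{R}^{|S_0| \times p}$.

Two standard decompositions are provided:

* **EGD** (`buildEGD`, `decomposeCollection(method = "egd")`). Level 0 is
  the vertex set with its attributes; level 1 holds every ego graph
  $g_{v,r}$ (all vertices within shortest-path distance $r$ of root $v$)
  for $r = 0..R$, whose parts are its member vertices with type `ROOT`
  (the root) or `ELEM`; the top level is the whole graph, with the radius
  $r$ as the type of each ego graph. Ego graphs never cross connected
  components.
* **NEGD** (`buildNEGD`, `decomposeCollection(method = "negd")`). Level 1
  holds the radius-1 ego graphs, typed by their vertex count; their parts
  are the ego graphs of their members, typed `ROOT` or by the symbol of the
  connecting edge. Bottom objects are *identified* by the Weisfeiler-Lehman
  color of their root after `wlIterations` refinement rounds (default 4),
  and the bottom attributes are one-hot encodings of these identifiers.

Object ids and alphabets are fixed in first-encounter order at build time,
so every matrix layout is reproducible bit for bit for a given input order.

### Design choices in NEGD

Three points are genuinely open in the definition and resolved as follows.

* *Identifier criterion.* Exact isomorphism canonization of the bottom-level
  ego graphs is replaced by Weisfeiler-Lehman colors: two ego graphs are
  "the same object" iff their roots share a color after the configured
  refinement rounds. Colors are assigned by an injective dictionary keyed on
  (own color, sorted neighbor-color multiset), in first-encounter order; for
  a collection the dictionary is built on the disjoint union, so identifiers
  are comparable across graphs, and the returned dictionary can be passed
  back in to color held-out graphs consistently.
* *Sharing.* A bottom ego graph appearing in several parents is registered
  once per distinct identifier (maximal sharing). A consequence worth
  noting: when two members of an ego graph share an identifier *and* an edge
  symbol, the incidence carries an integer count $> 1$ — exactly the
  cardinality semantics that domain compression uses, so the count dtype is
  shared between both mechanisms. EGD incidences are always 0/1.
* *Open size alphabet.* The type of a level-1 object is its vertex count,
  which is unbounded. The alphabet is fixed to the sizes observed when the
  (training) collection is decomposed, in sorted order; a held-out graph
  with an unseen size raises an error unless `nearestSize = TRUE`, which
  maps it to the closest declared size (ties toward the smaller). Failing
  loudly is the default because silent bucket drift would change the shift
  layout. Identifiers unseen at training time get all-zero one-hot rows.

## The computation: shift, aggregate, extract

Per level, each object's input is assembled from its parts' representations:
the part representation $h_{l-1}(s')$ is *shifted* into the block of its
type by a Kronecker product with the type's indicator vector (norms are
preserved; different type blocks are orthogonal), the shifted vectors are
*aggregated* by summation, and a per-level feedforward stack *extracts* the
object's representation. In matrix form,

$$A_l = R_l \, \mathcal{H}_{l-1}, \qquad H_l = f_l(A_l;\theta_l)
\;\text{row-wise},$$

with $R_l = [R_{l,1}, \dots, R_{l,n(l)}]$ the concatenation in alphabet
order (`assembleLevelMatrix`) and $\mathcal{H}_{l-1}$ the block-diagonal
replication of $H_{l-1}$, $n(l)$ times (`blockDiagRepresentations`). The
implementation multiplies per type ($\sum_\pi R_{l,\pi} H_{l-1}$ into
column blocks), which is the same computation without materializing the
block-diagonal; the equality of the two routes and of the loop-form double
sum is property-tested.

One index convention is worth making explicit: $d(l)$ denotes the *output*
width of the level-$l$ extractor, so the level-$l$ input width is
$n(l)\,d(l-1)$ for $l \ge 1$ and $p$ for $l = 0$, and the top output width
is the class count. This is the only reading under which the matrix shapes
above compose.

Dropping the extraction step yields the explicit feature map of the
corresponding part-based kernel (`kernelFeatures`): attribute vectors are
shifted and summed up the hierarchy unchanged, so the width multiplies by
$n(l)$ per level — $p \prod_l n(l)$ at the top. The function guards this
exponential blow-up with a configurable width cap and exists mainly as an
independent oracle: the forward pass with identity extractors (square
identity weights, zero biases, activation slope 1) must reproduce it
exactly, and does so in the test suite.

### Model and training parameters

| parameter | meaning | default |
|---|---|---|
| `dims` | representation widths $d(0..L-1)$ | `c(8, 8)` in the CV driver |
| `hidden` | hidden-layer widths per level (a "5-3" configuration is `c(5L, 3L)`) | none (one linear layer per level) |
| `leakySlope` | negative slope of the leaky rectifier, applied to all hidden and output units | 0.01 (the conventional value; the slope is not prescribed by the architecture) |
| `activateTop` | activation on the final class scores | `FALSE`: raw scores feed the cross-entropy head directly, with internal softmax normalization and no extra output layer |
| `l2` | coefficient of the $\lambda \sum \lVert W \rVert^2$ penalty (weights only) | `1e-4` in the CV driver |
| `learningRate`, Adam moments | full-batch Adam | `1e-3` in `saenTrain` (0.9/0.999, eps `1e-8`); the CV driver uses 0.05, appropriate for the small compressed structures it trains on |
| `epochs` | full-batch updates | 60 in the CV driver |

Training is full batch: after merging and compression a whole training
split is a single small structure, so one Adam step per epoch is cheap and
the trajectory is bit-reproducible for a fixed seed on one thread.
Mini-batching would only complicate the compression story (symmetries are
collapsed across the whole split). Initialization is Gaussian with the
He scale $\sqrt{2/\text{fan-in}}$ and zero biases. All arithmetic is in
64-bit floats, which keeps the compression-equivalence checks at
`1e-6` relative tolerance comfortable. A non-finite loss aborts with the
epoch index rather than continuing silently.

## Domain compression

Objects that provably share their representation *for every parameter
value* can be merged without changing any output: bottom objects with
identical attribute rows, and compound objects with identical typed part
multisets after their parts were merged. `computeCD` groups identical
matrix rows in first-occurrence order and returns the boolean
decompression matrix $D$ (one 1 per row) together with a left
pseudo-inverse $C$: either the *averaging* form ($D^\top$ with rows divided
by their sums) or the sparser *representer* form (a single 1 per row, at
the first member of each class). The representer form is the default
because it keeps the matrices maximally sparse; the averaging form is used
by the worked-example tests and is equally lossless.

`domainCompress` runs the bottom-up pass: compress $X$; then, per level,
column-compress every $R_{l,\pi}$ by $D_{l-1}$ (merging fan-in and
accumulating integer cardinalities), group identical rows of the
concatenation over the *full* alphabet in its fixed order (types with no
incidences contribute zero columns), and left-multiply by $C_l$. Row
grouping hashes exact integer cardinality vectors, so it only applies to
categorical (integer-coded) attributes; real-valued attributes are rejected
— approximate, tolerance-based collapse would not be lossless and is out of
scope. Compressed cardinalities are provably integral (rows within a class
are identical); the averaging variant's floating-point noise is rounded
away at 9 decimals. `H_l = D_l H_l^{comp}` recovers the original
representations, and `verifyLossless` checks the equality level by level
for a random model.

Training on a compressed hierarchy decompresses only the top-level scores
(`decompression = D_L`), so every original top object contributes its own
label to the loss and gradients flow back through $D_L^\top$; identical
graphs collapsed at the top are thereby weighted by their multiplicity,
exactly as in uncompressed training.

### Worked fixtures

`workedExampleFixture` ships two small instances used as exact oracles.
The four-object instance has attribute rows
$[0,3],[0,3],[4,1],[0,3]$ and pins down $X^{comp}$, $D$, the averaging $C$
(first row: three entries of $1/3$) and the representer $C'$. The
four-level instance (levels A-D, types blue/red) compresses to two objects
per level below a single top object, with the two red arcs from the top
merging into one arc of cardinality 2. Two conventions: (i) the two
fixtures deliberately disagree about which bottom object carries the odd
attribute — each encodes its own narrated variant, and they are not
reconciled; (ii) the wiring of the middle object C2 is not narrated and is
fixed here as the *type-swapped* mirror of C1 (red to B2, blue to B4).
The swap matters: wiring C2 to B2/B4 with the *same* types as C1 would make
C2's column-compressed row identical to C1's after the level-B collapse,
and C2 would merge with C1/C3 — the type-swapped wiring is the minimal
choice that realizes the narrated outcome (only C1 and C3 collapse).

## Data handling and the synthetic generator

The reader/writer pair supports the usual multi-file benchmark layout
(`*_A.txt` edge list with 1-based global ids, `*_graph_indicator.txt`,
`*_graph_labels.txt`, optional node labels/attributes and edge labels).
Parsing is whitespace-tolerant; an edge listed in both directions is stored
once; class labels are recoded to 0..C-1 in sorted order with the original
values recorded; vertex labels are one-hot encoded over the collection-wide
alphabet so columns line up across graphs. No downloader is included:
datasets load from a local directory only.

`generateTwoClassCollection` emulates the two regimes such benchmarks
cover, at desk scale. The `uniform` degree model wires Erdős–Rényi graphs
with $2n$ edges (molecule-like, bounded degrees); `skewed` uses
preferential attachment, whose maximum degree grows with size like the
heavy-tailed social-network collections (the generator's summary statistic
of record is the average maximum node degree, `datasetStats`). The planted
class signal is a vertex-label contrast by default — class-1 graphs flip
$\lfloor \text{strength} \cdot n/2 \rceil$ vertices to a second label — so
the classes are separable already from radius-1 ego neighborhoods;
a triangle-closing structural variant is available, and strength 0 makes
the classes exchangeable by construction. Edge symbols come from a
two-letter alphabet (by endpoint parity), so the same collections exercise
NEGD. What the generator does *not* emulate: attribute noise, class
imbalance, size heterogeneity, or label signals that require deep (radius
> 1) context — so passing tests demonstrate the correctness of the
machinery and the protocol, not performance on real benchmark chemistry or
social data.

## The cross-validation protocol

`runCV` runs repeated stratified k-fold cross-validation (10×10 by
default; stratification keeps class counts balanced per fold, and repeat
$r$ derives its fold assignment from `seed + r`). Per fold, the training
split is decomposed, merged into one hierarchy (so compression collapses
symmetries *across* graphs), compressed and trained; held-out graphs are
decomposed with the training-time alphabets and evaluated uncompressed —
losslessness guarantees identical predictions either way, and nothing from
a held-out graph ever reaches the training structure or parameters (an
isolation test perturbs a held-out graph and asserts bitwise-identical
trained weights). A repetition's accuracy pools the fold predictions,
which equals averaging fold accuracies for equal fold sizes; mean and
standard deviation are over repetitions. Ties in the class scores resolve
toward the lower class index.

For the no-signal control the package implements the permutation-test
null, `runCV(permuteLabels = TRUE)`: every repetition freshly permutes the
labels before fold assignment, training and scoring. A single global
shuffle is deliberately *not* used as the null: its measured accuracy is
dominated by the residual label-feature association of that one draw (the
cross-count between classes and the planted feature deviates
hypergeometrically from balance), compounded by the known below-chance
bias of cross-validation on exactly balanced permuted labels — one draw
can sit several points above or below 0.5 under identical conditions.
Averaging over fresh permutations estimates the chance level itself, which
is what a null check is for.

## Problem sizes and numerical conventions

The test suite exercises: the two worked fixtures exactly; losslessness on
100 random hierarchies (2-4 levels, up to 50 objects per level, 1-3 types
per level, categorical attributes) under both pseudo-inverses at `1e-6`
relative tolerance; the matrix/loop/kernel equivalences at `1e-12`;
analytic-vs-numerical gradients at `1e-5` relative; and the full protocol
on 100 generated graphs of 10 vertices (10×10-fold, 60 epochs), where the
planted-signal mean accuracy must reach 0.9 and the permutation null must
sit within 3 standard deviations of 0.5. These sizes are the package's
reference conditions for the generator and protocol; they run comfortably
on one CPU core.

Conventions worth restating in one place: object, alphabet and class
orderings are first-encounter and fixed at construction; relation entries
are integer counts (0/1 before compression for EGD; NEGD sharing and
compression both use counts); serialization containers are versioned JSON
(coordinate triplets for relations) with strict parsing; prediction
tie-breaks go to the lower class index.

## Limitations

* Node-level prediction is out of scope: representations flow bottom-up to
  the top objects only.
* Compression requires categorical bottom attributes; with real-valued
  attributes the pipeline runs uncompressed.
* The explicit kernel feature map is exponential in depth and guarded by a
  cap; it is an oracle, not a scalable code path.
* Only strict level-to-next-level hierarchies are supported (no
  level-skipping relations); the 4-level edge-based decomposition sometimes
  drawn for illustration can be expressed through `buildHDecomposition`,
  but no dedicated builder is provided because it is not used by the
  experimental decomposers.
* No GPU or multi-machine execution; no hyperparameter search.
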