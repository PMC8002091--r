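---
title: "Inverse molecular design with the two-layered model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse molecular design with the two-layered model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moldesign)
```

## The model

A hydrogen-suppressed chemical graph is a simple connected graph $G = (H,
\alpha, \beta)$ whose vertices carry element labels $\alpha(v)$ and whose
edges carry bond multiplicities $\beta(e) \in [1,3]$, subject to the valence
condition $\beta_G(v) \le \mathrm{val}(\alpha(v))$ at every vertex.  The
difference $\mathrm{val}(\alpha(v)) - \beta_G(v)$, the *hydro-degree*, is the
implicit hydrogen count.  Every element has one fixed valence in $[1,4]$;
the default table is C:4, N:3, O:2, S:2, Cl:1 (divalent sulfur; species that
need other valences, and charged species, are outside the model and are
skipped when a file is loaded).  Vertex ids are 1-based throughout, the
native indexing of the language.

For a branch-parameter $\rho \ge 0$ the graph splits into two layers.
Repeatedly deleting all degree-1 vertices assigns each removed vertex the
round number as its height $\mathrm{ht}(v)$; vertices that survive forever
(cycle cores, path centers) are treated as infinitely high.  Vertices with
$\mathrm{ht}(v) < \rho$ form the *exterior*; edges touching them are
exterior edges and decompose into *$\rho$-fringe-trees*, each rooted at its
unique highest vertex, which is an interior vertex.  Every interior vertex
roots exactly one fringe tree, possibly the trivial single-vertex tree, so
fringe-tree counts add up to the interior size — an identity the test suite
asserts.  The recommended and default branch-parameter is $\rho = 2$:
height-2 fringe trees behave like functional groups while the interior
retains the scaffold topology.

## Descriptors

The feature vector of a graph relative to a data set $D$ has
$K = 17 + |\Lambda^{\mathrm{int}}| + |\Lambda^{\mathrm{ex}}| +
|\Gamma^{\mathrm{int}}| + |\mathcal{F}|$ coordinates: the vertex count, the
interior vertex count, the mean of $\lfloor 10\,\mathrm{mass}\rfloor$ over
atoms, interior vertices by degree (1–4) in $G$ and in the interior
subgraph, vertices by hydro-degree (0–3), interior edges of multiplicity 2
and 3, then one frequency slot per interior element, exterior element,
interior edge-configuration, and fringe-tree class observed in $D$.  An
edge-configuration is the oriented triple of endpoint *chemical symbols*
(element plus degree, e.g. `C3`) and the bond multiplicity.  Fringe trees
are counted up to root-preserving isomorphism; the canonical code is a
recursive minimal string — each node emits `(<element><bond-to-parent>`
followed by its children's codes in lexicographic order — which makes codes
both comparable and parseable back into trees.  Any deterministic canonical
form would do; this one is simple, testable against a brute-force
permutation search, and doubles as the serialization format for candidate
fringe sets.

Set encodings are deterministic: elements in element-table order (ascending
lexicographic symbol order — only used to orient tuples, so any fixed order
is correct, but it must be stable across serialization), edge-configurations
by symbol rank, fringe codes lexicographically.  An element counts as
"exterior" only if it labels an exterior vertex somewhere in the data set.
The mean-mass slot is the one non-integer descriptor; it is stored as a
real number (integer masses divided by $n$ in floating point).

## Target specifications

A target specification $(G_C, \sigma_{\mathrm{int}}, \sigma_{\mathrm{ce}})$
prescribes the admissible graphs.  The seed graph's edges carry one of four
expansion classes (`ge2`, `ge1`, `e01`, `eq1`); a subdivision replaces each
`ge2` edge by a path of length at least 2, each `ge1` edge by a path of
length at least 1, keeps or drops each `e01` edge and keeps each `eq1` edge.
Leaf paths may hang from seed vertices or internal path vertices.  The
interior specification bounds path lengths, leaf-path counts and lengths,
interior size, and per-edge multi-bond counts; the chemical specification
bounds total size, restricts elements, chemical symbols, adjacency- and
edge-configurations, and lists the candidate fringe trees per seed vertex
($F(v)$) and for all other interior vertices ($F_E$).  Side constraints —
arbitrary linear inequalities over the path lengths — are supported because
published instance families use them (e.g. $\ell(a_1) \le \ell(a_2)$ to
break the symmetry of a monocyclic seed).

Two readings in the bound system were genuinely open and are fixed here as
follows.  The per-seed-vertex clause bounding "the number of leaf paths" is
a 0/1 indicator (`v_bl`), distinct from the per-vertex length bounds
(`v_ch`); this mirrors the per-edge `bl`/`ch` split.  And a lower bound on
the *maximum* leaf-path length on an edge is enforced only when at least
one leaf path is attached; the unconditional reading would make it
unsatisfiable exactly when the count bounds allow zero paths.

Validation inverts the three reduction steps (remove fringe trees, remove
leaf paths, contract pure paths) by backtracking: candidate images for seed
vertices are filtered by allowed elements and fringe sets, seed edges are
matched to internally disjoint interior paths, and the leftover vertices
must decompose into admissible leaf paths.  The generation side never needs
this search; validation exists here because every solver result is
re-verified from scratch rather than trusted.  Two
construction-side subtleties matter for correctness: an interior vertex of
interior degree 1 must root a fringe tree of height exactly $\rho$ (else
the decomposition would strip it into the exterior), and among parallel
seed edges at most one may be realized with length 1 (else the result would
not be a simple graph).  Both rules appear identically in the sampler, the
enumerator and the MILP.

## The regressor

Stages 2–3 train a fully connected ReLU network $(K, p_1[, p_2], 1)$ with
Adam on the mean squared error; $R^2$ is computed from its defining formula
rather than any library variant, and five-fold cross-validation partitions
the data reproducibly under a fold seed.  Inputs are min–max scaled during
optimization, but the affine scaling is folded into the first-layer weights
before the model is stored, so the serialized network — plain-text JSON with
full-precision weights plus the descriptor-space definition — consumes raw
integer descriptors.  That choice keeps the inversion MILP linear with no
scaling constants and makes the model file self-contained.  Before
inversion, input nodes for edge-configurations and fringe classes outside
the specification are removed together with their weight columns; on any
specification-conforming graph those descriptors are zero, so the reduced
network provably computes the same output.

## The inversion MILP

The mixed-integer program simulates, in one constraint system, (i) the
construction of a specification-conforming interior, (ii) the descriptor
counting, and (iii) the network forward pass:

* each subdividable seed edge owns up to $\ell_{UB}-1$ internal vertex
  slots activated in prefix order, so every potential interior edge has a
  linear activity expression; leaf-path slots work the same way;
* each vertex slot carries assignment binaries for its element, its
  chemical symbol, and its fringe code (restricted to $F(v)$ or $F_E$);
  each edge slot carries multiplicity binaries and directed
  edge-configuration binaries tied to the endpoint symbols by partial-sum
  constraints;
* descriptors are linear sums of those binaries.  The one nonlinear
  descriptor, mean mass, is linearized exactly by a one-hot choice of the
  vertex count $n$ with per-value big-M constants wide enough to cover the
  full attainable range of (total mass)/$n$ — constants taken from the
  element-mass extremes so the pair of inequalities is vacuous for
  non-selected values and exact for the selected one;
* ReLU units use the standard big-M encoding with per-neuron pre-activation
  bounds propagated by interval arithmetic from the descriptor boxes;
  provably-off and provably-linear units are specialized away.  The
  network output is constrained to $[y^* - \varepsilon, y^* + \varepsilon]$
  with $\varepsilon$ about $10^{-5}$ by default: the output is continuous,
  so a tiny band behaves like equality while keeping the solver's own
  tolerances out of trouble.

Dropping `e01` edges must not disconnect the seed; disconnecting subsets
are enumerated up front (the class is tiny) and excluded.  Feasible points
decode to chemical graphs by reading the active slots; the decoder's output
is never trusted: `verify_inference()` recomputes the decomposition, the
feature vector and the forward pass from the graph alone and validates the
specification.  Solving uses the HiGHS branch-and-bound behind
`scipy.optimize.milp`, reached through the `python` interpreter on the
path; instances are serialized to JSON and several instances can share one
interpreter call.  The formulation is this package's own; variable and
constraint counts of any MILP encoding are formulation-specific and not
comparable across implementations, but the size contract — variables linear
in $n^*$ at fixed interior size — is asserted empirically in the tests.

## Isomer counting and enumeration

Stage 5 asks for other graphs with exactly the feature vector of the
inferred $G^\dagger$.  The interior skeleton is kept fixed; choice sites
are interior element labels, interior bond multiplicities, and the
fringe-code assignment (interior rewirings are out of scope).  Enumeration
backtracks over those sites pruned by the reference multisets, filters by
exact feature-vector equality and specification validity, deduplicates by a
canonical certificate (BLISS canonical labeling of a colored graph in which
each bond is subdivided by a multiplicity-colored vertex), and emits in
certificate order, capped at 100 by default.  The count lower bound
multiplies, over classes of interchangeable sites (same element, interior
degree, interior bond sum, candidate set, and same fringe root degree and
root bond sum), the number of distinct code arrangements, then divides by
the automorphism count of the labeled interior: the two-layer split is an
isomorphism invariant, so any isomorphism between two assignments restricts
to an interior automorphism, and each isomorphism class meets at most
$|\mathrm{Aut}|$ assignments.  The bound is therefore valid and usually
conservative.

## Synthetic data

The generator emulates what the descriptor layer sees in small organic
molecules: a connected interior skeleton of 4–10 vertices with cycle rank
0–2 over {C, N, O}, valence-respecting element and bond assignment (about
20% of interior edges raised above single), and fringe trees of height at
most 2 drawn from a pool of 8 random candidates plus the trivial and
path-shaped ones; every skeleton vertex of degree at most 1 receives a
height-exactly-2 fringe so the decomposition provably recovers the skeleton.
Property values follow a fixed linear form over descriptor slots
(coefficients on $n$, interior size, mean mass, double-bond count and
interior oxygen count; intercept 20) with Gaussian noise of standard
deviation 0.1 — noiseless variants are used where exact recovery is the
point.  Being linear in descriptors, the ground truth is representable by
the regressor, which is what an end-to-end train-and-invert round trip
needs; real activity data is of course not linear in these descriptors, so
passing round trips demonstrate the machinery, not chemical accuracy.  The
generator does not emulate aromaticity conventions, stereochemistry,
charged species, or the size distribution of public databases.

## Problem sizes and numerical choices

The shipped tests run the pipeline at deliberately small scale: toy
specifications with $n^* \le 15$ and interiors of at most 6 vertices for
inversion round trips, extension sets up to a few thousand graphs for the
brute-force completeness check, isomer instances of at most 12 heavy atoms,
1000-graph batches for decomposition and descriptor invariants, and the
full sweep of all valence-valid labeled rooted trees on up to 6 vertices
(about $3.2 \times 10^5$ trees) for the canonical-code proof.  These sizes
make every oracle exhaustive while each suite finishes in minutes.
Degenerate inputs are handled explicitly: a graph entirely below height
$\rho$ raises a structured empty-interior condition rather than returning a
silent empty decomposition (downstream descriptors assume a nonempty
interior, and the data filters drop such tiny molecules anyway); $R^2$ on a
constant response is an error, not a number.  Ties in canonical forms are
broken by radix string order everywhere, which keeps serialized artifacts
platform-independent.

## Limitations

The valence table is a modeling choice (S could be 2 or 6; only one value
per element is representable) and is user-overridable.  Validation solves a
subgraph-homeomorphism-type problem by backtracking and is intended for
interiors of moderate size, not for screening large libraries.  The isomer
module does not explore alternative interior topologies.  Solver
performance depends on HiGHS; published running times obtained with
commercial solvers are not comparable.  Aromaticity perception,
stereochemistry, isotopes and explicit hydrogens are out of scope.
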