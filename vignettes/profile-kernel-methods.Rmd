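---
title: "The profile kernel in profkernel: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The profile kernel in profkernel: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profkernel)
```

## The model

`profkernel` implements the profile string kernel for protein
classification. Each protein is represented not by its sequence but by a
*profile*: an $L \times 20$ matrix of non-negative substitution scores
derived from an alignment of related proteins, one row per position, one
column per amino acid (fixed alphabetical order `A,C,D,...,Y`). A low
score means the amino acid is compatible with the conservation pattern
at that position.

For a k-mer $a = a_1 \ldots a_k$ and a window starting at position $i$,
the cumulative substitution score is
$s(a, i) = \sum_{d=1}^{k} P[i+d-1, a_d]$. The k-mer is *conserved* in
that window when $s(a, i) \le \sigma$ for a user-set threshold
$\sigma$. The feature map
$$\Phi(p) \in \mathbb{N}^{20^k}, \qquad
  \Phi(p)_j = \#\{\, i : s(a^{(j)}, i) \le \sigma \,\}$$
counts, for every one of the $20^k$ possible k-mers $a^{(j)}$, the
windows of $p$ in which it is conserved, and the kernel is the dot
product $K(p, q) = \Phi(p) \cdot \Phi(q)$ — the number of conserved
k-mer pairs the two profiles share. Because all quantities are counts,
the unnormalized Gram matrix is exact integer arithmetic; every
equality in the test suite on kernel values is therefore *exact*, not
approximate.

A note on the tie rule: a k-mer with cumulative score exactly equal to
$\sigma$ counts as conserved (`<=`, not `<`). The boundary case is
exercised explicitly in the tests.

## Conserved k-mer enumeration: the trie

Enumerating conserved k-mers profile-window by profile-window would
rescore every candidate from scratch. Instead all profiles are
traversed together through the 20-ary trie of depth $k$ whose leaves
are the $20^k$ k-mers. Every (profile, window) pair starts at the root
with score 0; descending an edge labelled $a$ extends every surviving
candidate by one letter and adds the corresponding position's score for
$a$. Candidates whose running score exceeds $\sigma$ are dropped.
Scores are non-negative, so a prefix score never decreases with depth —
a pruned candidate can never pass the threshold at a leaf below, which
makes the pruning sound (and is asserted on random instances in the
tests).

Two contracts matter downstream and are fixed here:

* **Leaf order.** Children are visited in alphabet order, so leaves
  fire in strictly increasing leaf index (base-20 encoding of the
  k-mer, first letter most significant). All floating-point
  accumulations downstream inherit this fixed order, which is what
  makes model files byte-reproducible across reruns.
* **Vectorized candidate handling.** The score extension and the
  $\sigma$ comparison at a node are whole-vector operations over the
  node's candidate arrays, never per-candidate interpreted steps.

`brute_force_feature_vector()` is the package's independent oracle: it
enumerates all $20^k$ k-mers and scores each against each window
directly, with no trie and no pruning. Trie/oracle equality on random
profiles across $(k, \sigma)$ regimes is the package's most important
invariant.

A third routine supports prediction: when a traversal is given a
*descent restriction* (a subset of profiles, in practice the queries),
any subtree in which no restricted candidate survives is skipped
entirely. Counts at visited leaves are unchanged — the restriction
saves work, never alters results — and the tests compare restricted
against full traversals to assert exactly that.

## Gram-matrix construction: the sparse count buffer

At each leaf the naive algorithm updates $K[i, j]$ for every pair of
profiles present — quadratic work per leaf, one tiny update at a time.
`profkernel` instead stages per-leaf counts as coordinate-list triplets
(profile row, leaf column, count) in a buffer. When the next leaf's
triplets would overflow the capacity, the buffered sparse matrix $C$ is
multiplied with itself once, $K \mathrel{+}= C C^\top$, which is
arithmetically identical to all the per-leaf pairwise updates it
replaces. Two details are deliberate:

* **Per-leaf atomicity.** One leaf's triplets never straddle a flush:
  splitting a column across two self-multiplications would lose its
  cross terms. The capacity is therefore a soft bound — a single leaf
  with more triplets than the capacity is flushed as one oversized
  batch. Kernel results are invariant to the capacity (tested for
  capacities 1, 7, 1000 and unbounded).
* **Exactness guard.** Counts accumulate in doubles, which are exact
  integers below $2^{53}$ — far beyond the $20^k L^2$ scale reachable
  at supported sizes. The bound is checked, not silently wrapped.

### Split computation

For training sets whose Gram matrix is too expensive for one process,
`plan_jobs()` splits the $m$ profiles into $n$ contiguous groups of
near-equal size (first $m \bmod n$ groups get one extra) and emits one
job per unordered group pair. Each job sees only its two groups'
profiles, computes its rectangular block with the same trie/buffer
machinery, and the blocks reassemble to the monolithic matrix *exactly*
(integer arithmetic again). Group assignment is contiguous by input
order rather than hashed so that assembly is pure index arithmetic and
block files are reproducible. The file-level workflow
(`run_blocks()` / `run_assemble()`) parallelizes over jobs with forked
worker processes; the trie traversal inside a job stays single-process.
Results are byte-identical for 1, 2 or 4 workers.

## SVM training and the normal matrix

Multi-class classification uses one-vs-rest: one binary C-SVM per
class, trained on the precomputed Gram matrix by `kernlab::ksvm()`. The
SVM solver is standard machinery, not this package's contribution; the
package's part is what happens before (the kernel) and after (making
the discriminant explicit). Each fitted binary SVM is repackaged as a
`dual_svm`: support ids, weights $\alpha_i y_i$, and bias, oriented so
that the positive class has the larger mean decision value (the
underlying solver's internal label coding is not documented, so the
orientation is established empirically per fit — a deterministic
procedure).

Because the profile kernel lives in an explicit feature space, the
primal normal vector of each SVM can be materialized:
$$w = \sum_i \alpha_i y_i \, \Phi(x_i), \qquad
  \text{score}(q) = w \cdot \Phi(q) + b .$$
`extract_normals()` builds the normal vectors of *all* SVMs in a single
trie traversal over the union of support profiles: at each leaf the
surviving support counts are multiplied into every SVM's weight vector
at once, producing one row of the *normal matrix* (rows = populated
leaves, columns = SVMs). Only rows with at least one nonzero entry are
stored; the $20^k$-dense representation is exactly what makes naive
normal matrices enormous at $k \ge 5$. An all-zero column (weights that
cancel on every leaf) is rejected rather than stored.

Scoring is the reverse single traversal: all queries descend the trie
together, their per-leaf counts are buffered, and each flush multiplies
the sparse count matrix against the matching rows of the normal matrix,
updating the whole query-by-SVM score matrix at once. The baseline
predictor `score_queries_baseline()` — the dual expansion
$\sum_i \alpha_i y_i K(x_i, q) + b$ over a supports-versus-queries
restricted traversal — is kept as a reference implementation; the
dual/primal identity between the two paths is the package's central
correctness criterion and holds to $\sim 10^{-15}$ relative (the test
bound is $10^{-9}$).

### Normalized kernels

Cosine normalization ($\hat K_{ij} = K_{ij}/\sqrt{K_{ii} K_{jj}}$) is
off by default — raw shared-count values are the kernel's native output
— but supported end to end because downstream SVMs often expect it.
The package keeps a single convention: dual weights are mapped back to
the *raw* feature space at training time
($\alpha_i y_i / \sqrt{K_{ii}}$), and query scores are divided by the
query's raw feature norm, which is accumulated in the same traversal
that scores it. This keeps extraction and both scoring paths identical
in structure for raw and normalized models. Profiles with no conserved
k-mers make normalization undefined and are reported by id rather than
silently guarded.

## Numerical and degenerate-input choices

* Exact tie $s = \sigma$ is conserved; tested at the boundary.
* Profiles shorter than $k$: an error naming the profile id in
  training-side operations; in batch scoring, such queries are skipped
  with a warning and the rest of the batch proceeds (a genome-scale
  batch should not die on one fragment). An error is raised only when
  no query can be scored.
* Exact score ties between classes at prediction time are broken by
  class-name order and flagged in the `tie` column.
* Model files store doubles with 17 significant digits
  (`%.17g`), which round-trips IEEE doubles exactly; `load_model()`
  restores every field bit-for-bit.
* Text prediction output rounds scores to 6 decimals; returned R
  objects keep full precision.
* Floating-point accumulation order is fixed (leaf-index order)
  everywhere, so reruns of `run_create()` produce byte-identical model
  archives. Score matrices are invariant to buffer capacity up to
  float-summation reordering only (below $10^{-12}$ relative; the
  integer-valued kernel is invariant exactly).

## The synthetic generator

No real profile resource (PSI-BLAST, HHblits, PredictProtein) ships
with the package, and generating such profiles is out of its scope.
Instead `generate_synthetic_profiles()` emulates their *shape*: per
position one uniformly drawn "true" residue gets a score uniform on
$[0, 1]$ and the other 19 get $1 + 9c + \mathrm{U}(0, 3)$ where
$c \in (0, 1]$ is the conservation parameter. Larger $c$ widens the gap
between the true residue and alternatives, so conserved-k-mer
neighborhoods shrink — the property the tests assert. The bands were
chosen once so that thresholds scaled to desk-size $k \le 3$ (the
production regime uses $k = 5\ldots6$ with proportionally larger
$\sigma$) give non-degenerate neighborhoods: $\sigma \approx 1.5$
admits essentially only the true k-mer, $\sigma \approx 6$ admits
single substitutions at moderate conservation, $\sigma \approx 12$
admits broad neighborhoods.

`generate_labeled_profiles()` builds a classification task by
implanting one strongly conserved class-specific motif (default length
8; true-residue scores $\mathrm{U}(0, 0.5)$, mismatches
$10 + \mathrm{U}(0, 2)$) at a random position of each member profile.
Members of a class therefore share the motif's exact k-mers while
between-class overlap is limited to chance background collisions
(expected well below one shared 3-mer per profile pair at the default
lengths). The end-to-end task used in the tests and the acceptance
script — 3 classes, 20 profiles each, lengths 40–60, background
conservation 0.9, $k = 3$, $\sigma = 5$, raw kernel, cost 1 — is
deliberately well separated: it checks that the pipeline's plumbing
(kernel → SVM → normal matrix → scoring → ranking) preserves an
easily learnable signal, not that the kernel solves hard remote
homology.

What the generator does **not** emulate: position-position
correlations, alignment-depth-dependent score calibration, indel
structure, compositional bias, and realistic class overlap. Passing
tests on synthetic data therefore demonstrate algorithmic correctness
and pipeline fidelity, not expected accuracy on real remote-homology
or localization tasks.

## Problem sizes

The default test and acceptance runs use desk-scale inputs chosen to
exercise every code path while keeping the whole suite fast: up to 100
profiles of length $\le 60$ for trie/oracle equivalence at
$k \in \{1,2,3\}$, 30 profiles for split/assemble, 20 queries by 4 SVMs
for the dual/primal identity, and 60 labeled profiles end to end. The
engine itself has no hard-coded size limits other than $k \le 14$
(leaf indices must stay exact in a double) and the $2^{53}$ count
guard.

## Known limitations

* Single-machine, in-memory matrices; the split workflow distributes
  CPU work but assembly materializes the full matrix.
* One $(k, \sigma)$ per traversal; evaluating several parameter
  combinations in one pass over the trie is a known possible
  optimization that this implementation does not attempt.
* One-vs-rest with raw score ranking; no probability calibration. The
  optional `softmax_scores()` is a monotone rescaling, clearly labelled
  non-calibrated.
* Sequence input is supported only via degenerate one-hot profiles;
  non-standard residues are rejected rather than remapped.
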