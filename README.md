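# profkernel

Fast profile string kernel for multi-class protein classification in R.

## The problem

Assigning proteins to classes — families, structural relatives,
subcellular localizations — is one of the most common tasks in
computational biology, and profile-based SVM kernels remain among the
most accurate tools for it. The profile kernel represents each protein
by a position-specific scoring profile (an L×20 matrix of substitution
scores over the 20 amino acids; lower = more conserved) and compares
two proteins by counting the k-mers they both conserve:

- a k-mer *a* is **conserved** in a window starting at position *i* of
  profile *P* when its cumulative score
  `s(a, i) = Σ_d P[i+d−1, a_d]` is ≤ a threshold **σ**;
- the feature map **Φ(p)** counts, for each of the 20^k possible
  k-mers, the windows of *p* in which it is conserved;
- the kernel is `K(p, q) = Φ(p)·Φ(q)` — an exact integer.

Computed naively this is far too slow for modern dataset sizes.
`profkernel` implements the engine that makes it practical:

- **k-mer trie traversal** with cumulative-score pruning enumerates all
  conserved k-mers of all profiles in one depth-first pass;
- **sparse count buffering** replaces per-leaf pairwise kernel updates
  with one coordinate-list self-multiplication per flush;
- **split computation**: the Gram matrix is partitioned into group-pair
  sub-matrices computed by independent (parallel) processes and
  reassembled exactly;
- **explicit normal vectors**: for trained SVMs the primal discriminant
  `w = Σ_i α_i y_i Φ(x_i)` is materialized for *all* SVMs in a single
  traversal (the *normal matrix*), so scoring a query is a sparse dot
  product `s = w·Φ(q) + b` instead of kernel evaluations against every
  support vector;
- **batch scoring**: many queries × many SVMs in one traversal;
- a **baseline support-vector predictor** kept as an internal oracle,
  and a **single-call workflow** (`create` / `apply`) that turns labeled
  profiles into a ready-to-use multi-class one-vs-rest classifier.

A synthetic profile generator (background conservation model plus
implanted class motifs) provides self-contained, seed-reproducible test
data; no external profile resource is required.

## Worked example

```r
library(profkernel)

# a 3-class synthetic task: 20 profiles per class, one conserved motif
# per class implanted in a noisy conservation background
task <- generate_labeled_profiles(n_per_class = 20, n_classes = 3, seed = 42)
ids  <- profile_ids(task$profiles)
by_class <- split(seq_along(ids), task$labels[ids])
tr    <- unlist(lapply(by_class, function(v) v[1:14]))
train <- task$profiles[tr]
test  <- task$profiles[-tr]

# Gram matrix of shared conserved 3-mer counts (exact integers)
K <- compute_kernel_matrix(train, k = 3, sigma = 5)
K[1:4, 1:4]
#>              class01_p001 class01_p002 class01_p003 class01_p004
#> class01_p001           40            8            6            7
#> class01_p002            8           38            6            7
#> class01_p003            6            6           42            7
#> class01_p004            7            7            7           60
```

The diagonal counts each profile's conserved k-mer pairs with itself
(driven by profile length and conservation); within-class off-diagonal
values are lifted by the ~6 shared motif 3-mers plus background
collisions.

```r
dir <- tempfile("model")
run_create(train, task$labels[profile_ids(train)], dir, k = 3, sigma = 5)
ap <- run_apply(dir, test)
head(ap$predictions, 4)
#>       query_id predicted_class  score second_class margin   tie
#> 1 class01_p015         class01 0.6041      class03  1.395 FALSE
#> 2 class01_p016         class01 0.5710      class02  1.327 FALSE
#> 3 class01_p017         class01 0.6025      class02  1.383 FALSE
#> 4 class01_p018         class01 0.5990      class02  1.367 FALSE
mean(ap$predictions$predicted_class == task$labels[ap$predictions$query_id])
#> [1] 1
```

Each row ranks the one-vs-rest SVM scores: `score` is the winning
class's raw margin and `margin` its lead over the runner-up. Since the
feature space is explicit, trained models also expose their evidence:

```r
fv <- feature_vector(train[[1]], 3, 5)
fv
#> <kmer_features> k = 3 sigma = 5 | 40 nonzero leaves, total count 40
leaf_to_kmer(fv$leaf[order(-fv$count)][1:3], 3)
#> [1] "ALE" "ALM" "ATH"
```

## Command line

A thin CLI over the same functions is installed at
`exec/profkernel` inside the package:

```sh
profkernel=$(Rscript -e 'cat(system.file("exec/profkernel", package = "profkernel"))')
Rscript $profkernel generate --out prof.txt --labels lab.tsv --seed 4
Rscript $profkernel create   --profiles prof.txt --labels lab.tsv \
                             --model mdl --kmer 3 --sigma 5
Rscript $profkernel apply    --model mdl --profiles prof.txt --out pred.tsv
Rscript $profkernel kernel   --profiles prof.txt --out K.tsv --kmer 3 --sigma 5
Rscript $profkernel blocks   --profiles prof.txt --out blocks/ --groups 3 --processes 3 --kmer 3 --sigma 5
Rscript $profkernel assemble --blocks blocks/ --out K2.tsv   # identical to K.tsv
```

## File formats

- **Profiles**: text records `>ID L` followed by `L` lines of 20
  whitespace-separated scores (columns in `A,C,D,...,Y` order); `#`
  lines are comments. FASTA sequences can be used via degenerate
  one-hot profiles (`read_fasta_profiles()`).
- **Labels**: two-column TSV `id<TAB>class`, no header.
- **Model folder**: `params.json`, sparse `normals.tsv.gz`,
  `biases.tsv`, `training_ids.txt`, `manifest.json`; doubles stored at
  17 significant digits so `load_model()` is bit-exact.
- **Kernel / block / prediction outputs**: TSV with id headers.

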