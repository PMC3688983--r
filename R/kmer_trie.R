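#' Leaf index of a k-mer string
#'
#' Leaves of the depth-k trie are numbered 0 .. 20^k - 1 by base-20
#' encoding of the k-mer over [AMINO_ACIDS], first letter most
#' significant. Returned as a double so indices stay exact for any
#' practical k (20^k < 2^53 for k <= 14).
#'
#' @param kmer Character vector of k-mer strings (equal lengths).
#' @return Double vector of 0-based leaf indices.
#' @export
kmer_to_leaf <- function(kmer) {
  k <- unique(nchar(kmer))
  if (length(k) != 1L) stop("k-mers must have equal length", call. = FALSE)
  letters <- matrix(match(unlist(strsplit(kmer, "")), AMINO_ACIDS),
                    ncol = k, byrow = TRUE)
  if (anyNA(letters)) stop("non-standard residue in k-mer", call. = FALSE)
  as.vector((letters - 1) %*% 20^((k - 1):0))
}

#' k-mer string of a leaf index
#'
#' Inverse of [kmer_to_leaf()].
#'
#' @param leaf Double/integer vector of 0-based leaf indices.
#' @param k k-mer length.
#' @return Character vector of k-mer strings.
#' @export
leaf_to_kmer <- function(leaf, k) {
  if (any(leaf < 0) || any(leaf >= 20^k))
    stop("leaf index out of range for k = ", k, call. = FALSE)
  out <- character(length(leaf))
  for (i in seq_along(leaf)) {
    digits <- (leaf[i] %/% 20^((k - 1):0)) %% 20
    out[i] <- paste(AMINO_ACIDS[digits + 1], collapse = "")
  }
  out
}

check_trie_params <- function(k, sigma) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("k must be a positive integer", call. = FALSE)
  if (k > 14)
    stop("k must be <= 14 (leaf indices must stay exact in a double)",
         call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("sigma must be a finite non-negative number", call. = FALSE)
  invisible(NULL)
}

#' Depth-first conserved k-mer trie traversal
#'
#' The engine under all kernel, normal-extraction and scoring
#' operations. Conceptually every (profile, window) pair starts as a
#' candidate at the trie root with cumulative score 0; descending one
#' letter extends every surviving candidate's prefix and adds that
#' profile position's substitution score for the letter; candidates
#' whose cumulative score exceeds `sigma` are pruned (a k-mer is
#' conserved iff its total score is `<= sigma` -- ties count as
#' conserved). Score extension and the sigma comparison are whole-array
#' operations over a node's candidate vector, never per-candidate
#' interpreted steps. Because scores are non-negative, a pruned prefix
#' can never reappear below, which makes pruning sound.
#'
#' `on_leaf` is invoked exactly once for every leaf with at least one
#' surviving candidate, in strictly increasing leaf-index order, with
#' arguments `(leaf, profile_indices, counts)`: the 0-based leaf index,
#' the 1-based indices of profiles with survivors, and the number of
#' surviving windows per such profile.
#'
#' With `restrict_descent_to`, subtrees in which no candidate from the
#' given profile-index subset survives are skipped entirely (their
#' callbacks never fire). This is the baseline-predictor pruning rule:
#' at every visited leaf the counts of the restricted profiles are
#' unchanged, only work on irrelevant subtrees is saved.
#'
#' @param profiles List of `"profile"` objects, all of length >= k.
#' @param k k-mer length.
#' @param sigma Substitution score threshold (>= 0).
#' @param on_leaf Callback `function(leaf, profile_indices, counts)`.
#' @param restrict_descent_to Optional integer vector of profile indices.
#' @return Invisibly, the number of leaves visited.
#' @export
trie_traverse <- function(profiles, k, sigma, on_leaf,
                          restrict_descent_to = NULL) {
  check_trie_params(k, sigma)
  check_profile_set(profiles)
  n <- length(profiles)
  if (n == 0L) return(invisible(0))
  lens <- vapply(profiles, profile_length, integer(1))
  if (any(lens < k)) {
    bad <- profile_ids(profiles)[lens < k]
    stop("profile(s) shorter than k = ", k, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  restrict <- NULL
  if (!is.null(restrict_descent_to)) {
    restrict <- logical(n)
    restrict[as.integer(restrict_descent_to)] <- TRUE
  }

  S <- do.call(rbind, lapply(profiles, function(p) p$scores))
  scol <- lapply(seq_len(20L), function(a) S[, a])  # column-wise lookup
  offs <- cumsum(c(0L, lens[-n]))
  nwin <- lens - k + 1L
  prof0 <- rep.int(seq_len(n), nwin)
  row0 <- unlist(lapply(seq_len(n),
                        function(p) offs[p] + seq_len(nwin[p])),
                 use.names = FALSE)
  pow <- 20^((k - 1):0)
  nleaf <- 0L

  descend <- function(depth, leaf_base, prof, rows, score) {
    d1 <- depth + 1L
    for (a in 1:20) {
      s2 <- score + scol[[a]][rows + depth]
      keep <- s2 <= sigma
      if (!any(keep)) next
      pk <- prof[keep]
      if (!is.null(restrict) && !any(restrict[pk])) next
      leaf <- leaf_base + (a - 1) * pow[d1]
      if (d1 == k) {
        tb <- tabulate(pk, nbins = n)
        nz <- which(tb > 0L)
        nleaf <<- nleaf + 1L
        on_leaf(leaf, nz, tb[nz])
      } else {
        descend(d1, leaf, pk, rows[keep], s2[keep])
      }
    }
  }
  descend(0L, 0, prof0, row0, numeric(length(prof0)))
  invisible(nleaf)
}

collector <- function() {
  e <- new.env(parent = emptyenv())
  e$items <- vector("list", 64L)
  e$n <- 0L
  e
}

collect <- function(e, x) {
  n <- e$n + 1L
  if (n > length(e$items)) e$items <- c(e$items, vector("list", length(e$items)))
  e$items[[n]] <- x
  e$n <- n
}

collected <- function(e) e$items[seq_len(e$n)]

#' Conserved k-mer feature vector of a profile
#'
#' Maps a profile into the 20^k-dimensional feature space: entry j
#' counts the windows of the profile in which the k-mer of leaf j is
#' conserved (cumulative substitution score <= sigma). Computed by a
#' single trie traversal; only nonzero entries are returned.
#'
#' @inheritParams trie_traverse
#' @param profile A single `"profile"` object.
#' @return Object of class `"kmer_features"`: list with `leaf` (sorted
#'   0-based leaf indices, double), `count` (positive integer counts),
#'   `k`, `sigma`.
#' @export
feature_vector <- function(profile, k, sigma) {
  acc <- collector()
  trie_traverse(list(profile), k, sigma, function(leaf, idx, cnt) {
    collect(acc, c(leaf, cnt))
  })
  m <- collected(acc)
  leaf <- vapply(m, `[`, numeric(1), 1L)
  count <- as.integer(vapply(m, `[`, numeric(1), 2L))
  structure(list(leaf = leaf, count = count, k = k, sigma = sigma),
            class = "kmer_features")
}

#' @export
print.kmer_features <- function(x, ...) {
  cat("<kmer_features> k =", x$k, "sigma =", x$sigma, "|",
      length(x$leaf), "nonzero leaves, total count", sum(x$count), "\n")
  invisible(x)
}

#' Brute-force conserved k-mer counts (test oracle)
#'
#' Definitionally correct counterpart of [feature_vector()]: enumerates
#' all 20^k k-mers, scores each against every window of the profile
#' directly, and counts those with cumulative score <= sigma. No trie,
#' no pruning -- intended as an independent oracle at small k.
#'
#' @inheritParams feature_vector
#' @return Same structure as [feature_vector()].
#' @export
brute_force_feature_vector <- function(profile, k, sigma) {
  check_trie_params(k, sigma)
  if (20^k > 1e7)
    stop("k too large for brute-force enumeration", call. = FALSE)
  L <- profile_length(profile)
  if (L < k)
    stop("profile(s) shorter than k = ", k, ": ", profile$id, call. = FALSE)
  m <- as.integer(20^k)
  # letter of k-mer j at position d (1-based), leaf-index order
  letter <- lapply(seq_len(k), function(d)
    ((seq_len(m) - 1L) %/% 20^(k - d)) %% 20 + 1L)
  counts <- integer(m)
  P <- profile$scores
  for (pos in seq_len(L - k + 1L)) {
    sc <- numeric(m)
    for (d in seq_len(k)) sc <- sc + P[pos + d - 1L, ][letter[[d]]]
    counts <- counts + (sc <= sigma)
  }
  nz <- which(counts > 0L)
  structure(list(leaf = as.numeric(nz - 1L), count = counts[nz],
                 k = k, sigma = sigma),
            class = "kmer_features")
}

#' Dense expansion of a sparse feature vector
#'
#' @param fv A `"kmer_features"` object.
#' @return Numeric vector of length 20^k.
#' @export
dense_features <- function(fv) {
  v <- numeric(20^fv$k)
  v[fv$leaf + 1] <- fv$count
  v
}
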