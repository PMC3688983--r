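# Kernel counts are accumulated in doubles; integers are exact below
# 2^53, far beyond the 20^k * L^2 scale reachable at supported sizes,
# and the bound is enforced rather than silently wrapped.
.COUNT_LIMIT <- 2^53

#' Create a sparse coordinate-list count buffer
#'
#' During trie traversal, per-leaf conserved k-mer counts are staged as
#' (row = profile, column = leaf, value = count) triplets instead of
#' updating the kernel matrix at every leaf. When the buffer fills, one
#' sparse self-multiplication adds the buffered contribution to the
#' Gram matrix in a single operation ([flush_buffer()]).
#'
#' The capacity is a soft bound with per-leaf atomicity: all triplets of
#' one leaf always land in the same flush (splitting a leaf's column
#' across two self-multiplications would lose its cross terms), so a
#' single leaf with more triplets than the capacity is flushed as one
#' oversized batch. Results are independent of the capacity.
#'
#' @param capacity Maximum number of buffered triplets before a flush
#'   (>= 1; may be `Inf`).
#' @return An environment of class `"count_buffer"` with fields `i`
#'   (profile rows), `leaf` (leaf indices), `x` (counts), `capacity`.
#' @export
new_count_buffer <- function(capacity = 1e6) {
  if (!is.numeric(capacity) || length(capacity) != 1L || capacity < 1)
    stop("capacity must be >= 1", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$i <- integer(0)
  e$leaf <- numeric(0)
  e$x <- numeric(0)
  e$capacity <- capacity
  class(e) <- "count_buffer"
  e
}

buffer_size <- function(buffer) length(buffer$x)

buffer_add <- function(buffer, rows, leaf, counts) {
  buffer$i <- c(buffer$i, rows)
  buffer$leaf <- c(buffer$leaf, rep.int(leaf, length(rows)))
  buffer$x <- c(buffer$x, as.numeric(counts))
  invisible(buffer)
}

#' Create a kernel accumulator
#'
#' Mutable accumulator for the (block of the) Gram matrix that
#' [flush_buffer()] adds into. `rows_a`/`rows_b` select which profile
#' indices form the block's rows and columns; for the full symmetric
#' matrix both are all profiles.
#'
#' @param rows_a,rows_b Integer vectors of profile indices (rows /
#'   columns of the accumulated block).
#' @return Environment of class `"kernel_accumulator"` with field `K`.
#' @export
new_kernel_accumulator <- function(rows_a, rows_b = rows_a) {
  e <- new.env(parent = emptyenv())
  e$rows_a <- as.integer(rows_a)
  e$rows_b <- as.integer(rows_b)
  e$K <- matrix(0, length(rows_a), length(rows_b))
  class(e) <- "kernel_accumulator"
  e
}

#' Flush a count buffer into a kernel accumulator
#'
#' Adds the buffered contribution to the accumulated Gram block by
#' sparse self-multiplication: with C the buffered counts matrix (rows
#' = profiles, columns = the buffered leaves), the update is
#' `K += C[rows_a, ] %*% t(C[rows_b, ])`. Arithmetically identical to
#' the per-leaf pairwise count update, but performed as one sparse
#' matrix product. The buffer is emptied.
#'
#' @param buffer A `"count_buffer"`.
#' @param accumulator A `"kernel_accumulator"`.
#' @return Invisibly, the accumulator.
#' @export
flush_buffer <- function(buffer, accumulator) {
  if (buffer_size(buffer) == 0L) return(invisible(accumulator))
  cols <- match(buffer$leaf, unique(buffer$leaf))
  C <- Matrix::sparseMatrix(i = buffer$i, j = cols, x = buffer$x,
                            dims = c(max(c(accumulator$rows_a,
                                           accumulator$rows_b)),
                                     max(cols)))
  A <- C[accumulator$rows_a, , drop = FALSE]
  if (identical(accumulator$rows_a, accumulator$rows_b)) {
    accumulator$K <- accumulator$K + as.matrix(Matrix::tcrossprod(A))
  } else {
    B <- C[accumulator$rows_b, , drop = FALSE]
    accumulator$K <- accumulator$K + as.matrix(Matrix::tcrossprod(A, B))
  }
  buffer$i <- integer(0)
  buffer$leaf <- numeric(0)
  buffer$x <- numeric(0)
  invisible(accumulator)
}

# shared traversal + buffering core for full and block computation
accumulate_kernel <- function(profiles, k, sigma, buffer_capacity,
                              rows_a, rows_b) {
  acc <- new_kernel_accumulator(rows_a, rows_b)
  buf <- new_count_buffer(buffer_capacity)
  trie_traverse(profiles, k, sigma, function(leaf, idx, cnt) {
    if (buffer_size(buf) > 0L &&
        buffer_size(buf) + length(idx) > buf$capacity)
      flush_buffer(buf, acc)
    buffer_add(buf, idx, leaf, cnt)
  })
  flush_buffer(buf, acc)
  if (any(acc$K >= .COUNT_LIMIT))
    stop("kernel counts exceed exact integer range (2^53); ",
         "reduce k, sigma or profile lengths", call. = FALSE)
  acc$K
}

#' Compute the profile-kernel Gram matrix
#'
#' `K[i, j]` is the dot product of the conserved k-mer feature vectors
#' of profiles i and j, i.e. the number of conserved k-mer pairs the two
#' profiles share, summed over all 20^k leaves. Computed in one trie
#' traversal with the sparse count buffer ([new_count_buffer()]); the
#' result is independent of the buffer capacity.
#'
#' Unnormalized values are exact non-negative integers. With
#' `normalize = TRUE` the cosine normalization
#' `K[i,j] / sqrt(K[i,i] * K[j,j])` is applied; profiles without any
#' conserved k-mer (zero diagonal) make that undefined and raise an
#' error naming the offending ids.
#'
#' @inheritParams trie_traverse
#' @param buffer_capacity Triplet capacity of the count buffer.
#' @param normalize Apply cosine normalization (default off: raw shared
#'   conserved k-mer counts).
#' @return n x n numeric matrix with profile ids as dimnames and
#'   attributes `k`, `sigma`, `normalized`.
#' @export
compute_kernel_matrix <- function(profiles, k, sigma,
                                  buffer_capacity = 1e6,
                                  normalize = FALSE) {
  ids <- check_profile_set(profiles)
  if (length(profiles) < 1L) stop("need at least one profile", call. = FALSE)
  n <- length(profiles)
  K <- accumulate_kernel(profiles, k, sigma, buffer_capacity,
                         seq_len(n), seq_len(n))
  dimnames(K) <- list(ids, ids)
  if (normalize) K <- normalize_kernel(K)
  attr(K, "k") <- k
  attr(K, "sigma") <- sigma
  attr(K, "normalized") <- normalize
  K
}

#' Cosine-normalize a raw kernel matrix
#'
#' @param K Square kernel matrix of raw counts.
#' @return `K[i,j] / sqrt(K[i,i] K[j,j])`; errors if any diagonal entry
#'   is zero.
#' @export
normalize_kernel <- function(K) {
  d <- diag(K)
  if (any(d == 0)) {
    bad <- rownames(K)[d == 0]
    if (is.null(bad)) bad <- which(d == 0)
    stop("cannot normalize: profile(s) with no conserved k-mers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Kn <- K / sqrt(outer(d, d))
  attributes(Kn)[c("k", "sigma")] <- attributes(K)[c("k", "sigma")]
  attr(Kn, "normalized") <- TRUE
  Kn
}

#' Plan block-wise kernel computation
#'
#' Splits m profiles into `n_groups` contiguous groups of near-equal
#' size (first `m %% n_groups` groups get the extra profile) and emits
#' one job per unordered group pair (a <= b):
#' `n_groups * (n_groups + 1) / 2` jobs that together cover every
#' profile pair exactly once. Deterministic.
#'
#' @param m Number of profiles.
#' @param n_groups Number of groups, `1 <= n_groups <= m`.
#' @return List of `"submatrix_job"` objects with fields `a`, `b`
#'   (group numbers), `rows_a`, `rows_b` (profile index ranges), `m`,
#'   `n_groups`.
#' @export
plan_jobs <- function(m, n_groups) {
  if (n_groups < 1 || n_groups > m)
    stop("n_groups must be in [1, m]", call. = FALSE)
  base <- m %/% n_groups
  extra <- m %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_groups] + 1L)
  jobs <- list()
  for (a in seq_len(n_groups)) {
    for (b in a:n_groups) {
      jobs[[length(jobs) + 1L]] <- structure(
        list(a = a, b = b,
             rows_a = starts[a]:ends[a], rows_b = starts[b]:ends[b],
             m = as.integer(m), n_groups = as.integer(n_groups)),
        class = "submatrix_job")
    }
  }
  jobs
}

#' @export
print.submatrix_job <- function(x, ...) {
  cat(sprintf("<submatrix_job> groups (%d, %d) of %d; rows %d..%d x %d..%d\n",
              x$a, x$b, x$n_groups, min(x$rows_a), max(x$rows_a),
              min(x$rows_b), max(x$rows_b)))
  invisible(x)
}

#' Compute one kernel sub-matrix block
#'
#' Runs the trie traversal over only the profiles of the job's two
#' groups and returns the rectangular block of feature-space dot
#' products `K[rows_a, rows_b]`. Off-diagonal jobs compute only
#' cross-group dot products; a diagonal job (`a == b`) returns the full
#' symmetric within-group block. Each job is self-contained (no shared
#' state), so jobs can run in independent processes.
#'
#' @param profiles Full ordered profile list the plan was made for.
#' @param job A `"submatrix_job"` from [plan_jobs()].
#' @inheritParams compute_kernel_matrix
#' @return Object of class `"kernel_block"`: list with `job`, `block`
#'   (matrix with id dimnames), `ids_a`, `ids_b`.
#' @export
compute_sub_matrix <- function(profiles, job, k, sigma,
                               buffer_capacity = 1e6) {
  if (!inherits(job, "submatrix_job"))
    stop("job must come from plan_jobs()", call. = FALSE)
  if (job$m != length(profiles))
    stop("job was planned for ", job$m, " profiles, got ",
         length(profiles), call. = FALSE)
  ids <- profile_ids(profiles)
  if (job$a == job$b) {
    sub <- profiles[job$rows_a]
    blk <- accumulate_kernel(sub, k, sigma, buffer_capacity,
                             seq_along(sub), seq_along(sub))
  } else {
    sub <- profiles[c(job$rows_a, job$rows_b)]
    na <- length(job$rows_a)
    blk <- accumulate_kernel(sub, k, sigma, buffer_capacity,
                             seq_len(na), na + seq_along(job$rows_b))
  }
  dimnames(blk) <- list(ids[job$rows_a], ids[job$rows_b])
  structure(list(job = job, block = blk,
                 ids_a = ids[job$rows_a], ids_b = ids[job$rows_b]),
            class = "kernel_block")
}

#' Assemble sub-matrix blocks into the full kernel matrix
#'
#' Joins the blocks of one complete plan into the full symmetric Gram
#' matrix; off-diagonal blocks are mirrored. Since all arithmetic is
#' exact integer counting, the assembled matrix is identical to the
#' monolithic [compute_kernel_matrix()] result.
#'
#' @param blocks List of `"kernel_block"` objects covering all jobs of
#'   one plan exactly once.
#' @param k,sigma Trie parameters recorded on the result (must match
#'   those used for the blocks).
#' @return Full n x n kernel matrix as from [compute_kernel_matrix()]
#'   (unnormalized).
#' @export
assemble_kernel <- function(blocks, k, sigma) {
  if (!length(blocks)) stop("no blocks to assemble", call. = FALSE)
  if (!all(vapply(blocks, inherits, logical(1), what = "kernel_block")))
    stop("blocks must be 'kernel_block' objects", call. = FALSE)
  jobs <- lapply(blocks, `[[`, "job")
  m <- unique(vapply(jobs, `[[`, integer(1), "m"))
  ng <- unique(vapply(jobs, `[[`, integer(1), "n_groups"))
  if (length(m) != 1L || length(ng) != 1L)
    stop("blocks come from different plans", call. = FALSE)
  want <- plan_jobs(m, ng)
  key <- function(j) paste0(j$a, "_", j$b)
  have <- vapply(jobs, key, character(1))
  need <- vapply(want, key, character(1))
  if (anyDuplicated(have))
    stop("duplicate block(s): block_",
         paste(unique(have[duplicated(have)]), collapse = ", block_"),
         call. = FALSE)
  missing <- setdiff(need, have)
  if (length(missing))
    stop("missing block(s): block_", paste(missing, collapse = ", block_"),
         call. = FALSE)
  ids <- character(m)
  K <- matrix(0, m, m)
  for (bl in blocks) {
    j <- bl$job
    if (!identical(dim(bl$block),
                   c(length(j$rows_a), length(j$rows_b))))
      stop("block_", key(j), ": dimension mismatch", call. = FALSE)
    K[j$rows_a, j$rows_b] <- bl$block
    if (j$a != j$b) K[j$rows_b, j$rows_a] <- t(bl$block)
    ids[j$rows_a] <- bl$ids_a
    ids[j$rows_b] <- bl$ids_b
  }
  dimnames(K) <- list(ids, ids)
  attr(K, "k") <- k
  attr(K, "sigma") <- sigma
  attr(K, "normalized") <- FALSE
  K
}

#' Write / read a kernel matrix as TSV
#'
#' Human-readable persistence: a header line with profile ids, then one
#' row per profile (`id` + values). Values are printed with 17
#' significant digits and round-trip exactly; writing is deterministic,
#' so equal matrices produce byte-identical files.
#'
#' @param K Kernel matrix with id dimnames (and `k`/`sigma`/`normalized`
#'   attributes, stored in a comment line).
#' @param path Output path.
#' @return `write_kernel_tsv`: invisibly `path`. `read_kernel_tsv`: the
#'   matrix with dimnames and attributes restored.
#' @export
write_kernel_tsv <- function(K, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# profkernel kernel k=%s sigma=%s normalized=%d",
                     fmt_num(attr(K, "k") %||% NA_real_),
                     fmt_num(attr(K, "sigma") %||% NA_real_),
                     as.integer(isTRUE(attr(K, "normalized")))), con)
  writeLines(paste(c("id", colnames(K)), collapse = "\t"), con)
  for (i in seq_len(nrow(K)))
    writeLines(paste(c(rownames(K)[i], fmt_num(K[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[1]
  if (!startsWith(meta, "# profkernel kernel"))
    stop("not a profkernel kernel TSV: ", path, call. = FALSE)
  kv <- regmatches(meta, gregexpr("[a-z]+=[^ ]+", meta))[[1]]
  vals <- sub("^[a-z]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  ids <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[2 + i], "\t", fixed = TRUE)[[1]]
    if (f[1] != ids[i])
      stop("kernel TSV row/column id mismatch at row ", i, call. = FALSE)
    K[i, ] <- as.numeric(f[-1])
  }
  attr(K, "k") <- as.numeric(vals[["k"]])
  attr(K, "sigma") <- as.numeric(vals[["sigma"]])
  attr(K, "normalized") <- vals[["normalized"]] == "1"
  K
}
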