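test_that("saturated single-profile kernel follows the closed form", {
  # all-zero 4x20 profile, k=3, sigma=1: every one of the 20^3 leaves
  # holds both windows, so K = 20^3 * (L-k+1)^2 = 32000
  K <- compute_kernel_matrix(list(zero_profile(4)), 3, 1)
  expect_identical(as.numeric(K), 8000 * 4)
})

test_that("spectrum-degenerate profiles without shared k-mers are orthogonal", {
  ps <- list(profile_from_sequence("ACD", id = "s1"),
             profile_from_sequence("CDE", id = "s2"))
  K <- compute_kernel_matrix(ps, 3, 50, normalize = TRUE)
  expect_identical(as.numeric(diag(K)), c(1, 1))
  expect_identical(K[1, 2], 0)
})

test_that("kernel matrix equals the brute-force Gram matrix exactly", {
  ps <- rand_profiles(10, c(15, 30), seed = 41)
  k <- 3; sigma <- 6
  K <- compute_kernel_matrix(ps, k, sigma)
  expect_identical(kernel_values(K), oracle_kernel(ps, k, sigma))
  expect_identical(kernel_values(K), t(kernel_values(K)))
  expect_true(all(K == floor(K)) && all(K >= 0))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * norm(K, "2"))
})

test_that("kernel result is invariant to buffer capacity", {
  ps <- rand_profiles(8, c(15, 25), seed = 43)
  ref <- compute_kernel_matrix(ps, 2, 6, buffer_capacity = Inf)
  for (cap in c(1, 7, 1000)) {
    expect_identical(compute_kernel_matrix(ps, 2, 6, buffer_capacity = cap),
                     ref)
  }
})

test_that("flush_buffer performs the per-leaf pairwise update as one product", {
  # empty buffer: no-op
  acc <- new_kernel_accumulator(1:3)
  flush_buffer(new_count_buffer(10), acc)
  expect_identical(acc$K, matrix(0, 3, 3))

  # one triplet (profile 1, leaf 5, count 3): only K[1,1] += 9
  buf <- new_count_buffer(10)
  profkernel:::buffer_add(buf, 1L, 5, 3L)
  flush_buffer(buf, acc)
  expect_identical(acc$K[1, 1], 9)
  expect_identical(sum(acc$K != 0), 1L)
  expect_identical(profkernel:::buffer_size(buf), 0L)

  # random buffer equals the naive double loop over same-leaf pairs
  set.seed(8)
  n <- 6L
  i <- sample.int(n, 200, replace = TRUE)
  leaf <- sample(0:39, 200, replace = TRUE)
  key <- paste(i, leaf)
  keep <- !duplicated(key)  # one triplet per (row, column) pair
  i <- i[keep]; leaf <- leaf[keep]
  x <- sample.int(5, length(i), replace = TRUE)
  naive <- matrix(0, n, n)
  for (a in seq_along(i)) for (b in seq_along(i)) {
    if (leaf[a] == leaf[b]) naive[i[a], i[b]] <- naive[i[a], i[b]] + x[a] * x[b]
  }
  buf <- new_count_buffer(1e4)
  buf$i <- i; buf$leaf <- leaf; buf$x <- as.numeric(x)
  acc <- new_kernel_accumulator(seq_len(n))
  flush_buffer(buf, acc)
  expect_equal(acc$K, naive)
})

test_that("kernel entries are monotone in sigma", {
  ps <- rand_profiles(6, c(15, 25), seed = 47)
  sigmas <- c(1, 4, 8, 13)
  Ks <- lapply(sigmas, function(s) compute_kernel_matrix(ps, 2, s))
  for (i in seq_len(length(Ks) - 1))
    expect_true(all(Ks[[i]] <= Ks[[i + 1]]))
})

test_that("saturation closed form holds for every profile pair", {
  ps <- rand_profiles(4, c(10, 15), seed = 49)
  lens <- vapply(ps, profile_length, integer(1))
  for (k in 1:3) {
    sigma <- k * max(vapply(ps, function(p) max(p$scores), numeric(1))) + 1
    K <- compute_kernel_matrix(ps, k, sigma)
    expect_identical(kernel_values(K),
                     matrix(20^k * outer(lens - k + 1, lens - k + 1),
                            4, dimnames = list(profile_ids(ps),
                                               profile_ids(ps))))
  }
})

test_that("normalization is cosine and refuses zero-diagonal profiles", {
  ps <- rand_profiles(5, c(15, 20), seed = 51)
  K <- compute_kernel_matrix(ps, 2, 6)
  Kn <- compute_kernel_matrix(ps, 2, 6, normalize = TRUE)
  expect_equal(unname(diag(Kn)), rep(1, 5))
  expect_equal(kernel_values(Kn),
               kernel_values(K / sqrt(outer(diag(K), diag(K)))))
  # a profile with no conserved k-mers must be named in the error
  psz <- c(ps, list(new_profile("allhigh", matrix(50, 10, 20))))
  expect_error(compute_kernel_matrix(psz, 2, 6, normalize = TRUE),
               "allhigh")
})

test_that("job planning partitions profiles into near-equal contiguous groups", {
  jobs <- plan_jobs(10, 1)
  expect_length(jobs, 1L)
  expect_identical(jobs[[1]]$rows_a, 1:10)

  jobs <- plan_jobs(10, 3)
  expect_length(jobs, 6L)
  sizes <- vapply(plan_jobs(10, 3)[c(1, 4, 6)],
                  function(j) length(j$rows_a), integer(1))
  expect_identical(sizes, c(4L, 3L, 3L))
  expect_error(plan_jobs(5, 6), "n_groups")

  # every unordered profile pair is covered exactly once
  for (m in c(17L, 60L, 200L)) {
    for (ng in c(2L, 5L, min(20L, m))) {
      cover <- matrix(0L, m, m)
      for (j in plan_jobs(m, ng)) {
        cover[j$rows_a, j$rows_b] <- cover[j$rows_a, j$rows_b] + 1L
        if (j$a != j$b)
          cover[j$rows_b, j$rows_a] <- cover[j$rows_b, j$rows_a] + 1L
      }
      expect_true(all(cover == 1L))
    }
  }
})

test_that("sub-matrix blocks sit bit-identically inside the monolithic matrix", {
  ps <- rand_profiles(30, c(15, 25), seed = 53)
  k <- 2; sigma <- 5
  K <- compute_kernel_matrix(ps, k, sigma)
  jobs <- plan_jobs(30, 3)
  for (j in jobs) {
    blk <- compute_sub_matrix(ps, j, k, sigma)
    expect_identical(blk$block, K[j$rows_a, j$rows_b, drop = FALSE])
  }
  # single-group plan is the monolithic computation
  whole <- compute_sub_matrix(ps, plan_jobs(30, 1)[[1]], k, sigma)
  expect_identical(whole$block, kernel_values(K))
  # single-profile diagonal block is the squared feature norm
  one <- compute_sub_matrix(ps[1], plan_jobs(1, 1)[[1]], k, sigma)
  expect_identical(as.numeric(one$block),
                   sum(dense_fv(ps[[1]], k, sigma)^2))
})

test_that("assembled matrix is identical to the monolithic one for all group counts", {
  ps <- rand_profiles(30, c(15, 25), seed = 57)
  k <- 2; sigma <- 5
  K <- compute_kernel_matrix(ps, k, sigma)
  for (ng in c(2, 3, 5)) {
    blocks <- lapply(plan_jobs(30, ng), compute_sub_matrix,
                     profiles = ps, k = k, sigma = sigma)
    expect_identical(assemble_kernel(blocks, k, sigma), K)
  }
})

test_that("assembly validates coverage and dimensions", {
  ps <- rand_profiles(9, c(15, 20), seed = 59)
  blocks <- lapply(plan_jobs(9, 3), compute_sub_matrix,
                   profiles = ps, k = 2, sigma = 5)
  expect_error(assemble_kernel(blocks[-2], 2, 5), "missing block.*1_2")
  expect_error(assemble_kernel(c(blocks, blocks[2]), 2, 5),
               "duplicate block.*1_2")
  bad <- blocks
  bad[[2]]$block <- bad[[2]]$block[-1, , drop = FALSE]
  expect_error(assemble_kernel(bad, 2, 5), "dimension mismatch")
})

test_that("kernel TSV persistence round-trips exactly", {
  ps <- rand_profiles(6, c(15, 20), seed = 61)
  K <- compute_kernel_matrix(ps, 2, 5)
  f <- withr::local_tempfile()
  write_kernel_tsv(K, f)
  expect_identical(read_kernel_tsv(f), K)
})
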