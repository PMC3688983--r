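# one end-to-end labeled task shared by the workflow tests
wf_task <- generate_labeled_profiles(n_per_class = 10, n_classes = 3,
                                     seed = 401)
wf_split <- split_task(wf_task, 7)
wf_k <- 3; wf_sigma <- 5

test_that("one-vs-rest training produces one oriented SVM per class", {
  K <- compute_kernel_matrix(wf_split$train, wf_k, wf_sigma)
  labs <- wf_split$labels[rownames(K)]
  svms <- train_ovr_svms(K, labs)
  expect_identical(names(svms), sort(unique(unname(labs))))
  for (cls in names(svms)) {
    s <- svms[[cls]]
    expect_s3_class(s, "dual_svm")
    expect_true(all(s$support_ids %in% rownames(K)))
    dec <- as.vector(K[, s$support_ids] %*% s$weights) + s$bias
    # oriented: the class's own members score higher on average
    expect_gt(mean(dec[labs == cls]), mean(dec[labs != cls]))
  }
  expect_error(train_ovr_svms(K, labs[-1]), "unlabeled")
  expect_error(train_ovr_svms(K, setNames(rep("one", nrow(K)),
                                          rownames(K))),
               "at least 2 classes")
})

test_that("labels referencing a missing profile id are rejected by id", {
  K <- compute_kernel_matrix(wf_split$train, wf_k, wf_sigma)
  labs <- wf_split$labels[rownames(K)]
  labs["phantom_id"] <- "class01"
  expect_error(train_ovr_svms(K, labs), "missing profile id.*phantom_id")
})

test_that("model creation writes a complete model folder with manifest", {
  dir <- withr::local_tempdir()
  res <- run_create(wf_split$train, wf_split$labels[profile_ids(wf_split$train)],
                    dir, wf_k, wf_sigma)
  expect_setequal(list.files(dir),
                  c("params.json", "normals.tsv.gz", "biases.tsv",
                    "training_ids.txt", "manifest.json"))
  expect_length(res$svms, 3L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(as.numeric(man$k), wf_k)
  expect_identical(man$n_svms, 3L)
  expect_true(all(c("kernel_matrix", "svm_training", "normal_extraction")
                  %in% names(man$stage_seconds)))
})

test_that("model creation is reproducible: reruns are byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  labs <- wf_split$labels[profile_ids(wf_split$train)]
  run_create(wf_split$train, labs, d1, wf_k, wf_sigma)
  run_create(wf_split$train, labs, d2, wf_k, wf_sigma)
  for (f in c("normals.tsv.gz", "biases.tsv", "params.json",
              "training_ids.txt"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
})

test_that("applying a model to its training profiles reproduces training scores", {
  dir <- withr::local_tempdir()
  labs <- wf_split$labels[profile_ids(wf_split$train)]
  res <- run_create(wf_split$train, labs, dir, wf_k, wf_sigma)
  train_scores <- score_queries(wf_split$train, res$normal)
  out <- file.path(dir, "pred.tsv")
  ap <- run_apply(dir, wf_split$train, out = out)
  rel <- abs(ap$scores - train_scores) /
    pmax(abs(train_scores), 1e-12)
  expect_lt(max(rel), 1e-9)
  tsv <- utils::read.table(out, sep = "\t", header = TRUE)
  expect_identical(nrow(tsv), length(wf_split$train))
  expect_named(tsv, c("query_id", "predicted_class", "score",
                      "second_class", "margin"))
})

test_that("apply validates parameters and rejects empty query sets", {
  dir <- withr::local_tempdir()
  labs <- wf_split$labels[profile_ids(wf_split$train)]
  run_create(wf_split$train, labs, dir, wf_k, wf_sigma)
  expect_error(run_apply(dir, wf_split$test, k = wf_k + 1),
               "does not match model")
  expect_error(run_apply(dir, list()), "empty query set")
  # a too-short query among valid ones: valid rows still produced
  shorty <- new_profile("shorty", matrix(0, 2, 20))
  expect_warning(ap <- run_apply(dir, c(wf_split$test[1:3], list(shorty))),
                 "shorty")
  expect_identical(nrow(ap$predictions), 3L)
})

test_that("single-query application yields a single-row output", {
  dir <- withr::local_tempdir()
  labs <- wf_split$labels[profile_ids(wf_split$train)]
  run_create(wf_split$train, labs, dir, wf_k, wf_sigma)
  out <- file.path(dir, "one.tsv")
  ap <- run_apply(dir, wf_split$test[1], out = out)
  expect_identical(nrow(ap$predictions), 1L)
  expect_length(readLines(out), 2L)  # header + one row
})

test_that("blocks mode + assembly reproduce the monolithic kernel byte-for-byte", {
  ps <- rand_profiles(30, c(15, 25), seed = 403)
  pf <- withr::local_tempfile(); write_profiles(ps, pf)
  mono <- withr::local_tempfile()
  run_kernel(pf, mono, 2, 5)
  for (np in c(1L, 2L, 4L)) {
    bd <- withr::local_tempdir()
    paths <- run_blocks(pf, bd, 2, 5, n_groups = 3, n_processes = np)
    expect_length(paths, 6L)
    asm <- withr::local_tempfile()
    run_assemble(bd, asm)
    expect_identical(readLines(asm), readLines(mono))
  }
  # single group, single process: one block equals the whole kernel
  bd <- withr::local_tempdir()
  expect_length(run_blocks(pf, bd, 2, 5, n_groups = 1), 1L)
  asm <- withr::local_tempfile()
  run_assemble(bd, asm)
  expect_identical(readLines(asm), readLines(mono))
  # deleted block file: error names the block
  bd <- withr::local_tempdir()
  run_blocks(pf, bd, 2, 5, n_groups = 3)
  file.remove(file.path(bd, "block_1_2.tsv"))
  expect_error(run_assemble(bd, withr::local_tempfile()),
               "block_1_2")
})

test_that("create + apply recovers held-out classes on a separable task", {
  dir <- withr::local_tempdir()
  labs <- wf_split$labels[profile_ids(wf_split$train)]
  run_create(wf_split$train, labs, dir, wf_k, wf_sigma)
  ap <- run_apply(dir, wf_split$test)
  acc <- mean(ap$predictions$predicted_class ==
                wf_split$labels[ap$predictions$query_id])
  expect_gte(acc, 0.9)
})

test_that("the normalized-kernel pipeline is internally consistent end to end", {
  dir <- withr::local_tempdir()
  labs <- wf_split$labels[profile_ids(wf_split$train)]
  res <- run_create(wf_split$train, labs, dir, wf_k, wf_sigma,
                    normalize = TRUE)
  expect_true(res$normal$normalized)
  a <- score_queries(wf_split$test, res$normal)
  b <- score_queries_baseline(wf_split$test, wf_split$train, res$svms,
                              wf_k, wf_sigma, normalized = TRUE)
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), 1e-9)
  ap <- run_apply(dir, wf_split$test)
  acc <- mean(ap$predictions$predicted_class ==
                wf_split$labels[ap$predictions$query_id])
  expect_gte(acc, 0.9)
})
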