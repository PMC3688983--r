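#' Train one-vs-rest SVMs on a precomputed profile kernel
#'
#' For every class (in sorted order) a binary C-SVM is trained on the
#' precomputed Gram matrix (class versus rest) with
#' [kernlab::ksvm()], and its dual solution is repackaged as a
#' [dual_svm()] oriented so that the positive class scores higher. When
#' the kernel was cosine-normalized, the dual weights are mapped back
#' to the raw feature space (`coef_i / sqrt(K_raw[i, i])`, with
#' `raw_diag` the raw kernel diagonal) so that downstream trie-based
#' scoring operates on raw conserved k-mer counts throughout.
#'
#' @param K Kernel matrix with profile ids as dimnames (attributes
#'   `k`/`sigma` are carried onto the SVMs when present).
#' @param labels Named character vector id -> class covering every row
#'   of `K`; at least two classes.
#' @param cost SVM cost parameter C.
#' @param raw_diag Raw-kernel diagonal named by id; required when `K`
#'   is normalized.
#' @return List of `"dual_svm"` objects, one per class, named by class.
#' @export
train_ovr_svms <- function(K, labels, cost = 1, raw_diag = NULL) {
  ids <- rownames(K)
  if (is.null(ids)) stop("K must have profile ids as dimnames",
                         call. = FALSE)
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab))
    stop("unlabeled profile id(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  unresolved <- setdiff(names(labels), ids)
  if (length(unresolved))
    stop("label(s) reference missing profile id(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  y_all <- labels[ids]
  classes <- sort(unique(unname(y_all)))
  if (length(classes) < 2L)
    stop("need at least 2 classes, got: ", classes, call. = FALSE)
  if (isTRUE(attr(K, "normalized")) && is.null(raw_diag))
    stop("raw_diag is required for a normalized kernel", call. = FALSE)
  km <- kernlab::as.kernelMatrix(unclass(K)[, , drop = FALSE])
  svms <- lapply(classes, function(cls) {
    y <- factor(ifelse(y_all == cls, cls, ".rest"),
                levels = c(cls, ".rest"))
    fit <- kernlab::ksvm(km, y, type = "C-svc", C = cost)
    sv <- kernlab::alphaindex(fit)
    co <- kernlab::coef(fit)
    if (is.list(sv)) sv <- sv[[1]]
    if (is.list(co)) co <- co[[1]]
    bb <- kernlab::b(fit)
    dec <- as.vector(K[, sv, drop = FALSE] %*% co) - bb
    w <- co; bias <- -bb
    # orient so the positive class has the larger mean decision value
    if (mean(dec[y_all == cls]) < mean(dec[y_all != cls])) {
      w <- -w; bias <- -bias
    }
    if (!is.null(raw_diag)) w <- w / sqrt(raw_diag[ids[sv]])
    dual_svm(ids[sv], as.numeric(w), bias, name = cls,
             k = attr(K, "k"), sigma = attr(K, "sigma"))
  })
  names(svms) <- classes
  svms
}

resolve_profiles <- function(x) {
  if (is.character(x) && length(x) == 1L) read_profiles(x) else {
    check_profile_set(x)
    x
  }
}

resolve_labels <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    read_labels(x)
  else x
}

stage_timer <- function() {
  e <- new.env(parent = emptyenv())
  e$stages <- list()
  e$run <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(code)
    e$stages[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  e
}

#' Build a ready-to-use profile-kernel classifier (model creation)
#'
#' Single-call training pipeline: computes the kernel matrix from the
#' labeled training profiles, trains one one-vs-rest SVM per class,
#' extracts all SVM normal vectors in one trie traversal and stores
#' the model folder together with a manifest (k, sigma, class counts,
#' SVM count, per-stage wall times). Deterministic given fixed inputs.
#'
#' @param profiles Profile file path or list of `"profile"` objects.
#' @param labels Label TSV path or named character vector id -> class.
#' @param model_dir Output model folder.
#' @param k,sigma Trie parameters.
#' @param buffer_capacity Count-buffer capacity.
#' @param normalize Cosine-normalize the kernel before SVM training.
#' @param cost SVM cost parameter C.
#' @return Invisibly, a list with `model_dir`, `svms`, `normal`,
#'   `kernel` and the manifest.
#' @export
run_create <- function(profiles, labels, model_dir, k, sigma,
                       buffer_capacity = 1e6, normalize = FALSE,
                       cost = 1) {
  tm <- stage_timer()
  profiles <- tm$run("read_profiles", resolve_profiles(profiles))
  labels <- resolve_labels(labels)
  K_raw <- tm$run("kernel_matrix",
                  compute_kernel_matrix(profiles, k, sigma,
                                        buffer_capacity))
  K_train <- if (normalize) normalize_kernel(K_raw) else K_raw
  raw_diag <- if (normalize)
    stats::setNames(diag(K_raw), rownames(K_raw)) else NULL
  svms <- tm$run("svm_training",
                 train_ovr_svms(K_train, labels, cost = cost,
                                raw_diag = raw_diag))
  sup_ids <- sort(unique(unlist(lapply(svms, `[[`, "support_ids"))))
  normal <- tm$run("normal_extraction",
                   extract_normals(profiles, svms, k, sigma,
                                   normalized = normalize))
  tm$run("save_model", save_model(normal, model_dir,
                                  training_ids = sup_ids))
  cls_counts <- table(labels[profile_ids(profiles)])
  manifest <- list(k = k, sigma = sigma, normalize = normalize,
                   cost = cost, n_profiles = length(profiles),
                   classes = as.list(cls_counts),
                   n_svms = length(svms),
                   stage_seconds = tm$stages)
  jsonlite::write_json(manifest, file.path(model_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model_dir = model_dir, svms = svms, normal = normal,
                 kernel = K_raw, manifest = manifest))
}

#' Apply a stored model to query profiles (model application)
#'
#' Loads a model folder, scores every query with the normal matrix in
#' one trie traversal and writes a prediction TSV with one row per
#' scored query: `query_id`, `predicted_class`, `score`,
#' `second_class`, `margin` (scores rounded to 6 decimals in the text
#' output; the returned objects keep full precision). Queries shorter
#' than k are skipped with a warning.
#'
#' @param model_dir Model folder from [run_create()] / [save_model()].
#' @param queries Profile file path or list of `"profile"` objects.
#' @param out Output TSV path (optional).
#' @param scores_out Optional path for the full score matrix TSV.
#' @param k,sigma Optional; when given they must match the model's
#'   stored parameters (guards against applying a model with the wrong
#'   settings).
#' @param buffer_capacity Count-buffer capacity.
#' @return Invisibly, list with `predictions` (data frame) and
#'   `scores` (matrix).
#' @export
run_apply <- function(model_dir, queries, out = NULL, scores_out = NULL,
                      k = NULL, sigma = NULL, buffer_capacity = 1e6) {
  normal <- load_model(model_dir)
  if ((!is.null(k) && k != normal$k) ||
      (!is.null(sigma) && sigma != normal$sigma))
    stop("requested (k, sigma) = (", k %||% "-", ", ", sigma %||% "-",
         ") does not match model parameters (", normal$k, ", ",
         normal$sigma, ")", call. = FALSE)
  queries <- resolve_profiles(queries)
  if (!length(queries)) stop("empty query set", call. = FALSE)
  scores <- score_queries(queries, normal, buffer_capacity)
  pred <- predict_classes(scores)
  if (!is.null(out)) {
    txt <- pred
    txt$score <- sprintf("%.6f", txt$score)
    txt$margin <- sprintf("%.6f", txt$margin)
    utils::write.table(txt[, c("query_id", "predicted_class", "score",
                               "second_class", "margin")],
                       out, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  if (!is.null(scores_out)) {
    con <- file(scores_out, "w")
    writeLines(paste(c("query_id", colnames(scores)), collapse = "\t"),
               con)
    for (i in seq_len(nrow(scores)))
      writeLines(paste(c(rownames(scores)[i], fmt_num(scores[i, ])),
                       collapse = "\t"), con)
    close(con)
  }
  invisible(list(predictions = pred, scores = scores))
}

#' Compute and write the full kernel matrix (kernel mode)
#'
#' @inheritParams run_create
#' @param out Output TSV path.
#' @return Invisibly, the kernel matrix.
#' @export
run_kernel <- function(profiles, out, k, sigma, buffer_capacity = 1e6,
                       normalize = FALSE) {
  profiles <- resolve_profiles(profiles)
  K <- compute_kernel_matrix(profiles, k, sigma, buffer_capacity,
                             normalize)
  write_kernel_tsv(K, out)
  invisible(K)
}

block_file <- function(dir, a, b) file.path(dir,
                                            sprintf("block_%d_%d.tsv", a, b))

write_block_tsv <- function(block, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  j <- block$job
  writeLines(sprintf("# profkernel block a=%d b=%d n_groups=%d m=%d",
                     j$a, j$b, j$n_groups, j$m), con)
  writeLines(paste(c("id", block$ids_b), collapse = "\t"), con)
  for (i in seq_len(nrow(block$block)))
    writeLines(paste(c(block$ids_a[i], fmt_num(block$block[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

read_block_tsv <- function(path, job) {
  lines <- readLines(path, warn = FALSE)
  ids_b <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ids_a <- vapply(rows, `[`, character(1), 1L)
  blk <- matrix(as.numeric(unlist(lapply(rows, `[`, -1L))),
                nrow = length(rows), byrow = TRUE,
                dimnames = list(ids_a, ids_b))
  structure(list(job = job, block = blk, ids_a = ids_a, ids_b = ids_b),
            class = "kernel_block")
}

#' Block-wise kernel computation across processes (blocks mode)
#'
#' Plans the group pairs with [plan_jobs()], computes every sub-matrix
#' with [compute_sub_matrix()] distributed over `n_processes` worker
#' processes, and writes one `block_<a>_<b>.tsv` file per job plus a
#' `plan.json` describing the split. Each job only receives its two
#' groups' profiles, so workers share no state; results are identical
#' for any process count.
#'
#' @inheritParams run_create
#' @param out_dir Output directory for block files.
#' @param n_groups Number of profile groups.
#' @param n_processes Number of parallel worker processes.
#' @return Invisibly, the vector of written block file paths.
#' @export
run_blocks <- function(profiles, out_dir, k, sigma, n_groups,
                       n_processes = 1L, buffer_capacity = 1e6) {
  profiles <- resolve_profiles(profiles)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jobs <- plan_jobs(length(profiles), n_groups)
  jsonlite::write_json(list(m = length(profiles), n_groups = n_groups,
                            k = k, sigma = sigma,
                            ids = profile_ids(profiles)),
                       file.path(out_dir, "plan.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  worker <- function(job) {
    blk <- compute_sub_matrix(profiles, job, k, sigma, buffer_capacity)
    write_block_tsv(blk, block_file(out_dir, job$a, job$b))
  }
  paths <- if (n_processes > 1L) {
    unlist(parallel::mclapply(jobs, worker, mc.cores = n_processes))
  } else {
    vapply(jobs, worker, character(1))
  }
  invisible(paths)
}

#' Assemble block files into the full kernel matrix (assemble mode)
#'
#' Reads `plan.json` and every block file written by [run_blocks()],
#' joins them with [assemble_kernel()] and writes the kernel TSV --
#' byte-identical to the output of [run_kernel()] on the same input.
#'
#' @param blocks_dir Directory holding `plan.json` and block files.
#' @param out Output kernel TSV path.
#' @return Invisibly, the assembled kernel matrix.
#' @export
run_assemble <- function(blocks_dir, out) {
  pf <- file.path(blocks_dir, "plan.json")
  if (!file.exists(pf))
    stop("missing plan.json in ", blocks_dir, call. = FALSE)
  plan <- jsonlite::read_json(pf, simplifyVector = TRUE)
  jobs <- plan_jobs(plan$m, plan$n_groups)
  blocks <- lapply(jobs, function(j) {
    bf <- block_file(blocks_dir, j$a, j$b)
    if (!file.exists(bf))
      stop("missing block file: block_", j$a, "_", j$b, ".tsv",
           call. = FALSE)
    read_block_tsv(bf, j)
  })
  K <- assemble_kernel(blocks, k = plan$k, sigma = plan$sigma)
  write_kernel_tsv(K, out)
  invisible(K)
}
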