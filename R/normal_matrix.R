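#' Construct a dual-form binary SVM
#'
#' Minimal representation of a trained binary SVM in dual form: the
#' support-vector profile ids, one real weight per support (the product
#' of dual coefficient and label, expressed in the *raw* conserved
#' k-mer feature space), and the bias. The decision value of a query q
#' is `sum_i weights[i] * K(x_i, q) + bias` (divided by the query's
#' feature norm first when the model is cosine-normalized).
#'
#' @param support_ids Character vector of support profile ids.
#' @param weights Numeric weights, same length, finite, not all zero.
#' @param bias Scalar bias added to every score.
#' @param name Optional SVM name (the class it separates in
#'   one-vs-rest).
#' @param k,sigma Optional trie parameters the SVM was trained with;
#'   checked for consistency at extraction time when present.
#' @return Object of class `"dual_svm"`.
#' @export
dual_svm <- function(support_ids, weights, bias, name = NULL,
                     k = NULL, sigma = NULL) {
  if (length(support_ids) != length(weights) || length(support_ids) == 0L)
    stop("support_ids and weights must have equal positive length",
         call. = FALSE)
  if (anyDuplicated(support_ids))
    stop("duplicate support ids", call. = FALSE)
  if (any(!is.finite(weights)) || all(weights == 0))
    stop("weights must be finite with at least one nonzero entry",
         call. = FALSE)
  if (!is.numeric(bias) || length(bias) != 1L || !is.finite(bias))
    stop("bias must be a finite scalar", call. = FALSE)
  structure(list(support_ids = as.character(support_ids),
                 weights = as.numeric(weights), bias = as.numeric(bias),
                 name = name, k = k, sigma = sigma),
            class = "dual_svm")
}

#' @export
print.dual_svm <- function(x, ...) {
  cat("<dual_svm>", if (!is.null(x$name)) x$name else "(unnamed)",
      "|", length(x$support_ids), "support vectors, bias",
      format(x$bias), "\n")
  invisible(x)
}

#' Extract explicit SVM normal vectors via one trie traversal
#'
#' Makes the primal discriminants of dual-form SVMs explicit in the
#' 20^k feature space: column j is `w_j = sum_i weights_j[i] * Phi(x_i)`
#' over SVM j's support profiles. All columns are built in a *single*
#' traversal over the union of support profiles: at every leaf the
#' surviving counts are multiplied into all SVM weight vectors at once.
#' Leaves are visited in increasing index order, fixing the
#' floating-point accumulation order for run-to-run reproducibility.
#' Only leaves with at least one nonzero weight across SVMs are stored.
#'
#' @param support_profiles Profiles covering every support id of every
#'   SVM (extra profiles are ignored).
#' @param svms List of `"dual_svm"` objects (all with the same (k,
#'   sigma) where recorded).
#' @param k,sigma Trie parameters.
#' @param normalized Set when the SVMs were trained on a
#'   cosine-normalized kernel with weights already mapped to raw
#'   feature space; recorded so scoring divides by the query norm.
#' @return Object of class `"normal_matrix"`: list with `leaf` (sorted
#'   populated leaf indices), `values` (matrix, one row per stored leaf,
#'   one column per SVM), `biases`, `svm_names`, `k`, `sigma`,
#'   `normalized`.
#' @export
extract_normals <- function(support_profiles, svms, k, sigma,
                            normalized = FALSE) {
  check_trie_params(k, sigma)
  if (!length(svms)) stop("need at least one SVM", call. = FALSE)
  if (!all(vapply(svms, inherits, logical(1), what = "dual_svm")))
    stop("svms must be 'dual_svm' objects", call. = FALSE)
  for (s in svms) {
    if ((!is.null(s$k) && s$k != k) ||
        (!is.null(s$sigma) && s$sigma != sigma))
      stop("SVM '", s$name %||% "?",
           "' was trained with different (k, sigma)", call. = FALSE)
  }
  ids <- profile_ids(support_profiles)
  used <- sort(unique(unlist(lapply(svms, `[[`, "support_ids"))))
  unresolved <- setdiff(used, ids)
  if (length(unresolved))
    stop("unresolvable support id(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  sup <- support_profiles[match(used, ids)]
  n_sup <- length(sup)
  n_svm <- length(svms)
  W <- matrix(0, n_sup, n_svm)
  for (j in seq_len(n_svm))
    W[match(svms[[j]]$support_ids, used), j] <- svms[[j]]$weights
  acc_leaf <- collector()
  acc_val <- collector()
  trie_traverse(sup, k, sigma, function(leaf, idx, cnt) {
    v <- as.vector(crossprod(W[idx, , drop = FALSE], cnt))
    if (any(v != 0)) {
      collect(acc_leaf, leaf)
      collect(acc_val, v)
    }
  })
  leaf <- unlist(collected(acc_leaf), use.names = FALSE)
  if (is.null(leaf)) leaf <- numeric(0)
  values <- do.call(rbind, collected(acc_val))
  if (is.null(values)) values <- matrix(0, 0L, n_svm)
  names_ <- vapply(seq_len(n_svm), function(j)
    svms[[j]]$name %||% paste0("svm", j), character(1))
  zero_col <- colSums(values != 0) == 0
  if (any(zero_col))
    stop("all-zero normal vector(s) for SVM(s): ",
         paste(names_[zero_col], collapse = ", "), call. = FALSE)
  colnames(values) <- names_
  structure(list(leaf = leaf, values = values,
                 biases = stats::setNames(
                   vapply(svms, `[[`, numeric(1), "bias"), names_),
                 svm_names = names_, k = k, sigma = sigma,
                 normalized = isTRUE(normalized)),
            class = "normal_matrix")
}

#' @export
print.normal_matrix <- function(x, ...) {
  cat("<normal_matrix> k =", x$k, "sigma =", x$sigma, "|",
      length(x$leaf), "populated leaves x", ncol(x$values), "SVM(s)",
      if (x$normalized) "(normalized kernel)" else "", "\n")
  invisible(x)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a prediction model folder
#'
#' A model folder holds everything needed to score queries:
#' `params.json` (format version, k, sigma, SVM/class names, whether
#' the kernel was normalized), `normals.tsv.gz` (sparse normal matrix,
#' one row per populated leaf: leaf index + one weight per SVM, 17
#' significant digits so doubles round-trip bit-exactly),
#' `biases.tsv`, and `training_ids.txt` (support ids, when supplied).
#' `load_model(save_model(x))` reproduces every field exactly.
#'
#' @param normal A `"normal_matrix"` with at least one stored leaf.
#' @param path Model folder (created if needed).
#' @param training_ids Optional character vector recorded in the
#'   folder.
#' @return `save_model`: invisibly `path`; `load_model`: the restored
#'   `"normal_matrix"` (with a `training_ids` attribute when present).
#' @export
save_model <- function(normal, path, training_ids = NULL) {
  if (!inherits(normal, "normal_matrix"))
    stop("normal must be a 'normal_matrix'", call. = FALSE)
  if (length(normal$leaf) == 0L)
    stop("refusing to save an empty normal matrix", call. = FALSE)
  if (any(colSums(normal$values != 0) == 0))
    stop("refusing to save all-zero normal vector(s)", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  params <- list(format_version = MODEL_FORMAT_VERSION,
                 k = normal$k, sigma = normal$sigma,
                 normalized = normal$normalized,
                 svm_names = as.list(normal$svm_names),
                 n_leaves = length(normal$leaf))
  jsonlite::write_json(params, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- gzfile(file.path(path, "normals.tsv.gz"), "wb")
  writeLines(c(paste(c("leaf", normal$svm_names), collapse = "\t"),
               vapply(seq_along(normal$leaf), function(i)
                 paste(c(fmt_num(normal$leaf[i]),
                         fmt_num(normal$values[i, ])), collapse = "\t"),
                 character(1))), con)
  close(con)
  writeLines(c("svm\tbias",
               paste(normal$svm_names, fmt_num(normal$biases),
                     sep = "\t")),
             file.path(path, "biases.tsv"))
  if (!is.null(training_ids))
    writeLines(training_ids, file.path(path, "training_ids.txt"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  pj <- file.path(path, "params.json")
  if (!file.exists(pj))
    stop("not a model folder (missing params.json): ", path, call. = FALSE)
  params <- jsonlite::read_json(pj, simplifyVector = TRUE)
  if (is.null(params$format_version) ||
      params$format_version != MODEL_FORMAT_VERSION)
    stop("unsupported model format version: ",
         params$format_version %||% "missing", call. = FALSE)
  nf <- file.path(path, "normals.tsv.gz")
  if (!file.exists(nf))
    stop("corrupted model folder (missing normals.tsv.gz): ", path,
         call. = FALSE)
  lines <- readLines(gzfile(nf), warn = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  svm_names <- hdr[-1]
  if (!identical(svm_names, as.character(params$svm_names)))
    stop("corrupted model: SVM names in normals.tsv.gz disagree with ",
         "params.json", call. = FALSE)
  body <- lines[-1]
  if (length(body) != params$n_leaves)
    stop("corrupted model: expected ", params$n_leaves,
         " normal-matrix rows, found ", length(body), call. = FALSE)
  vals <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
                 nrow = length(body), byrow = TRUE)
  if (ncol(vals) != length(svm_names) + 1L)
    stop("corrupted model: malformed normals.tsv.gz row width",
         call. = FALSE)
  bl <- utils::read.table(file.path(path, "biases.tsv"), sep = "\t",
                          header = TRUE, colClasses = c("character",
                                                        "numeric"))
  biases <- stats::setNames(bl$bias, bl$svm)[svm_names]
  values <- vals[, -1, drop = FALSE]
  colnames(values) <- svm_names
  out <- structure(list(leaf = vals[, 1], values = values,
                        biases = biases, svm_names = svm_names,
                        k = as.numeric(params$k),
                        sigma = as.numeric(params$sigma),
                        normalized = isTRUE(params$normalized)),
                   class = "normal_matrix")
  tf <- file.path(path, "training_ids.txt")
  if (file.exists(tf)) attr(out, "training_ids") <- readLines(tf)
  out
}
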