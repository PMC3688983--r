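# Drop queries shorter than k with a warning (partial-failure
# contract); errors only if nothing remains.
filter_scorable <- function(queries, k) {
  lens <- vapply(queries, profile_length, integer(1))
  short <- lens < k
  if (any(short))
    warning("skipping ", sum(short), " quer",
            if (sum(short) == 1L) "y" else "ies", " shorter than k = ", k,
            ": ", paste(profile_ids(queries)[short], collapse = ", "),
            call. = FALSE)
  if (all(short))
    stop("no query of length >= k = ", k, call. = FALSE)
  queries[!short]
}

#' Score query profiles against a normal matrix
#'
#' Computes the SVM score matrix `S[q, j] = w_j . Phi(query_q) +
#' bias_j` for every query and every SVM in *one* trie traversal over
#' all queries: at each leaf the queries' conserved k-mer counts are
#' staged in a sparse coordinate-list buffer; on flush the buffered
#' count matrix is multiplied against the corresponding rows of the
#' normal matrix and added to the score matrix. The result is
#' independent of the buffer capacity. For a model trained on a
#' cosine-normalized kernel, raw scores are divided by each query's
#' feature norm (accumulated in the same traversal) before the bias is
#' added.
#'
#' Queries shorter than k are skipped with a warning; remaining queries
#' are scored (an error is raised only when no query can be scored).
#'
#' @param queries List of `"profile"` objects.
#' @param normal A `"normal_matrix"` (see [extract_normals()],
#'   [load_model()]).
#' @param buffer_capacity Triplet capacity of the count buffer.
#' @return Numeric score matrix (rows = scored queries in input order,
#'   columns = SVMs), with dimnames.
#' @export
score_queries <- function(queries, normal, buffer_capacity = 1e6) {
  if (!inherits(normal, "normal_matrix"))
    stop("normal must be a 'normal_matrix'", call. = FALSE)
  check_profile_set(queries)
  queries <- filter_scorable(queries, normal$k)
  nq <- length(queries)
  ns <- ncol(normal$values)
  scores <- matrix(0, nq, ns)
  norm2 <- numeric(nq)
  buf <- new_count_buffer(buffer_capacity)
  flush_scores <- function() {
    if (buffer_size(buf) == 0L) return(invisible(NULL))
    hit <- match(buf$leaf, normal$leaf)
    ok <- !is.na(hit)
    if (any(ok)) {
      rows <- sort(unique(hit[ok]))
      C <- Matrix::sparseMatrix(i = buf$i[ok],
                                j = match(hit[ok], rows),
                                x = buf$x[ok],
                                dims = c(nq, length(rows)))
      scores <<- scores +
        as.matrix(C %*% normal$values[rows, , drop = FALSE])
    }
    buf$i <- integer(0); buf$leaf <- numeric(0); buf$x <- numeric(0)
    invisible(NULL)
  }
  trie_traverse(queries, normal$k, normal$sigma,
                function(leaf, idx, cnt) {
    norm2[idx] <<- norm2[idx] + as.numeric(cnt)^2
    if (buffer_size(buf) > 0L &&
        buffer_size(buf) + length(idx) > buf$capacity)
      flush_scores()
    buffer_add(buf, idx, leaf, cnt)
  })
  flush_scores()
  if (normal$normalized) {
    nrm <- sqrt(norm2)
    nrm[nrm == 0] <- 1  # zero-feature query: raw part is 0, score = bias
    scores <- scores / nrm
  }
  scores <- sweep(scores, 2L, normal$biases, "+")
  dimnames(scores) <- list(profile_ids(queries), normal$svm_names)
  scores
}

#' Baseline support-vector scoring (reference predictor)
#'
#' Reference implementation of prediction through the dual expansion:
#' `S[q, j] = sum_i weights_j[i] * K(x_i, query_q) + bias_j`, with the
#' supports-versus-queries kernel values obtained from a single
#' restricted trie traversal -- descent stops as soon as a subtree
#' holds no surviving query k-mer, so only support-query dot products
#' are computed. Agrees with [score_queries()] on the same model up to
#' floating-point accumulation order; kept as an internal oracle for
#' the normal-matrix path.
#'
#' @inheritParams score_queries
#' @param support_profiles Profiles resolving every support id.
#' @param svms List of `"dual_svm"` objects.
#' @param k,sigma Trie parameters (must match the SVMs' where
#'   recorded).
#' @param normalized Divide by query feature norms before adding
#'   biases, as for a cosine-normalized model.
#' @return Score matrix as in [score_queries()].
#' @export
score_queries_baseline <- function(queries, support_profiles, svms,
                                   k, sigma, normalized = FALSE) {
  check_trie_params(k, sigma)
  for (s in svms) {
    if ((!is.null(s$k) && s$k != k) ||
        (!is.null(s$sigma) && s$sigma != sigma))
      stop("SVM '", s$name %||% "?",
           "' was trained with different (k, sigma)", call. = FALSE)
  }
  check_profile_set(queries)
  queries <- filter_scorable(queries, k)
  ids <- profile_ids(support_profiles)
  used <- sort(unique(unlist(lapply(svms, `[[`, "support_ids"))))
  unresolved <- setdiff(used, ids)
  if (length(unresolved))
    stop("unresolvable support id(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  sup <- support_profiles[match(used, ids)]
  n_sup <- length(sup)
  nq <- length(queries)
  ns <- length(svms)
  W <- matrix(0, n_sup, ns)
  for (j in seq_len(ns))
    W[match(svms[[j]]$support_ids, used), j] <- svms[[j]]$weights
  Kcross <- matrix(0, n_sup, nq)
  norm2 <- numeric(nq)
  qidx <- n_sup + seq_len(nq)
  # queries may coincide with supports (e.g. scoring the training set);
  # give them distinct internal ids for the combined traversal
  qtmp <- lapply(seq_len(nq), function(i) {
    q <- queries[[i]]
    q$id <- paste0(".query:", i, ":", q$id)
    q
  })
  trie_traverse(c(sup, qtmp), k, sigma, function(leaf, idx, cnt) {
    isq <- idx > n_sup
    ci <- cnt[isq]
    qs <- idx[isq] - n_sup
    norm2[qs] <<- norm2[qs] + as.numeric(ci)^2
    if (any(!isq))
      Kcross[idx[!isq], qs] <<- Kcross[idx[!isq], qs, drop = FALSE] +
        outer(as.numeric(cnt[!isq]), as.numeric(ci))
  }, restrict_descent_to = qidx)
  scores <- crossprod(Kcross, W)
  if (normalized) {
    nrm <- sqrt(norm2)
    nrm[nrm == 0] <- 1
    scores <- scores / nrm
  }
  scores <- sweep(scores, 2L,
                  vapply(svms, `[[`, numeric(1), "bias"), "+")
  dimnames(scores) <- list(profile_ids(queries),
                           vapply(seq_len(ns), function(j)
                             svms[[j]]$name %||% paste0("svm", j),
                             character(1)))
  scores
}

#' Rank one-vs-rest SVM scores into class predictions
#'
#' With one SVM per class, classes are ranked per query by descending
#' score; exact ties are broken by class-name order (alphabetically
#' first wins) and flagged. Scores are raw one-vs-rest margins, not
#' calibrated probabilities.
#'
#' @param scores Score matrix from [score_queries()] or
#'   [score_queries_baseline()]; column names are the class names.
#' @return Data frame with one row per query: `query_id`,
#'   `predicted_class`, `score`, `second_class`, `margin`, `tie`; the
#'   full per-query class ranking is attached as attribute `"ranking"`
#'   (character matrix, one row per query).
#' @export
predict_classes <- function(scores) {
  if (is.null(colnames(scores)))
    stop("scores must have class names as column names", call. = FALSE)
  cls <- colnames(scores)
  if (anyDuplicated(cls))
    stop("one-vs-rest scheme requires one SVM per class", call. = FALSE)
  nq <- nrow(scores)
  ranking <- matrix("", nq, length(cls))
  out <- data.frame(query_id = rownames(scores),
                    predicted_class = character(nq), score = numeric(nq),
                    second_class = character(nq), margin = numeric(nq),
                    tie = logical(nq), stringsAsFactors = FALSE)
  for (i in seq_len(nq)) {
    ord <- order(-scores[i, ], cls)
    ranking[i, ] <- cls[ord]
    out$predicted_class[i] <- cls[ord[1]]
    out$score[i] <- scores[i, ord[1]]
    if (length(cls) > 1L) {
      out$second_class[i] <- cls[ord[2]]
      out$margin[i] <- scores[i, ord[1]] - scores[i, ord[2]]
      out$tie[i] <- scores[i, ord[1]] == scores[i, ord[2]]
    } else {
      out$second_class[i] <- NA_character_
      out$margin[i] <- NA_real_
    }
  }
  attr(out, "ranking") <- ranking
  out
}

#' Optional softmax over one-vs-rest scores
#'
#' Maps each query's score vector through a numerically stable softmax.
#' These are *not* calibrated probabilities -- only a monotone
#' convenience rescaling of the raw margins.
#'
#' @param scores Score matrix.
#' @return Matrix of the same shape with rows summing to 1.
#' @export
softmax_scores <- function(scores) {
  e <- exp(scores - apply(scores, 1L, max))
  e / rowSums(e)
}
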