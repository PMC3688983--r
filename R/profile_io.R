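#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in lexicographic one-letter-code order.
#' This order fixes the column order of every profile and the leaf
#' indexing of the k-mer trie (first k-mer letter most significant), so
#' all downstream feature, kernel and normal-matrix column orders are
#' reproducible.
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a protein profile
#'
#' A profile is a position-specific scoring matrix: one row per residue
#' position, one column per amino acid (in [AMINO_ACIDS] order). Entries
#' are non-negative substitution scores where *lower* means the amino
#' acid is more strongly conserved at that position. A k-mer is called
#' conserved in a window when the sum of its per-position scores does
#' not exceed the threshold sigma (see [feature_vector()]).
#'
#' @param id Non-empty profile identifier.
#' @param scores Numeric L x 20 matrix of finite, non-negative scores.
#' @return An object of class `"profile"`: a list with elements `id` and
#'   `scores` (with column names set to [AMINO_ACIDS]).
#' @export
new_profile <- function(id, scores) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("profile id must be a single non-empty string", call. = FALSE)
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("profile '", id, "': scores must be a numeric matrix", call. = FALSE)
  if (ncol(scores) != 20L)
    stop("profile '", id, "': scores must have exactly 20 columns, got ",
         ncol(scores), call. = FALSE)
  if (nrow(scores) < 1L)
    stop("profile '", id, "': scores must have at least one row", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("profile '", id, "': scores contain non-finite values", call. = FALSE)
  if (any(scores < 0))
    stop("profile '", id, "': scores must be non-negative", call. = FALSE)
  storage.mode(scores) <- "double"
  dimnames(scores) <- list(NULL, AMINO_ACIDS)
  structure(list(id = id, scores = scores), class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat("<profile> ", x$id, " (L = ", nrow(x$scores), ")\n", sep = "")
  invisible(x)
}

#' Profile length (number of residue positions)
#'
#' @param profile A `"profile"` object.
#' @return Integer number of rows of the score matrix.
#' @export
profile_length <- function(profile) nrow(profile$scores)

#' Profile ids of a profile list
#'
#' @param profiles List of `"profile"` objects.
#' @return Character vector of ids, in list order.
#' @export
profile_ids <- function(profiles) {
  vapply(profiles, function(p) p$id, character(1))
}

check_profile_set <- function(profiles) {
  if (!is.list(profiles))
    stop("profiles must be a list of profile objects", call. = FALSE)
  ok <- vapply(profiles, inherits, logical(1), what = "profile")
  if (length(profiles) && !all(ok))
    stop("profiles must all be 'profile' objects", call. = FALSE)
  ids <- profile_ids(profiles)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate profile id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  invisible(ids)
}

#' Read profiles from the plain-text profile format
#'
#' The format is line-oriented UTF-8 text: each record starts with a
#' header line `>ID L`, followed by exactly `L` lines of 20
#' whitespace-separated decimal scores (columns in [AMINO_ACIDS] order).
#' Records are concatenated; lines starting with `#` are comments and
#' ignored anywhere. A zero-byte file is rejected; a file containing
#' only comments parses to an empty profile list (this is what
#' [write_profiles()] emits for an empty set).
#'
#' @param path Path to a profile text file.
#' @return List of `"profile"` objects in file order.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stop("profile file is empty: ", path, call. = FALSE)
  keep <- !startsWith(trimws(lines, "left"), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  body <- lines[keep]
  profiles <- list()
  i <- 1L
  while (i <= length(body)) {
    ln <- lineno[i]
    header <- body[i]
    if (!startsWith(header, ">"))
      stop("line ", ln, ": expected record header '>ID L', got: ", header,
           call. = FALSE)
    parts <- strsplit(trimws(sub("^>", "", header)), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      stop("line ", ln, ": header must be '>ID L'", call. = FALSE)
    id <- parts[1]
    L <- suppressWarnings(as.integer(parts[2]))
    if (is.na(L) || L < 1L)
      stop("line ", ln, ": invalid length '", parts[2], "' in header",
           call. = FALSE)
    if (i + L > length(body))
      stop("line ", ln, ": record '", id, "' declares ", L,
           " rows but the file ends early", call. = FALSE)
    rows <- vector("list", L)
    for (r in seq_len(L)) {
      rl <- lineno[i + r]
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(body[i + r]), "[[:space:]]+")[[1]]))
      if (length(vals) != 20L)
        stop("line ", rl, ": expected 20 scores, got ", length(vals),
             call. = FALSE)
      if (any(is.na(vals)) || any(!is.finite(vals)))
        stop("line ", rl, ": non-numeric or non-finite score", call. = FALSE)
      if (any(vals < 0))
        stop("line ", rl, ": negative score", call. = FALSE)
      rows[[r]] <- vals
    }
    profiles[[length(profiles) + 1L]] <-
      new_profile(id, do.call(rbind, rows))
    i <- i + L + 1L
  }
  check_profile_set(profiles)
  profiles
}

# %.17g round-trips doubles exactly through strtod
fmt_num <- function(x) sprintf("%.17g", x)

#' Write profiles in the plain-text profile format
#'
#' Inverse of [read_profiles()]: the written file parses back to a
#' bit-identical profile list. Scores are printed with 17 significant
#' digits so that doubles round-trip exactly; output is deterministic,
#' so repeated writes of the same set are byte-identical.
#'
#' @param profiles List of `"profile"` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  check_profile_set(profiles)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# profkernel profiles: ", length(profiles), " record(s)"),
             con)
  for (p in profiles) {
    writeLines(paste0(">", p$id, " ", nrow(p$scores)), con)
    writeLines(apply(p$scores, 1L,
                     function(r) paste(fmt_num(r), collapse = " ")), con)
  }
  invisible(path)
}

#' Convert an amino-acid sequence to a degenerate one-hot profile
#'
#' Lets plain sequences (e.g. from FASTA) be used where profiles are
#' expected: position i gets `match_score` in the column of the observed
#' residue and `mismatch_score` in the other 19 columns. With
#' `match_score = 0` and a threshold sigma below `mismatch_score`, the
#' only conserved k-mers are the sequence's own k-mers, so the profile
#' kernel degenerates to the exact k-mer spectrum kernel.
#'
#' Non-standard residues (B, J, O, U, X, Z, *) are rejected: silently
#' remapping them would change kernel values invisibly.
#'
#' @param sequence Non-empty string over the 20 standard amino acids.
#' @param match_score,mismatch_score Non-negative scores with
#'   `match_score < mismatch_score`.
#' @param id Profile id; defaults to the sequence itself.
#' @return A `"profile"` object with one row per residue.
#' @export
profile_from_sequence <- function(sequence, match_score = 0,
                                  mismatch_score = 100,
                                  id = sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string", call. = FALSE)
  if (match_score < 0 || mismatch_score < 0 || match_score >= mismatch_score)
    stop("scores must satisfy 0 <= match_score < mismatch_score",
         call. = FALSE)
  res <- strsplit(toupper(sequence), "")[[1]]
  col <- match(res, AMINO_ACIDS)
  if (anyNA(col)) {
    bad <- unique(res[is.na(col)])
    stop("non-standard residue(s) in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  L <- length(res)
  scores <- matrix(mismatch_score, L, 20L)
  scores[cbind(seq_len(L), col)] <- match_score
  new_profile(id, scores)
}

#' Read sequences from a FASTA file as degenerate profiles
#'
#' @param path FASTA file path.
#' @inheritParams profile_from_sequence
#' @return List of `"profile"` objects, one per FASTA record; ids are
#'   the first whitespace-delimited token of each header.
#' @export
read_fasta_profiles <- function(path, match_score = 0, mismatch_score = 100) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(hdr[-1] - 1L, length(lines))
  profiles <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    id <- strsplit(sub("^>", "", lines[hdr[i]]), "[[:space:]]+")[[1]][1]
    seqstr <- paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    seqstr <- gsub("[[:space:]]", "", seqstr)
    profiles[[i]] <- profile_from_sequence(seqstr, match_score,
                                           mismatch_score, id = id)
  }
  check_profile_set(profiles)
  profiles
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

synth_position <- function(L, conservation) {
  true_res <- sample.int(20L, L, replace = TRUE)
  scores <- matrix(1 + 9 * conservation + stats::runif(L * 20L, 0, 3), L, 20L)
  scores[cbind(seq_len(L), true_res)] <- stats::runif(L, 0, 1)
  scores
}

#' Generate synthetic protein profiles
#'
#' Emulates evolutionary profiles at desk scale: at every position one
#' "true" residue drawn uniformly receives a low substitution score
#' (uniform on \[0, 1\]) while the other 19 receive high scores
#' (`1 + 9 * conservation` plus uniform \[0, 3\] noise). Larger
#' `conservation` widens the gap between the true residue and the rest,
#' so at a fixed (k, sigma) fewer alternative k-mers pass the threshold
#' and conserved-k-mer neighborhoods shrink.
#'
#' Output is deterministic for a fixed seed, and the caller's RNG state
#' is left untouched.
#'
#' @param n Number of profiles (>= 1).
#' @param length_range Integer vector `c(Lmin, Lmax)`, `1 <= Lmin <= Lmax`;
#'   lengths are drawn uniformly from this range.
#' @param conservation Conservation strength in (0, 1].
#' @param seed Integer RNG seed.
#' @param prefix Id prefix; profiles are named `<prefix>1 ... <prefix>n`.
#' @return List of `n` `"profile"` objects.
#' @export
generate_synthetic_profiles <- function(n, length_range = c(30L, 60L),
                                        conservation = 0.8, seed = 1L,
                                        prefix = "synth") {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[1] > length_range[2])
    stop("length_range must be c(Lmin, Lmax) with 1 <= Lmin <= Lmax",
         call. = FALSE)
  if (conservation <= 0 || conservation > 1)
    stop("conservation must be in (0, 1]", call. = FALSE)
  with_seed(seed, {
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n,
                 replace = TRUE) - 1L
    lapply(seq_len(n), function(i)
      new_profile(paste0(prefix, i), synth_position(lens[i], conservation)))
  })
}

#' Generate a labeled synthetic classification task
#'
#' Builds `n_classes` classes of profiles from the background model of
#' [generate_synthetic_profiles()] and implants one strongly conserved
#' class-specific motif per class (length `motif_length`; motif columns
#' have true-residue scores uniform on \[0, 0.5\] and mismatch scores
#' `10 +` uniform \[0, 2\]) at a random position of each member. Profiles
#' of the same class therefore share the motif's k-mers while
#' between-class overlap is limited to chance background collisions --
#' a well-separated task for end-to-end classifier checks.
#'
#' @param n_per_class Profiles per class.
#' @param n_classes Number of classes (>= 2).
#' @param length_range,conservation,seed As in
#'   [generate_synthetic_profiles()].
#' @param motif_length Length of the implanted class motif.
#' @return List with elements `profiles` (list of `"profile"`), `labels`
#'   (named character vector id -> class) and `motifs` (character vector
#'   of implanted motif sequences, one per class).
#' @export
generate_labeled_profiles <- function(n_per_class = 20L, n_classes = 3L,
                                      length_range = c(40L, 60L),
                                      conservation = 0.9, seed = 1L,
                                      motif_length = 8L) {
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (motif_length < 1L || motif_length > length_range[1])
    stop("motif_length must be in [1, Lmin]", call. = FALSE)
  with_seed(seed, {
    classes <- sprintf("class%02d", seq_len(n_classes))
    motifs <- vapply(classes, function(cl)
      paste(sample(AMINO_ACIDS, motif_length, replace = TRUE), collapse = ""),
      character(1))
    profiles <- list()
    labels <- character(0)
    for (ci in seq_len(n_classes)) {
      motif_res <- match(strsplit(motifs[ci], "")[[1]], AMINO_ACIDS)
      for (j in seq_len(n_per_class)) {
        L <- length_range[1] +
          sample.int(length_range[2] - length_range[1] + 1L, 1L) - 1L
        scores <- synth_position(L, conservation)
        at <- sample.int(L - motif_length + 1L, 1L)
        idx <- at:(at + motif_length - 1L)
        scores[idx, ] <- 10 + stats::runif(motif_length * 20L, 0, 2)
        scores[cbind(idx, motif_res)] <- stats::runif(motif_length, 0, 0.5)
        id <- sprintf("%s_p%03d", classes[ci], j)
        profiles[[length(profiles) + 1L]] <- new_profile(id, scores)
        labels[id] <- classes[ci]
      }
    }
    list(profiles = profiles, labels = labels, motifs = motifs)
  })
}

#' Read a two-column label file
#'
#' Format: `id<TAB>class`, one row per profile, no header.
#'
#' @param path Path to the TSV label file.
#' @return Named character vector mapping profile id to class name.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", quote = "",
                         comment.char = "#")
  if (ncol(d) != 2L)
    stop("label file must have exactly two tab-separated columns",
         call. = FALSE)
  dup <- unique(d[[1]][duplicated(d[[1]])])
  if (length(dup))
    stop("duplicate id(s) in label file: ", paste(dup, collapse = ", "),
         call. = FALSE)
  stats::setNames(d[[2]], d[[1]])
}

#' Write a two-column label file
#'
#' @param labels Named character vector id -> class.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), class = unname(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
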