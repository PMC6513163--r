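# Feature encoding of regions and whole proteins.
#
# Four spaces: KMER (overlapping k-residue substrings of the region
# sequence), KEY (words tokenized from assigned feature descriptions), IPR
# (InterPro entry IDs), SIG (member-database signature IDs, including
# unintegrated entries).  Count matrices are TF-IDF weighted and
# L2-row-normalized so that the dot product of two rows is their cosine
# similarity; the kernel keeps only pairs at or above the 95th percentile of
# a sampled null of pairwise similarities.

FEATURE_SPACES <- c("KMER", "KEY", "IPR", "SIG")

#' Count overlapping k-mers of a sequence
#'
#' `"ABCDE"` with `k = 3` yields `ABC`, `BCD`, `CDE`.  Sequences shorter
#' than `k` yield an empty count vector.
#'
#' @param sequence Character scalar (amino-acid string).
#' @param k K-mer length (default 3).
#' @return Named integer vector of k-mer counts.
#' @export
extract_kmers <- function(sequence, k = 3L) {
  .assert(.is_count(k), "k must be a positive integer")
  n <- nchar(sequence)
  if (n < k) return(integer())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  tab <- table(kmers)
  setNames(as.integer(tab), names(tab))
}

#' Tokenize feature descriptions into keyword counts
#'
#' Splits each description on runs of non-alphanumeric characters,
#' lower-cases the tokens (configurable) and drops empties; counts are
#' aggregated over all descriptions.  `"WD repeat-containing"` yields
#' `wd`, `repeat`, `containing`.
#'
#' @param descriptions Character vector of free-text descriptions.
#' @param lowercase Case-fold tokens (default TRUE).
#' @return Named integer vector of token counts.
#' @export
extract_keywords <- function(descriptions, lowercase = TRUE) {
  if (length(descriptions) == 0L) return(integer())
  toks <- unlist(strsplit(descriptions, "[^A-Za-z0-9]+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  if (lowercase) toks <- tolower(toks)
  if (length(toks) == 0L) return(integer())
  tab <- table(toks)
  setNames(as.integer(tab), names(tab))
}

#' Extract assigned IDs of a region as 0/1 counts
#'
#' At the `interpro` level, the unique InterPro entry IDs among the region's
#' assigned annotations; at the `signature` level, the unique member-database
#' signature IDs, which include unintegrated entries such as signal-peptide
#' and transmembrane predictions.  Duplicate assignments count once (set
#' semantics).
#'
#' @param features Annotation data.frame assigned to one region
#'   (an element of `region_set$features`).
#' @param level `"interpro"` or `"signature"`.
#' @return Named integer vector of 0/1 counts.
#' @export
extract_ids <- function(features, level = c("interpro", "signature")) {
  level <- match.arg(level)
  if (is.null(features) || nrow(features) == 0L) return(integer())
  ids <- if (level == "interpro") {
    unique(features$interpro_id[!is.na(features$interpro_id) &
                                  nzchar(features$interpro_id)])
  } else {
    unique(features$entry_id[nzchar(features$entry_id)])
  }
  setNames(rep(1L, length(ids)), ids)
}

#' Feature counts for every region of a region set in one space
#'
#' @param region_set A `region_set` with features assigned
#'   (see [assign_features_to_regions()]).
#' @param space One of `"KMER"`, `"KEY"`, `"IPR"`, `"SIG"`.
#' @param k K-mer length for the KMER space.
#' @return Named list (by `region_id`) of named count vectors.
#' @export
region_counts <- function(region_set, space = FEATURE_SPACES, k = 3L) {
  space <- match.arg(space)
  reg <- region_set$regions
  out <- setNames(vector("list", nrow(reg)), reg$region_id)
  for (i in seq_len(nrow(reg))) {
    rid <- reg$region_id[i]
    out[[rid]] <- switch(
      space,
      KMER = extract_kmers(substr(region_set$protein$sequence,
                                  reg$start[i], reg$end[i]), k = k),
      KEY = extract_keywords(region_set$features[[rid]]$description),
      IPR = extract_ids(region_set$features[[rid]], "interpro"),
      SIG = extract_ids(region_set$features[[rid]], "signature")
    )
  }
  out
}

#' Whole-protein feature counts
#'
#' The baseline representation: all features found within the regions plus
#' those that span multiple regions (annotations failing the 75%
#' single-region overlap rule).  K-mers are computed on the full sequence,
#' so junction k-mers crossing region boundaries are included.
#'
#' @inheritParams region_counts
#' @return A single named count vector.
#' @export
protein_feature_vector <- function(region_set, space = FEATURE_SPACES, k = 3L) {
  space <- match.arg(space)
  if (space == "KMER") {
    return(extract_kmers(region_set$protein$sequence, k = k))
  }
  parts <- region_counts(region_set, space = space, k = k)
  span <- region_set$spanners
  extra <- switch(space,
    KEY = extract_keywords(span$description),
    IPR = extract_ids(span, "interpro"),
    SIG = extract_ids(span, "signature")
  )
  merged <- c(parts, list(extra))
  all_names <- unique(unlist(lapply(merged, names), use.names = FALSE))
  if (length(all_names) == 0L) return(integer())
  acc <- setNames(numeric(length(all_names)), all_names)
  for (v in merged) if (length(v)) acc[names(v)] <- acc[names(v)] + v
  if (space %in% c("IPR", "SIG")) acc <- pmin(acc, 1)  # set semantics
  acc
}

#' Assemble a sparse count matrix from per-item count vectors
#'
#' @param counts Named list of named numeric count vectors (one per item).
#' @param vocabulary Optional fixed vocabulary; features outside it are
#'   dropped, absent ones become zero columns.
#' @return A sparse `dgCMatrix` (items x vocabulary) with dimnames.
#' @export
count_matrix <- function(counts, vocabulary = NULL) {
  items <- names(counts)
  .assert(!is.null(items) && all(nzchar(items)), "counts must be a named list")
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  }
  i <- integer(); j <- integer(); x <- numeric()
  for (idx in seq_along(counts)) {
    v <- counts[[idx]]
    if (length(v) == 0L) next
    pos <- match(names(v), vocabulary)
    keep <- !is.na(pos)
    i <- c(i, rep(idx, sum(keep)))
    j <- c(j, pos[keep])
    x <- c(x, as.numeric(v[keep]))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(counts), length(vocabulary)),
                       dimnames = list(items, vocabulary))
}

#' Fit a TF-IDF weighting and transform the count matrix
#'
#' Weights are `count * idf` with the smoothed inverse document frequency
#' `idf(f) = ln((1 + N) / (1 + df(f))) + 1` (N items, df items containing
#' f), after which rows are L2-normalized, so the dot product of two rows is
#' their cosine similarity.  The vocabulary and idf are fixed at fit time
#' and reused by [tfidf_transform()]; unseen features in new items are
#' dropped.
#'
#' @param counts Named list of count vectors, or a sparse count matrix from
#'   [count_matrix()].
#' @param space Which feature space the matrix encodes (metadata).
#' @return An object of class `feature_matrix`: list with `space`,
#'   `item_ids`, `vocabulary`, `idf`, `weights` (sparse, L2-row-normalized)
#'   and `row_norm = TRUE`.
#' @export
tfidf_fit_transform <- function(counts, space = "KEY") {
  M <- if (is(counts, "Matrix")) counts else count_matrix(counts)
  .assert(sum(M) > 0, "all-zero count input: nothing to weight")
  N <- nrow(M)
  df <- Matrix::colSums(M > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  fm <- structure(list(space = space, item_ids = rownames(M),
                       vocabulary = colnames(M), idf = idf),
                  class = "feature_matrix")
  fm$weights <- .apply_tfidf(M, idf)
  fm$row_norm <- TRUE
  fm
}

.apply_tfidf <- function(M, idf) {
  W <- M %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(W^2))
  scale <- ifelse(norms > 0, 1 / norms, 0)
  W <- Matrix::Diagonal(x = scale) %*% W
  W <- as(as(W, "generalMatrix"), "CsparseMatrix")
  dimnames(W) <- dimnames(M)
  W
}

#' Transform new items with a fitted TF-IDF weighting
#'
#' @param fm A `feature_matrix` from [tfidf_fit_transform()].
#' @param counts Named list of count vectors for the new items; features
#'   outside the fitted vocabulary are dropped.
#' @return A sparse L2-row-normalized matrix over the fitted vocabulary.
#' @export
tfidf_transform <- function(fm, counts) {
  .assert(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  M <- if (is(counts, "Matrix")) counts else count_matrix(counts, fm$vocabulary)
  .assert(identical(colnames(M), fm$vocabulary), "vocabulary mismatch")
  .apply_tfidf(M, fm$idf)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d items x %d features (%.2f%% nonzero)\n",
              x$space, nrow(x$weights), ncol(x$weights),
              100 * Matrix::nnzero(x$weights) /
                max(1, prod(dim(x$weights)))))
  invisible(x)
}

#' Build the thresholded cosine-similarity kernel
#'
#' The threshold is the 95th percentile (configurable) of the off-diagonal
#' pairwise cosine similarities among up to `sample_size` items sampled
#' without replacement (zero similarities included in the percentile).
#' Kernel entries below the threshold are set to 0; the diagonal is kept at
#' 1 for items with a nonzero feature vector.
#'
#' @param fm A `feature_matrix` (rows must be L2-normalized).
#' @param percentile Percentile cutoff in (0, 100), default 95.
#' @param sample_size Number of items sampled for the percentile, default
#'   10000.
#' @param seed Integer seed for the sampling.
#' @return An object of class `similarity_kernel`: list with `space`,
#'   `threshold`, `item_ids` and `values` (sparse symmetric matrix).
#' @export
build_kernel <- function(fm, percentile = 95, sample_size = 10000L, seed = 1L) {
  .assert(inherits(fm, "feature_matrix") && isTRUE(fm$row_norm),
          "fm must be an L2-row-normalized feature_matrix")
  W <- fm$weights
  n <- nrow(W)
  .assert(n >= 2L, "need at least 2 items to build a kernel")

  m <- min(n, as.integer(sample_size))
  idx <- .with_seed(.derive_seed(seed, 1L), sample.int(n, m))
  S <- Matrix::tcrossprod(W[idx, , drop = FALSE])
  S <- as(as(S, "generalMatrix"), "CsparseMatrix")
  offdiag <- S
  Matrix::diag(offdiag) <- 0
  offdiag <- Matrix::drop0(offdiag)
  nz <- offdiag@x
  n_zero <- m * (m - 1) - length(nz)  # structural zeros count toward the percentile
  threshold <- .quantile_with_zeros(nz, n_zero, percentile / 100)

  K <- Matrix::tcrossprod(W)
  K <- as(as(K, "generalMatrix"), "CsparseMatrix")
  K@x[K@x < threshold] <- 0
  K <- Matrix::drop0(K)
  nonzero_row <- Matrix::rowSums(W^2) > 0
  Matrix::diag(K) <- as.numeric(nonzero_row)
  dimnames(K) <- list(fm$item_ids, fm$item_ids)
  structure(list(space = fm$space, threshold = threshold,
                 item_ids = fm$item_ids, values = K),
            class = "similarity_kernel")
}

#' @export
print.similarity_kernel <- function(x, ...) {
  n <- length(x$item_ids)
  off <- Matrix::nnzero(x$values) - sum(Matrix::diag(x$values) > 0)
  cat(sprintf(
    "similarity_kernel [%s]: %d items, threshold %.4f, %.2f%% off-diagonal nonzero\n",
    x$space, n, x$threshold, 100 * off / max(1, n * (n - 1))))
  invisible(x)
}

#' Persist a feature matrix as MatrixMarket plus sidecar text files
#'
#' Writes `<stem>.mtx` (weights), `<stem>.items.txt`, `<stem>.vocab.txt`
#' and `<stem>.idf.txt`.
#'
#' @param fm A `feature_matrix`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_feature_matrix <- function(fm, stem) {
  Matrix::writeMM(fm$weights, paste0(stem, ".mtx"))
  writeLines(fm$item_ids, paste0(stem, ".items.txt"))
  writeLines(fm$vocabulary, paste0(stem, ".vocab.txt"))
  writeLines(format(fm$idf, digits = 17), paste0(stem, ".idf.txt"))
  invisible(stem)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param stem Path stem used when writing.
#' @param space Feature-space tag to record.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(stem, space = "KEY") {
  W <- as(as(Matrix::readMM(paste0(stem, ".mtx")), "generalMatrix"),
          "CsparseMatrix")
  items <- readLines(paste0(stem, ".items.txt"))
  vocab <- readLines(paste0(stem, ".vocab.txt"))
  idf <- as.numeric(readLines(paste0(stem, ".idf.txt")))
  dimnames(W) <- list(items, vocab)
  structure(list(space = space, item_ids = items, vocabulary = vocab,
                 idf = setNames(idf, vocab), weights = W, row_norm = TRUE),
            class = "feature_matrix")
}
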