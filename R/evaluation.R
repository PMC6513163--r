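# Region- and protein-level evaluation: AUPR (average precision),
# bootstrap, paired Wilcoxon signed rank, F1-max positive calling,
# structure-derived region binding labels, and the sequence-identity
# baseline.

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: walking the items in decreasing score
#' order, each positive contributes the precision at its recall step.
#' Tied scores are grouped — precision is computed after including the
#' whole tie group — so the value is invariant to the ordering within
#' ties and to strictly monotone transformations of the scores.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 (or logical) vector, same length; both classes must
#'   be present.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  .assert(length(scores) == length(labels), "scores/labels length mismatch")
  P <- sum(labels)
  .assert(P >= 1L && P < length(labels),
          "AUPR needs at least one positive and one negative")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))          # tie groups in rank order
  tp_g <- tapply(y, grp, sum)            # positives per tie group
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  cum_tp <- cumsum(tp_g)
  cum_n <- cumsum(n_g)
  prec <- cum_tp / cum_n                 # precision after the whole group
  sum(tp_g * prec) / P
}

#' Bootstrap the AUPR
#'
#' Resamples evaluation items with replacement `n_boot` times.  The
#' resample indices are generated once from `seed`, so two methods
#' evaluated over the same items with the same seed share resamples and
#' their bootstrap vectors are paired.  Resamples containing a single
#' class are redrawn.
#'
#' @inheritParams aupr
#' @param n_boot Number of bootstrap rounds (default 1000).
#' @param seed Integer seed for the resampling.
#' @param go_id,method Metadata recorded on the result.
#' @return An object of class `eval_result`: list with `go_id`, `method`,
#'   `point` (plug-in AUPR), `boot` (length-`n_boot` vector), `n_boot`,
#'   `seed`.
#' @export
bootstrap_aupr <- function(scores, labels, n_boot = 1000L, seed = 1L,
                           go_id = NA_character_, method = NA_character_) {
  labels <- as.integer(as.logical(labels))
  point <- aupr(scores, labels)
  n <- length(scores)
  boot <- numeric(n_boot)
  .with_seed(.derive_seed(seed, 101L), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(labels[idx]) %in% c(0L, n)) next  # single class: redraw
        break
      }
      boot[b] <- aupr(scores[idx], labels[idx])
    }
  })
  structure(list(go_id = go_id, method = method, point = point,
                 boot = boot, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result [%s, %s]: AUPR %.4f (bootstrap median %.4f, n=%d)\n",
              x$go_id, x$method, x$point, median(x$boot), x$n_boot))
  invisible(x)
}

#' Two-tailed Wilcoxon signed rank test
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midrank ties.  For 25 or fewer nonzero differences without ties the
#' exact signed-rank distribution is used; otherwise a normal
#' approximation with tie correction and continuity correction.  All
#' differences zero gives p = 1.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Two-tailed p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  .assert(length(a) == length(b), "paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1.0)
  r <- rank(abs(d))  # midranks for ties
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25L) {
    # exact: psignrank gives the null CDF of W+
    p_low <- psignrank(W, n)
    p_high <- psignrank(W - 1, n, lower.tail = FALSE)
    return(min(1, 2 * min(p_low, p_high)))
  }
  mu <- n * (n + 1) / 4
  tie_sizes <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_sizes^3 - tie_sizes) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Threshold maximizing the F1 score
#'
#' Scans every distinct score as a candidate threshold (items scoring
#' strictly above... no: at or above the threshold are called positive)
#' and returns the threshold with maximal F1; ties go to the smaller
#' (more sensitive) threshold.
#'
#' @inheritParams aupr
#' @return A list with `threshold` and `f1`.
#' @export
f1max_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  P <- sum(labels)
  .assert(P >= 1L, "F1 needs at least one positive")
  cand <- sort(unique(scores))
  best_t <- cand[1]; best_f1 <- -1
  for (t in cand) {
    call_pos <- scores >= t
    tp <- sum(call_pos & labels == 1L)
    fp <- sum(call_pos & labels == 0L)
    f1 <- if (tp == 0L) 0 else 2 * tp / (2 * tp + fp + (P - tp))
    if (f1 > best_f1 + 1e-15) {  # strict improvement; ties keep smaller t
      best_f1 <- f1
      best_t <- t
    }
  }
  list(threshold = best_t, f1 = best_f1)
}

#' Label regions as ligand-binding from residue contact records
#'
#' A region is positive when strictly more than `min_residues` of its
#' residues lie within `cutoff` angstroms of the ligand; regions with less
#' than `min_coverage` of their residues structurally covered are excluded
#' from evaluation altogether.
#'
#' @param region_set A `region_set` (see [build_regions()]).
#' @param contacts Contact data.frame with columns `protein_accession`,
#'   `residue`, `min_distance`, `ligand_class`, `covered` (see
#'   [read_contacts()]); residues absent from the table are treated as not
#'   covered and infinitely far from the ligand.
#' @param cutoff Contact distance cutoff in angstroms (default 6).
#' @param min_residues Positive call requires strictly more than this many
#'   contact residues (default 3).
#' @param min_coverage Minimum structurally covered fraction (default 0.8).
#' @return Data.frame with `region_id`, `n_contact`, `coverage`, `status`
#'   (`"positive"`, `"negative"` or `"excluded"`).
#' @export
label_binding_regions <- function(region_set, contacts, cutoff = 6.0,
                                  min_residues = 3L, min_coverage = 0.8) {
  acc <- region_set$protein$accession
  ct <- contacts[contacts$protein_accession == acc, , drop = FALSE]
  reg <- region_set$regions
  out <- data.frame(region_id = reg$region_id, n_contact = 0L,
                    coverage = 0, status = "negative",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(reg))) {
    len <- reg$end[i] - reg$start[i] + 1L
    in_reg <- ct$residue >= reg$start[i] & ct$residue <= reg$end[i]
    cov <- sum(in_reg & ct$covered) / len
    ncontact <- sum(in_reg & ct$covered & ct$min_distance <= cutoff)
    out$n_contact[i] <- ncontact
    out$coverage[i] <- cov
    out$status[i] <- if (cov < min_coverage) "excluded"
      else if (ncontact > min_residues) "positive" else "negative"
  }
  out
}

#' Read per-residue ligand contact records
#'
#' TSV columns: accession, residue (1-based), min distance to ligand in
#' angstroms, ligand class (DNA, RNA, MG, ZN, other), covered (0/1).
#'
#' @param path Path to the TSV (plain or gzip-compressed; a header line is
#'   detected and skipped).
#' @return A data.frame with columns `protein_accession`, `residue`,
#'   `min_distance`, `ligand_class`, `covered`.
#' @export
read_contacts <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("accession", first, fixed = TRUE)
  raw <- read.delim(path, header = header, stringsAsFactors = FALSE)
  .assert(ncol(raw) == 5L, "expected 5 contact columns in %s", path)
  names(raw) <- c("protein_accession", "residue", "min_distance",
                  "ligand_class", "covered")
  raw$residue <- as.integer(raw$residue)
  raw$min_distance <- as.numeric(raw$min_distance)
  raw$covered <- as.logical(as.integer(raw$covered))
  .assert(all(raw$min_distance >= 0), "negative contact distance in %s", path)
  raw
}

#' Write contact records in the TSV dialect read by [read_contacts()]
#'
#' @param contacts Contact data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  out <- contacts
  out$covered <- as.integer(out$covered)
  names(out) <- c("accession", "residue", "min_distance", "ligand_class",
                  "covered")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Maximum pairwise sequence-identity baseline
#'
#' The CAFA-style identity baseline: the prediction score of a query is
#' the maximum, over positively labelled templates, of global-alignment
#' identity (matches / alignment length, Needleman-Wunsch with match 1,
#' mismatch 0, gap -1 per residue).
#'
#' @param query_sequence Amino-acid string.
#' @param templates Data.frame with `sequence` and `label` columns; at
#'   least one row must have `label == 1`.
#' @return Identity score in `[0, 1]`.
#' @export
identity_baseline <- function(query_sequence, templates) {
  pos <- templates$sequence[templates$label == 1]
  .assert(length(pos) >= 1L, "identity baseline needs a positive template")
  sub_mat <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sub_mat) <- 1
  best <- 0
  for (tmpl in pos) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query_sequence), Biostrings::AAString(tmpl),
      type = "global", substitutionMatrix = sub_mat,
      gapOpening = 0, gapExtension = 1)
    ident <- Biostrings::nmatch(aln) /
      nchar(as.character(Biostrings::alignedPattern(aln)))
    best <- max(best, ident)
  }
  best
}

#' Import BLAST tabular output (outfmt 6) for parity runs
#'
#' @param path Path to a `-outfmt 6` file.
#' @return Data.frame with `query`, `subject`, `identity` (fractional) and
#'   the remaining standard columns.
#' @export
read_blast_outfmt6 <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(raw) >= 12L, "expected 12 outfmt-6 columns in %s", path)
  names(raw)[1:12] <- c("query", "subject", "identity", "length",
                        "mismatch", "gapopen", "qstart", "qend",
                        "sstart", "send", "evalue", "bitscore")
  raw$identity <- raw$identity / 100
  raw
}

#' Compare two paired bootstrap results
#'
#' Sign convention: `result_a` is the region-specific method and
#' `result_b` the baseline, so a positive difference of bootstrap median
#' AUPRs means the region-specific method outperforms the baseline.  The
#' p-value is a two-tailed Wilcoxon signed rank test over the paired
#' bootstrap vectors.
#'
#' @param result_a,result_b `eval_result` objects produced with the same
#'   seed and number of rounds (paired resamples).
#' @return A list with `delta_median` and `p_value`.
#' @export
compare_methods <- function(result_a, result_b) {
  .assert(result_a$n_boot == result_b$n_boot && result_a$seed == result_b$seed,
          "results are not paired (different seeds or bootstrap rounds)")
  list(delta_median = median(result_a$boot) - median(result_b$boot),
       p_value = wilcoxon_signed_rank(result_a$boot, result_b$boot))
}
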