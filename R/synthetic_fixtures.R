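# Seeded synthetic corpora with the statistical structure the method
# assumes: proteins made of 1-6 tiling regions, sparse 0/1 region features,
# one planted region-specific function, protein labels as the OR of region
# labels, and contact records that let the structure-based evaluation
# recover the planted regions.
#
# The construction deliberately confounds the whole-protein baseline:
# every region of a positive protein carries "context" tokens that also
# occur (at a lower rate) in negative proteins.  A protein-level learner
# cannot tell the causal token from the context tokens that co-occur with
# it in the same protein vector, while the group-instance objective can,
# because negative proteins containing context tokens push their scores
# down.  Background tokens are drawn with Zipf-like frequencies so TF-IDF
# has a realistic dynamic range.

#' Parameters of a synthetic corpus
#'
#' Regions per protein follow a shifted Poisson (1 + Poisson(2), mean 3)
#' truncated to at most 6; region lengths are uniform on 25-400 residues so
#' no generated region triggers the 18/20-residue boundary rules.
#'
#' @param n_proteins Number of proteins (>= 4).
#' @param regions_lambda Poisson rate of the shifted region-count
#'   distribution (default 2, giving mean ~3 regions per protein).
#' @param vocab_size Total vocabulary size (causal + context + background).
#' @param causal_feature Name of the planted causal token.
#' @param positive_fraction Fraction of proteins carrying the planted
#'   function, in (0, 1).
#' @param label_noise Per-region label flip probability, in `[0, 0.5)`.
#' @param feature_noise_per_region Background tokens per region: either a
#'   single count or a `c(min, max)` range sampled uniformly per region
#'   (default 5-25).  Regions differ widely in annotation richness in real
#'   data, and this variability is what gives the whole-protein baseline
#'   its characteristic region-level errors.
#' @param n_context,context_per_region,context_rate_negative Size of the
#'   context-token pool, context tokens per positive-protein region, and
#'   the probability that a negative-protein region carries one context
#'   token.
#' @param n_family_pos,n_family_neg Sizes of the family-token pools for
#'   positive and negative proteins.  Every protein carries one family
#'   annotation spanning all its regions; in multi-region proteins it
#'   fails the 75% single-region overlap rule and so reaches only the
#'   whole-protein feature vector, emulating the protein-family spanners
#'   that handicap the whole-protein baseline at region level.
#' @param region_len_range Uniform region-length range in residues.
#' @param seed Integer master seed; the corpus is fully determined by it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 200L, regions_lambda = 2,
                           vocab_size = 500L, causal_feature = "CAUSAL",
                           positive_fraction = 0.4, label_noise = 0.05,
                           feature_noise_per_region = c(5L, 25L),
                           n_context = 20L, context_per_region = 2L,
                           context_rate_negative = 0.3,
                           n_family_pos = 3L, n_family_neg = 12L,
                           region_len_range = c(25L, 400L), seed = 1L) {
  .assert(n_proteins >= 4L, "need at least 4 proteins")
  .assert(positive_fraction > 0 && positive_fraction < 1,
          "positive_fraction must be in (0, 1)")
  .assert(label_noise >= 0 && label_noise < 0.5,
          "label_noise must be in [0, 0.5)")
  n_pos <- round(n_proteins * positive_fraction)
  .assert(n_pos >= 1L && n_pos <= n_proteins - 1L,
          "infeasible spec: positive_fraction leaves no positives or no negatives")
  if (length(feature_noise_per_region) == 1L) {
    feature_noise_per_region <- rep(feature_noise_per_region, 2L)
  }
  .assert(vocab_size > n_context + 1L + max(feature_noise_per_region),
          "vocabulary too small for the requested token pools")
  structure(list(n_proteins = as.integer(n_proteins),
                 regions_lambda = regions_lambda,
                 vocab_size = as.integer(vocab_size),
                 causal_feature = causal_feature,
                 positive_fraction = positive_fraction,
                 label_noise = label_noise,
                 feature_noise_per_region =
                   as.integer(feature_noise_per_region),
                 n_context = as.integer(n_context),
                 context_per_region = as.integer(context_per_region),
                 context_rate_negative = context_rate_negative,
                 n_family_pos = as.integer(n_family_pos),
                 n_family_neg = as.integer(n_family_neg),
                 region_len_range = as.integer(region_len_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a synthetic corpus
#'
#' Each positive protein gets exactly one region carrying the causal
#' token.  The true region label is 1 iff the region carries it; the
#' hidden (training) region label flips the true label with probability
#' `label_noise`, and the protein training label is the OR of the hidden
#' region labels, so at zero noise protein labels are exactly the OR of
#' region labels (the max-aggregation assumption).  Contact records place
#' five sub-6-angstrom residues, with full structural coverage, in every
#' true causal region, so the structure-based evaluation recovers the
#' planted truth independently of the annotation noise.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_corpus` with elements `spec`,
#'   `proteins`, `annotations`, `region_sets` (regions rebuilt through
#'   [build_regions()] and features assigned), `counts` (named list:
#'   region id to 0/1 token counts), `vocabulary`, `protein_labels`
#'   (hidden, for training), `protein_labels_true`, `region_labels`
#'   (hidden) and `region_labels_true` (named by region id), and
#'   `contacts`.
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  .assert(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  n_bg <- spec$vocab_size - 1L - spec$n_context -
    spec$n_family_pos - spec$n_family_neg
  .assert(n_bg >= max(spec$feature_noise_per_region),
          "vocabulary too small for the requested token pools")
  context_pool <- sprintf("CTX%03d", seq_len(spec$n_context))
  fam_pos_pool <- sprintf("FAMP%03d", seq_len(spec$n_family_pos))
  fam_neg_pool <- sprintf("FAMN%03d", seq_len(spec$n_family_neg))
  bg_pool <- sprintf("BG%04d", seq_len(n_bg))
  vocabulary <- c(spec$causal_feature, context_pool, fam_pos_pool,
                  fam_neg_pool, bg_pool)
  zipf <- (1 / seq_len(n_bg)); zipf <- zipf / sum(zipf)

  .with_seed(.derive_seed(spec$seed, 1L), {
    n <- spec$n_proteins
    n_pos <- round(n * spec$positive_fraction)
    is_pos <- rep(c(TRUE, FALSE), c(n_pos, n - n_pos))[sample.int(n)]
    acc <- sprintf("SYN%05d", seq_len(n))

    proteins <- vector("list", n)
    ann_rows <- vector("list", n)
    counts <- list()
    spanner_counts <- list()
    y_true <- numeric(0)
    contact_rows <- vector("list", n)

    for (p in seq_len(n)) {
      repeat {
        n_reg <- 1L + rpois(1L, spec$regions_lambda)
        if (n_reg <= 6L) break
      }
      lens <- sample(seq(spec$region_len_range[1], spec$region_len_range[2]),
                     n_reg, replace = TRUE)
      ends <- cumsum(lens)
      starts <- c(1L, head(ends, -1L) + 1L)
      L <- ends[n_reg]
      seqs <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
      proteins[[p]] <- data.frame(accession = acc[p], sequence = seqs,
                                  length = L, stringsAsFactors = FALSE)
      causal_at <- if (is_pos[p]) sample.int(n_reg, 1L) else 0L

      tok_by_reg <- vector("list", n_reg)
      for (r in seq_len(n_reg)) {
        n_bg_reg <- sample(
          seq(spec$feature_noise_per_region[1],
              spec$feature_noise_per_region[2]), 1L)
        toks <- sample(bg_pool, n_bg_reg, prob = zipf)
        if (is_pos[p]) {
          toks <- c(toks, sample(context_pool, spec$context_per_region))
          if (r == causal_at) toks <- c(toks, spec$causal_feature)
        } else if (runif(1) < spec$context_rate_negative) {
          toks <- c(toks, sample(context_pool, 1L))
        }
        tok_by_reg[[r]] <- unique(toks)
      }

      # one family token per protein, label-correlated pool; it spans all
      # regions, so in multi-region proteins it reaches only the protein
      # vector (spanner), while in single-region proteins the 75% rule
      # assigns it to the lone region
      fam <- if (is_pos[p]) sample(fam_pos_pool, 1L)
        else sample(fam_neg_pool, 1L)
      if (n_reg == 1L) {
        tok_by_reg[[1L]] <- unique(c(tok_by_reg[[1L]], fam))
      } else {
        spanner_counts[[acc[p]]] <- setNames(1L, fam)
      }

      rid <- paste0(acc[p], ":", seq_len(n_reg))
      for (r in seq_len(n_reg)) {
        counts[[rid[r]]] <- setNames(rep(1L, length(tok_by_reg[[r]])),
                                     tok_by_reg[[r]])
      }
      y_true <- c(y_true, setNames(as.numeric(seq_len(n_reg) == causal_at), rid))

      # one Domain row per region (shared ID so TF-IDF downweights it) plus
      # one unintegrated-signature row per token; both survive the builder
      dom <- data.frame(protein_accession = acc[p], source_db = "SYNSCAN",
                        entry_type = "Domain", entry_id = "SYNDOM0001",
                        interpro_id = "IPR999999",
                        description = "synthetic domain",
                        start = starts, end = ends, stringsAsFactors = FALSE)
      tok_n <- lengths(tok_by_reg)
      sig <- data.frame(protein_accession = acc[p], source_db = "SYNDB",
                        entry_type = "UnintegratedSignature",
                        entry_id = unlist(tok_by_reg),
                        interpro_id = NA_character_,
                        description = unlist(tok_by_reg),
                        start = rep(starts, tok_n), end = rep(ends, tok_n),
                        stringsAsFactors = FALSE)
      famrow <- data.frame(protein_accession = acc[p], source_db = "SYNDB",
                           entry_type = "Family", entry_id = fam,
                           interpro_id = NA_character_, description = fam,
                           start = 1L, end = L, stringsAsFactors = FALSE)
      ann_rows[[p]] <- rbind(dom, famrow, sig)

      # contacts: full coverage; causal regions get 5 residues inside 6 A
      dist <- runif(L, 8, 30)
      if (causal_at > 0L) {
        near <- starts[causal_at] +
          sample.int(lens[causal_at], 5L) - 1L
        dist[near] <- runif(5L, 2, 5.5)
      }
      contact_rows[[p]] <- data.frame(
        protein_accession = acc[p], residue = seq_len(L),
        min_distance = dist, ligand_class = "DNA", covered = TRUE,
        stringsAsFactors = FALSE)
    }

    proteins <- do.call(rbind, proteins)
    annotations <- do.call(rbind, ann_rows)
    contacts <- do.call(rbind, contact_rows)

    # annotation noise is incompleteness: a true causal region loses its
    # label with probability label_noise (missed annotation); negatives
    # are never spuriously annotated (open-world convention)
    flip <- runif(length(y_true)) < spec$label_noise
    y_hidden <- ifelse(flip & y_true == 1, 0, y_true)
    names(y_hidden) <- names(y_true)
    prot_of_region <- sub(":\\d+$", "", names(y_true))
    Y_true <- tapply(y_true, prot_of_region, max)[acc]
    Y_hidden <- tapply(y_hidden, prot_of_region, max)[acc]

    region_sets <- build_regions_all(proteins, annotations)
    region_sets <- lapply(region_sets, assign_features_to_regions, annotations)

    structure(list(spec = spec, proteins = proteins,
                   annotations = annotations, region_sets = region_sets,
                   counts = counts, spanner_counts = spanner_counts,
                   vocabulary = vocabulary,
                   protein_labels = setNames(as.numeric(Y_hidden), acc),
                   protein_labels_true = setNames(as.numeric(Y_true), acc),
                   region_labels = y_hidden, region_labels_true = y_true,
                   contacts = contacts),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "synthetic_corpus: %d proteins, %d regions, %d positive proteins (seed %d)\n",
    nrow(x$proteins), length(x$counts), sum(x$protein_labels_true),
    x$spec$seed))
  invisible(x)
}

#' Write a synthetic corpus in the standard file formats
#'
#' Emits `proteins.fasta`, `annotations.tsv` (InterProScan dialect),
#' `annotations.gaf` (hidden protein labels for `go_id`, plus a second
#' term annotating every protein so negatives have a non-empty record) and
#' `contacts.tsv` — exactly the formats the io readers consume.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @param go_id GO identifier used for the planted function.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir, go_id = "GO:0003677") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             tsv = file.path(dir, "annotations.tsv"),
             gaf = file.path(dir, "annotations.gaf"),
             contacts = file.path(dir, "contacts.tsv"))
  write_fasta(corpus$proteins, paths[["fasta"]])
  write_interproscan_tsv(corpus$annotations, paths[["tsv"]])
  acc <- corpus$proteins$accession
  pos <- acc[corpus$protein_labels[acc] == 1]
  gaf <- data.frame(
    protein_accession = c(pos, acc),
    go_id = rep(c(go_id, "GO:0099999"), c(length(pos), length(acc))),
    evidence_code = "IDA", qualifier = "", negated = FALSE,
    release_tag = "old", stringsAsFactors = FALSE)
  write_gaf(gaf, paths[["gaf"]])
  write_contacts(corpus$contacts, paths[["contacts"]])
  invisible(paths)
}

#' The worked 511-residue two-domain example fixture
#'
#' A synthetic stand-in for the BAIAP2L1 processing example: a 511-residue
#' sequence with an IMD/I-BAR-like domain at residues 1-249 and an
#' SH3-like domain at residues 339-402.  Running [build_regions()] on it
#' yields four regions: 1-249, 250-338, 339-402 and 403-511.
#'
#' @param dir Optional directory; when given, `example.fasta` and
#'   `example.tsv` are written there.
#' @return List with `proteins` and `annotations` data.frames (and
#'   `paths` when `dir` was given).
#' @export
generate_annotation_fixture <- function(dir = NULL) {
  seqs <- .with_seed(424243L,
                     paste(sample(AA_ALPHABET, 511L, replace = TRUE),
                           collapse = ""))
  proteins <- data.frame(accession = "Q9UHR4", sequence = seqs,
                         length = 511L, stringsAsFactors = FALSE)
  annotations <- data.frame(
    protein_accession = "Q9UHR4",
    source_db = c("PFAM", "PFAM"),
    entry_type = "Domain",
    entry_id = c("PF08397", "PF14604"),
    interpro_id = c("IPR013606", "IPR001452"),
    description = c("IMD/I-BAR domain", "SH3 domain"),
    start = c(1L, 339L), end = c(249L, 402L),
    stringsAsFactors = FALSE)
  out <- list(proteins = proteins, annotations = annotations)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "example.fasta"),
               tsv = file.path(dir, "example.tsv"))
    x <- Biostrings::AAStringSet(seqs)
    names(x) <- "sp|Q9UHR4|BI2L1_SYNTH synthetic 511-residue example"
    Biostrings::writeXStringSet(x, paths[["fasta"]])
    write_interproscan_tsv(annotations, paths[["tsv"]])
    out$paths <- paths
  }
  out
}
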