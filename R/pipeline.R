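# Pipeline orchestration: in-memory experiment runner over a corpus, plus
# the thin file-based commands the command-line entry point wraps
# (simulate, regions, featurize, train, predict, evaluate).

#' Default run configuration
#'
#' Every under-specified constant of the method in one overridable place:
#' feature space, k-mer length, assignment overlap, kernel percentile and
#' sample size, cost-function weights, optimizer settings, bootstrap
#' rounds and seeds.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    space = "SIG", k = 3L, min_overlap = 0.75,
    kernel_percentile = 95, kernel_sample = 10000L,
    w1 = 1, w2 = 1, lam = 1,
    lam_grid = c(0.1, 1, 10, 100),
    learning_rate = 0.1, momentum = 0.9, batch_size = 32L,
    max_epochs = 200L, pair_sample = 0L, patience = 10L,
    val_fraction = 0.2, n_boot = 1000L, seed = 1L
  )
  dots <- list(...)
  .assert(all(names(dots) %in% names(cfg)),
          "unknown config field(s): %s",
          paste(setdiff(names(dots), names(cfg)), collapse = ", "))
  cfg[names(dots)] <- dots
  .assert(cfg$space %in% FEATURE_SPACES, "invalid feature space")
  .assert(cfg$min_overlap > 0 && cfg$min_overlap <= 1, "invalid min_overlap")
  .assert(cfg$kernel_percentile > 0 && cfg$kernel_percentile < 100,
          "invalid kernel percentile")
  .assert(cfg$val_fraction > 0 && cfg$val_fraction < 1, "invalid val_fraction")
  structure(cfg, class = "run_config")
}

# Deterministic short hash of a config (for output provenance).
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

# Region and whole-protein TF-IDF matrices from per-region counts.
# Regions and proteins share one vocabulary (the union of region features
# and multi-region spanner features) so theta_base applies to both; the
# idf is fit on the regions (the unit of prediction), with spanner-only
# features taking the maximal smoothed idf (document frequency zero among
# regions).
.corpus_matrices <- function(counts, region_protein, space = "SIG",
                             spanner_counts = NULL) {
  vocab <- sort(unique(c(unlist(lapply(counts, names), use.names = FALSE),
                         unlist(lapply(spanner_counts, names),
                                use.names = FALSE))))
  M_reg <- count_matrix(counts, vocab)
  fm <- tfidf_fit_transform(M_reg, space = space)
  X_regions <- add_intercept(fm$weights)
  prots <- unique(region_protein)
  agg <- Matrix::sparseMatrix(
    i = match(region_protein, prots), j = seq_along(region_protein), x = 1,
    dims = c(length(prots), length(region_protein)),
    dimnames = list(prots, NULL))
  M_prot <- agg %*% M_reg
  if (!is.null(spanner_counts)) {
    spn <- setNames(vector("list", length(prots)), prots)
    for (p in prots) spn[[p]] <- spanner_counts[[p]] %||% integer()
    M_span <- count_matrix(spn, vocab)
    M_prot <- M_prot + M_span
  }
  M_prot <- as(as(M_prot, "generalMatrix"), "CsparseMatrix")
  W_prot <- .apply_tfidf(M_prot, fm$idf)
  list(fm = fm, X_regions = X_regions, W_prot = W_prot)
}

#' Run the full region-specific experiment on a corpus
#'
#' Featurizes regions and whole proteins, builds the thresholded cosine
#' kernel, fits the whole-protein baseline (which doubles as the seed),
#' trains the group-instance model on the hidden protein labels of the
#' training split, and evaluates region-level AUPR for both methods
#' against the structure-derived region labels, with paired bootstrap and
#' Wilcoxon comparison.
#'
#' @param corpus A `synthetic_corpus` (or any list with the same fields).
#' @param config A [run_config()].
#' @param use_contacts Derive evaluation region labels from the contact
#'   records through [label_binding_regions()] (default) instead of using
#'   the generator's true region labels directly.
#' @return A list with the fitted `model`, the `baseline` seed fit, region
#'   scores and labels, `eval_region` / `eval_baseline` (`eval_result`s),
#'   their `comparison` (delta median AUPR, p-value), and protein-level
#'   AUPRs on the validation split.
#' @export
run_experiment <- function(corpus, config = run_config(),
                           use_contacts = TRUE) {
  counts <- corpus$counts
  region_ids <- names(counts)
  region_protein <- sub(":\\d+$", "", region_ids)
  mats <- .corpus_matrices(counts, region_protein, space = config$space,
                           spanner_counts = corpus$spanner_counts)
  kernel <- build_kernel(mats$fm, percentile = config$kernel_percentile,
                         sample_size = config$kernel_sample,
                         seed = .derive_seed(config$seed, 3L))

  Y <- corpus$protein_labels
  prots <- rownames(mats$W_prot)
  # stratified train/validation split of proteins
  val <- .with_seed(.derive_seed(config$seed, 5L), {
    pos <- prots[Y[prots] == 1]; neg <- prots[Y[prots] == 0]
    c(sample(pos, max(1L, round(length(pos) * config$val_fraction))),
      sample(neg, max(1L, round(length(neg) * config$val_fraction))))
  })
  train <- setdiff(prots, val)
  .assert(length(unique(Y[train])) == 2L && length(unique(Y[val])) == 2L,
          "train/validation split lost a class; corpus too small")

  base <- seed_theta(mats$W_prot[train, , drop = FALSE], Y,
                     lam_grid = config$lam_grid,
                     validation = list(X = mats$W_prot[val, , drop = FALSE],
                                       labels = Y))

  train_rows <- which(region_protein %in% train)
  val_rows <- which(region_protein %in% val)
  data <- gicf_data(mats$X_regions[train_rows, , drop = FALSE],
                    region_protein[train_rows], kernel, Y,
                    positive_regions = intersect(
                      corpus$anchor_regions %||% character(),
                      region_ids[train_rows]))
  opt <- optimizer_config(learning_rate = config$learning_rate,
                          momentum = config$momentum,
                          batch_size = config$batch_size,
                          max_epochs = config$max_epochs,
                          pair_sample = config$pair_sample,
                          early_stop_patience = config$patience,
                          seed = .derive_seed(config$seed, 7L))
  model <- gicf_fit(base$theta, data, w1 = config$w1, w2 = config$w2,
                    lam = config$lam, config = opt,
                    validation = list(X = mats$X_regions[val_rows, , drop = FALSE],
                                      region_protein = region_protein[val_rows],
                                      labels = Y),
                    go_id = corpus$go_id %||% "GO:SYNTH", space = config$space)

  region_scores <- score_region(model$theta, mats$X_regions)
  baseline_scores <- score_region(base$theta, mats$X_regions)

  if (use_contacts) {
    lab_list <- lapply(corpus$region_sets, label_binding_regions,
                       contacts = corpus$contacts)
    lab <- do.call(rbind, lab_list)
    keep <- lab$status != "excluded"
    region_labels <- setNames(as.numeric(lab$status == "positive"),
                              lab$region_id)[keep]
  } else {
    region_labels <- corpus$region_labels_true
  }
  # known anchors were supervised: keep them out of the evaluation
  eval_ids <- setdiff(intersect(names(region_labels), region_ids),
                      corpus$anchor_regions %||% character())
  boot_seed <- .derive_seed(config$seed, 11L)
  eval_region <- bootstrap_aupr(region_scores[eval_ids],
                                region_labels[eval_ids],
                                n_boot = config$n_boot, seed = boot_seed,
                                go_id = model$go_id, method = "region-specific")
  eval_baseline <- bootstrap_aupr(baseline_scores[eval_ids],
                                  region_labels[eval_ids],
                                  n_boot = config$n_boot, seed = boot_seed,
                                  go_id = model$go_id, method = "whole-protein")

  val_prot <- tapply(region_scores[val_rows], region_protein[val_rows], max)
  val_prot_base <- tapply(baseline_scores[val_rows],
                          region_protein[val_rows], max)
  list(
    config = config, model = model, baseline = base,
    feature_matrix = mats$fm, kernel = kernel,
    region_scores = region_scores, baseline_scores = baseline_scores,
    region_labels = region_labels, eval_ids = eval_ids,
    train_proteins = train, val_proteins = val,
    eval_region = eval_region, eval_baseline = eval_baseline,
    comparison = compare_methods(eval_region, eval_baseline),
    aupr_region = aupr(region_scores[eval_ids], region_labels[eval_ids]),
    aupr_baseline = aupr(baseline_scores[eval_ids], region_labels[eval_ids]),
    aupr_protein_val = aupr(as.numeric(val_prot), Y[names(val_prot)]),
    aupr_protein_val_baseline = aupr(as.numeric(val_prot_base),
                                     Y[names(val_prot_base)])
  )
}

# ---- file-based commands (what the command-line script wraps) ----------

.write_log <- function(path, cfg, extra = list()) {
  log <- c(list(config = unclass(cfg), config_hash = config_hash(cfg),
                package_version = as.character(utils::packageVersion("regionprop")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Command: generate a synthetic dataset on disk
#'
#' @param dir Output directory.
#' @param spec A [synthetic_spec()].
#' @param go_id GO identifier used for the planted function.
#' @return The file paths, invisibly.
#' @export
rp_simulate <- function(dir, spec = synthetic_spec(), go_id = "GO:0003677") {
  corpus <- generate_corpus(spec)
  paths <- write_corpus(corpus, dir, go_id = go_id)
  .write_log(file.path(dir, "simulate.log.json"),
             structure(unclass(spec), class = "run_config"),
             list(command = "simulate", go_id = go_id))
  invisible(paths)
}

# Shared loader: sequences + annotations -> region sets with features.
.load_region_sets <- function(fasta, tsv, min_overlap = 0.75) {
  proteins <- read_fasta(fasta)
  annotations <- read_interproscan_tsv(tsv)
  rs <- build_regions_all(proteins, annotations)
  lapply(rs, assign_features_to_regions, annotations,
         min_overlap = min_overlap)
}

#' Command: build consensus regions and write them as BED-like TSV
#'
#' @param fasta,tsv Input FASTA and InterProScan TSV paths.
#' @param out Output path for the region table.
#' @param config A [run_config()].
#' @return `out`, invisibly.
#' @export
rp_regions <- function(fasta, tsv, out, config = run_config()) {
  .assert(file.exists(fasta) && file.exists(tsv), "missing input file")
  rs <- .load_region_sets(fasta, tsv, config$min_overlap)
  write_regions_bed(rs, out)
  .write_log(paste0(out, ".log.json"), config, list(command = "regions"))
  invisible(out)
}

# counts for every region of every region set, plus per-protein spanners
.counts_of_sets <- function(region_sets, space, k) {
  counts <- list()
  spanners <- list()
  for (rs in region_sets) {
    counts <- c(counts, region_counts(rs, space = space, k = k))
    span <- switch(space,
      KMER = integer(),
      KEY = extract_keywords(rs$spanners$description),
      IPR = extract_ids(rs$spanners, "interpro"),
      SIG = extract_ids(rs$spanners, "signature"))
    spanners[[rs$protein$accession]] <- span
  }
  list(counts = counts, spanners = spanners)
}

#' Command: encode regions in one feature space and persist the matrix
#'
#' @inheritParams rp_regions
#' @param stem Output path stem for [write_feature_matrix()].
#' @return `stem`, invisibly.
#' @export
rp_featurize <- function(fasta, tsv, stem, config = run_config()) {
  .assert(file.exists(fasta) && file.exists(tsv), "missing input file")
  rs <- .load_region_sets(fasta, tsv, config$min_overlap)
  cs <- .counts_of_sets(rs, config$space, config$k)
  fm <- tfidf_fit_transform(cs$counts, space = config$space)
  write_feature_matrix(fm, stem)
  .write_log(paste0(stem, ".log.json"), config, list(command = "featurize"))
  invisible(stem)
}

# Assemble an in-memory corpus-like bundle from files.
.load_corpus_files <- function(dir, go_id, config) {
  fasta <- file.path(dir, "proteins.fasta")
  tsv <- file.path(dir, "annotations.tsv")
  gaf <- file.path(dir, "annotations.gaf")
  contacts_path <- file.path(dir, "contacts.tsv")
  for (f in c(fasta, tsv, gaf)) .assert(file.exists(f), "missing input: %s", f)
  rs <- .load_region_sets(fasta, tsv, config$min_overlap)
  cs <- .counts_of_sets(rs, config$space, config$k)
  gafd <- filter_non_iea(read_gaf(gaf, "old"))
  acc <- names(rs)
  pos <- unique(gafd$protein_accession[gafd$go_id == go_id & !gafd$negated])
  Y <- setNames(as.numeric(acc %in% pos), acc)
  contacts <- if (file.exists(contacts_path)) read_contacts(contacts_path)
    else NULL
  list(region_sets = rs, counts = cs$counts, spanners = cs$spanners,
       protein_labels = Y, contacts = contacts, go_id = go_id)
}

#' Command: train the region model (and baseline) from files on disk
#'
#' Expects the directory layout written by [rp_simulate()]: FASTA,
#' InterProScan TSV, GAF and (optionally) contacts TSV.  Writes the
#' trained model, the whole-protein baseline and a run log next to
#' `out_model`.
#'
#' @param dir Input directory.
#' @param go_id GO term to train.
#' @param out_model Output path of the model JSON archive.
#' @param config A [run_config()].
#' @return The experiment result list, invisibly.
#' @export
rp_train <- function(dir, go_id, out_model, config = run_config()) {
  bundle <- .load_corpus_files(dir, go_id, config)
  corpus <- list(counts = bundle$counts,
                 spanner_counts = bundle$spanners,
                 region_sets = bundle$region_sets,
                 protein_labels = bundle$protein_labels,
                 contacts = bundle$contacts, go_id = go_id)
  res <- run_experiment(corpus, config,
                        use_contacts = !is.null(bundle$contacts))
  res$model$idf <- res$feature_matrix$idf
  write_gicf_model(res$model, out_model)
  base_model <- structure(list(go_id = go_id, space = config$space,
                               theta = res$baseline$theta,
                               w1 = 0, w2 = 0, lam = res$baseline$lambda,
                               config = optimizer_config(seed = config$seed),
                               trace = data.frame()),
                          class = "gicf_model")
  write_gicf_model(base_model, sub("(\\.json)?$", ".baseline.json",
                                   out_model, perl = TRUE)[1])
  .write_log(paste0(out_model, ".log.json"), config,
             list(command = "train", go_id = go_id,
                  seed_lambda = res$baseline$lambda))
  invisible(res)
}

#' Command: score regions and proteins with a stored model
#'
#' @param model_path Path to a model JSON archive.
#' @param dir Input directory (FASTA + TSV).
#' @param out Output TSV of region and protein scores.
#' @param config A [run_config()].
#' @return `out`, invisibly.
#' @export
rp_predict <- function(model_path, dir, out, config = run_config()) {
  model <- read_gicf_model(model_path)
  rs <- .load_region_sets(file.path(dir, "proteins.fasta"),
                          file.path(dir, "annotations.tsv"),
                          config$min_overlap)
  cs <- .counts_of_sets(rs, model$space, config$k)
  vocab <- setdiff(names(model$theta), INTERCEPT_NAME)
  M <- count_matrix(cs$counts, vocab)
  # theta lives on the TF-IDF scale of the training matrix, so new items
  # must be weighted with the training idf (stored in the archive)
  idf <- if (!is.null(model$idf)) model$idf[vocab] else rep(1, ncol(M))
  idf[is.na(idf)] <- 1
  W <- .apply_tfidf(M, idf)
  pred <- gicf_predict(model, W,
                       region_protein = sub(":\\d+$", "", rownames(W)),
                       aggregate = TRUE)
  reg <- data.frame(item = names(pred$region_scores), level = "region",
                    score = as.numeric(pred$region_scores))
  prot <- data.frame(item = names(pred$protein_scores), level = "protein",
                     score = as.numeric(pred$protein_scores))
  write.table(rbind(reg, prot), out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  .write_log(paste0(out, ".log.json"), config, list(command = "predict"))
  invisible(out)
}

#' Command: run the full evaluation and write a report
#'
#' Trains (seeded) and evaluates region-level AUPR of the region-specific
#' model against the whole-protein baseline with paired bootstrap and the
#' Wilcoxon signed rank test, writing a JSON report and a TSV of region
#' scores.
#'
#' @param dir Input directory as written by [rp_simulate()].
#' @param go_id GO term to evaluate.
#' @param out Output path of the JSON report.
#' @param config A [run_config()].
#' @return The report list, invisibly.
#' @export
rp_evaluate <- function(dir, go_id, out, config = run_config()) {
  bundle <- .load_corpus_files(dir, go_id, config)
  corpus <- list(counts = bundle$counts, spanner_counts = bundle$spanners,
                 region_sets = bundle$region_sets,
                 protein_labels = bundle$protein_labels,
                 contacts = bundle$contacts, go_id = go_id)
  res <- run_experiment(corpus, config,
                        use_contacts = !is.null(bundle$contacts))
  report <- list(
    go_id = go_id, space = config$space, config_hash = config_hash(config),
    aupr_region = res$aupr_region, aupr_baseline = res$aupr_baseline,
    bootstrap_median_region = median(res$eval_region$boot),
    bootstrap_median_baseline = median(res$eval_baseline$boot),
    delta_median_aupr = res$comparison$delta_median,
    wilcoxon_p = res$comparison$p_value,
    n_boot = config$n_boot, seed = config$seed
  )
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  scores <- data.frame(region_id = names(res$region_scores),
                       score = as.numeric(res$region_scores),
                       baseline_score = as.numeric(res$baseline_scores))
  write.table(scores, sub("\\.json$", ".scores.tsv", out), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .write_log(paste0(out, ".log.json"), config,
             list(command = "evaluate", go_id = go_id))
  invisible(report)
}
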