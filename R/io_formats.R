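# Readers/writers for the standard formats the pipeline touches and the
# temporal-holdout label assembly.
#
# Coordinates are 1-based inclusive throughout (UniProt/InterPro convention);
# conversion to other conventions (e.g. BED) happens only at the boundary.

# Evidence codes accepted as experimental/manual ("non-IEA") annotations.
NON_IEA_CODES <- c("EXP", "IDA", "IMP", "IGI", "IEP", "TAS", "IC", "IPI")

#' Read protein sequences from a FASTA file
#'
#' Accessions are taken from the header token before the first whitespace.
#' UniProt-style headers (`sp|ACC|NAME` or `tr|ACC|NAME`) are recognised and
#' the accession field is extracted.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A data.frame with columns `accession`, `sequence`, `length`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|Q9UHR4|BI2L1_HUMAN desc", "ACDEFGHIK"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), "FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && nzchar(first) && !startsWith(first, ">")) {
    stop(sprintf("malformed FASTA at line 1 of %s: expected '>'", path), call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    return(data.frame(accession = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  acc <- sub("\\s.*$", "", names(seqs))
  upi <- grepl("^(sp|tr)\\|", acc)
  acc[upi] <- vapply(strsplit(acc[upi], "|", fixed = TRUE), `[`, "", 2L)
  .assert(all(nzchar(acc)), "FASTA record with empty accession in %s", path)
  data.frame(accession = unname(acc), sequence = unname(as.character(seqs)),
             length = unname(Biostrings::width(seqs)),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param proteins A data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- proteins$accession
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Map one InterProScan row to an entry type when the file itself does not
# carry one: Phobius topology/signal signatures and MobiDB-lite disorder are
# recognised by source database; otherwise signatures without an InterPro
# entry are treated as unintegrated and the rest fall through to "Other"
# (supply `entry_types` for integrated entries in real runs).
.entry_type_from_source <- function(source_db, signature_id, interpro_id) {
  sdb <- toupper(source_db)
  sig <- toupper(signature_id)
  if (sdb == "PHOBIUS") {
    if (startsWith(sig, "SIGNAL_PEPTIDE")) return("SignalPeptide")
    if (sig == "TRANSMEMBRANE") return("Transmembrane")
    if (sig %in% c("CYTOPLASMIC_DOMAIN", "NON_CYTOPLASMIC_DOMAIN")) {
      return("NonTransmembrane")
    }
  }
  if (sdb %in% c("MOBIDBLITE", "MOBIDB-LITE", "MOBIDB_LITE")) return("Disorder")
  if (sdb == "SIGNALP" || startsWith(sdb, "SIGNALP_")) return("SignalPeptide")
  if (sdb == "TMHMM") return("Transmembrane")
  if (is.na(interpro_id) || !nzchar(interpro_id)) return("UnintegratedSignature")
  "Other"
}

#' Read feature annotations from InterProScan 5 tab-separated output
#'
#' Consumes the 15-column InterProScan 5 TSV dialect (columns: protein
#' accession, MD5, length, analysis, signature accession, signature
#' description, start, stop, score, status, date, InterPro accession,
#' InterPro description, GO, pathways; trailing columns may be absent).  An
#' optional 16th column giving the InterPro entry type directly is honoured
#' when present — the synthetic-fixture writer emits it.  Otherwise the entry
#' type is taken from the `entry_types` lookup (named by InterPro entry ID or
#' signature ID), falling back to source-database rules (Phobius signal
#' peptide / transmembrane / non-transmembrane, MobiDB-lite disorder) and to
#' `UnintegratedSignature` for signatures without an InterPro entry.
#'
#' Rows whose start exceeds their end are rejected with a warning;
#' non-integer coordinates are a parse error.
#'
#' @param path Path to the TSV (plain or gzip-compressed).
#' @param entry_types Optional named character vector mapping InterPro entry
#'   IDs and/or signature IDs to entry types (see `ENTRY_TYPES`).
#' @return A data.frame of feature annotations with columns
#'   `protein_accession`, `source_db`, `entry_type`, `entry_id`,
#'   `interpro_id`, `description`, `start`, `end`.
#' @export
read_interproscan_tsv <- function(path, entry_types = NULL) {
  .assert(file.exists(path), "InterProScan TSV not found: %s", path)
  raw <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, colClasses = "character",
                    fill = TRUE)
  if (nrow(raw) == 0L) {
    return(.empty_annotations())
  }
  .assert(ncol(raw) >= 8, "InterProScan TSV %s has %d columns; need >= 8",
          path, ncol(raw))
  start <- suppressWarnings(as.numeric(raw[[7]]))
  end <- suppressWarnings(as.numeric(raw[[8]]))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) {
    stop(sprintf("non-integer coordinates in %s (first offending row: %d)",
                 path, which(bad)[1L]), call. = FALSE)
  }
  ipr <- if (ncol(raw) >= 12) raw[[12]] else rep(NA_character_, nrow(raw))
  ipr[ipr %in% c("", "-")] <- NA_character_
  type_col <- if (ncol(raw) >= 16) raw[[16]] else rep(NA_character_, nrow(raw))
  type_col[type_col %in% c("", "-")] <- NA_character_

  etype <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    t <- type_col[i]
    if (is.na(t) && !is.null(entry_types)) {
      if (!is.na(ipr[i]) && ipr[i] %in% names(entry_types)) {
        t <- unname(entry_types[[ipr[i]]])
      } else if (raw[[5]][i] %in% names(entry_types)) {
        t <- unname(entry_types[[raw[[5]][i]]])
      }
    }
    if (is.na(t)) t <- .entry_type_from_source(raw[[4]][i], raw[[5]][i], ipr[i])
    .assert(t %in% ENTRY_TYPES, "unknown entry type '%s' in %s", t, path)
    etype[i] <- t
  }

  ann <- data.frame(
    protein_accession = raw[[1]],
    source_db = raw[[4]],
    entry_type = etype,
    entry_id = raw[[5]],
    interpro_id = ipr,
    description = if (ncol(raw) >= 6) raw[[6]] else "",
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  rev_ok <- ann$start <= ann$end
  if (!all(rev_ok)) {
    warning(sprintf("%d annotation row(s) with start > end rejected in %s",
                    sum(!rev_ok), path), call. = FALSE)
    ann <- ann[rev_ok, , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

.empty_annotations <- function() {
  data.frame(protein_accession = character(), source_db = character(),
             entry_type = character(), entry_id = character(),
             interpro_id = character(), description = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

#' Write feature annotations in the InterProScan 5 TSV dialect
#'
#' Emits the 15 standard columns plus a 16th column carrying the entry type,
#' so that [read_interproscan_tsv()] round-trips the records exactly.
#'
#' @param annotations Annotation data.frame (see [read_interproscan_tsv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interproscan_tsv <- function(annotations, path) {
  n <- nrow(annotations)
  out <- data.frame(
    annotations$protein_accession,
    strrep("0", 32),
    rep("0", n),
    annotations$source_db,
    annotations$entry_id,
    annotations$description,
    annotations$start,
    annotations$end,
    rep("-", n),
    rep("T", n),
    rep("01-01-2026", n),
    ifelse(is.na(annotations$interpro_id), "-", annotations$interpro_id),
    rep("-", n),
    rep("-", n),
    rep("-", n),
    annotations$entry_type,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read GO annotations from a GAF 2.x file
#'
#' All rows are parsed; evidence filtering happens downstream in
#' [filter_non_iea()].  Rows carrying a `NOT` qualifier are retained but
#' flagged in the `negated` column; they are excluded from both positives and
#' the negative pool by [temporal_split()].
#'
#' @param path Path to a GAF file (plain or gzip-compressed); comment lines
#'   start with `!`.
#' @param release_tag Tag recorded on every row, e.g. `"old"` or `"new"`.
#' @return A data.frame with columns `protein_accession`, `go_id`,
#'   `evidence_code`, `qualifier`, `negated`, `release_tag`.
#' @export
read_gaf <- function(path, release_tag) {
  .assert(file.exists(path), "GAF file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(protein_accession = character(), go_id = character(),
                      evidence_code = character(), qualifier = character(),
                      negated = logical(), release_tag = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L)) {
    stop(sprintf("GAF row with %d columns (need >= 15) at data line %d of %s",
                 min(nf), which(nf < 15L)[1L], path), call. = FALSE)
  }
  qual <- vapply(fields, `[`, "", 4L)
  data.frame(
    protein_accession = vapply(fields, `[`, "", 2L),
    go_id = vapply(fields, `[`, "", 5L),
    evidence_code = vapply(fields, `[`, "", 7L),
    qualifier = qual,
    negated = grepl("(^|\\|)NOT($|\\|)", qual),
    release_tag = release_tag,
    stringsAsFactors = FALSE
  )
}

#' Write GO annotations as GAF 2.1
#'
#' @param annotations Data.frame as returned by [read_gaf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  n <- nrow(annotations)
  if (n > 0L) {
    out <- data.frame(
      rep("UniProtKB", n), annotations$protein_accession,
      annotations$protein_accession, annotations$qualifier,
      annotations$go_id, rep("PMID:0", n), annotations$evidence_code,
      rep("", n), rep("F", n), rep("", n), rep("", n),
      rep("protein", n), rep("taxon:9606", n), rep("20260101", n),
      rep("SYN", n), rep("", n), rep("", n),
      stringsAsFactors = FALSE
    )
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Keep only experimentally supported (non-IEA) GO annotations
#'
#' Retains annotations whose evidence code is one of
#' EXP, IDA, IMP, IGI, IEP, TAS, IC, IPI.  Idempotent.
#'
#' @param annotations Data.frame as returned by [read_gaf()].
#' @return The filtered data.frame.
#' @export
filter_non_iea <- function(annotations) {
  out <- annotations[annotations$evidence_code %in% NON_IEA_CODES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a temporal-holdout split for one GO term
#'
#' Training positives are proteins annotated with `go_id` in the older
#' release; evaluation positives are proteins that gained a `go_id`
#' annotation by the newer release without having one before (a fully blind
#' test).  Negatives for each side are proteins with at least one non-IEA
#' annotation to some other term in the corresponding release but none to
#' the target term (nor, optionally, to any of its descendants) in either
#' release.  Rows flagged `NOT` are excluded from positives and from the
#' negative pool.
#'
#' @param old_annotations,new_annotations Non-IEA-filtered annotation
#'   data.frames from the two releases (see [filter_non_iea()]).
#' @param go_id Target GO term, e.g. `"GO:0003677"`.
#' @param descendants Optional character vector of descendant GO IDs of
#'   `go_id`; when supplied, proteins annotated to a descendant are also
#'   removed from the negative pool.
#' @return A list with data.frames `train` and `eval`, each with columns
#'   `accession` and `label` (1 = positive, 0 = negative), and the `go_id`.
#' @export
temporal_split <- function(old_annotations, new_annotations, go_id,
                           descendants = NULL) {
  target <- c(go_id, descendants)
  pos_of <- function(ann) unique(ann$protein_accession[ann$go_id == go_id & !ann$negated])
  tgt_of <- function(ann) unique(ann$protein_accession[ann$go_id %in% target])
  not_of <- function(ann) unique(ann$protein_accession[ann$negated])

  old_pos <- pos_of(old_annotations)
  new_pos <- pos_of(new_annotations)
  if (length(old_pos) == 0L && length(new_pos) == 0L) {
    stop(sprintf("GO term %s absent from both releases: empty split", go_id),
         call. = FALSE)
  }
  tgt_any <- union(tgt_of(old_annotations), tgt_of(new_annotations))
  not_any <- union(not_of(old_annotations), not_of(new_annotations))

  eval_pos <- setdiff(new_pos, old_pos)
  old_neg <- setdiff(unique(old_annotations$protein_accession),
                     union(tgt_any, not_any))
  new_neg <- setdiff(unique(new_annotations$protein_accession),
                     union(union(tgt_any, not_any), old_neg))

  list(
    go_id = go_id,
    train = data.frame(
      accession = c(old_pos, old_neg),
      label = rep(c(1L, 0L), c(length(old_pos), length(old_neg))),
      stringsAsFactors = FALSE
    ),
    eval = data.frame(
      accession = c(eval_pos, new_neg),
      label = rep(c(1L, 0L), c(length(eval_pos), length(new_neg))),
      stringsAsFactors = FALSE
    )
  )
}

#' Read signature-to-GO mappings in the interpro2go/external2go line format
#'
#' Parses lines of the form
#' `InterPro:IPR000008 C2 domain > GO:protein binding ; GO:0005515`.
#' Comment lines (`!`) are skipped; lines without a `"; GO:"` part are
#' skipped with a warning.
#'
#' @param path Path to the mapping file (plain or gzip-compressed).
#' @return A data.frame with columns `signature_id` and `go_id`.
#' @export
read_external2go <- function(path) {
  .assert(file.exists(path), "external2go file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  m <- regmatches(lines, regexec(
    "^[A-Za-z0-9_]+:(\\S+).*>.*;\\s*(GO:\\d{7})\\s*$", lines))
  ok <- lengths(m) == 3L
  if (any(!ok)) {
    warning(sprintf("%d unparseable line(s) skipped in %s", sum(!ok), path),
            call. = FALSE)
  }
  hits <- m[ok]
  data.frame(
    signature_id = vapply(hits, `[`, "", 2L),
    go_id = vapply(hits, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

#' Write signature-to-GO mappings in external2go format
#'
#' @param mappings Data.frame with `signature_id` and `go_id` columns.
#' @param namespace Namespace prefix written before each signature ID.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_external2go <- function(mappings, path, namespace = "InterPro") {
  lines <- sprintf("%s:%s mapped entry > GO:mapped term ; %s",
                   namespace, mappings$signature_id, mappings$go_id)
  writeLines(c("!external2go mapping", lines), path)
  invisible(path)
}

#' Attach external2go region labels and propagate them to parent proteins
#'
#' Regions whose assigned signature or InterPro IDs match a mapping for
#' `go_id` become known positive regions (the sparse anchor set r+ of the
#' cost function); their parent proteins are marked positive for consistency.
#'
#' @param regions Region data.frame (see [build_regions()]) with features
#'   assigned by [assign_features_to_regions()].
#' @param region_features A list mapping `region_id` to the annotation rows
#'   assigned to that region (the `features` attribute produced by
#'   [assign_features_to_regions()]).
#' @param mappings Data.frame from [read_external2go()].
#' @param go_id Target GO term.
#' @return A list with `positive_regions` (character region ids) and
#'   `positive_proteins` (character accessions).
#' @export
map_signature_labels <- function(regions, region_features, mappings, go_id) {
  sig <- unique(mappings$signature_id[mappings$go_id == go_id])
  if (length(sig) == 0L) {
    return(list(positive_regions = character(), positive_proteins = character()))
  }
  hit <- vapply(regions$region_id, function(rid) {
    f <- region_features[[rid]]
    !is.null(f) && nrow(f) > 0L &&
      (any(f$entry_id %in% sig) || any(!is.na(f$interpro_id) & f$interpro_id %in% sig))
  }, logical(1L))
  list(
    positive_regions = regions$region_id[hit],
    positive_proteins = unique(regions$protein_accession[hit])
  )
}
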