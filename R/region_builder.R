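# Consensus region boundaries.
#
# Proteins are split into continuous candidate functional regions by letting
# typed annotation tiers claim sequence in a fixed precedence order; leftover
# stretches become Unassigned regions, subject to the terminal-merge (<18
# residues) and linker-discard (<20 residues) rules.

# Precedence order for boundary building.  Signal peptides are handled
# before the tiers and are always kept; Family and Homologous superfamily
# share one tier; Repeats and Sites never contribute to boundaries.
REGION_TIERS <- list(
  Domain = "Domain",
  FamilySuperfamily = c("Family", "HomologousSuperfamily"),
  UnintegratedSignature = "UnintegratedSignature",
  Transmembrane = "Transmembrane",
  NonTransmembrane = "NonTransmembrane",
  Disorder = "Disorder"
)

MIN_TERMINAL_LEN <- 18L  # unassigned terminal regions shorter than this merge
MIN_LINKER_LEN <- 20L    # unassigned inter-domain regions shorter than this are discarded

.ir <- function(start, end) IRanges::IRanges(start = start, end = end)

#' Split a protein into candidate functional regions
#'
#' Boundary building proceeds in a fixed precedence order: signal peptides
#' (always kept when present), then Domain, then Family and Homologous
#' superfamily, then unintegrated signatures, Transmembrane,
#' Non-transmembrane and Disorder.  Within a tier, overlapping intervals are
#' union-merged into consensus intervals; each tier may only claim residues
#' not claimed by an earlier tier (intervals are clipped).  Repeat and Site
#' annotations are excluded from boundary building entirely.  Residues
#' claimed by no tier become Unassigned regions; unassigned terminal regions
#' shorter than 18 residues are merged into their neighbouring region, and
#' unassigned inter-domain regions shorter than 20 residues are discarded
#' (their residues belong to no region, removing most linkers).
#'
#' @param protein One-row data.frame with `accession`, `sequence`, `length`
#'   (a row of [read_fasta()] output), or a list with those fields.
#' @param annotations Annotation data.frame for this protein
#'   (see [read_interproscan_tsv()]).
#' @return An object of class `region_set`: a list with `protein` and
#'   `regions`, the latter a data.frame with columns `region_id`
#'   (`accession:index`), `protein_accession`, `index`, `start`, `end`,
#'   `origin_type`, sorted and indexed left to right.
#' @examples
#' prot <- data.frame(accession = "Q9UHR4", sequence = strrep("A", 511), length = 511)
#' ann <- data.frame(protein_accession = "Q9UHR4", source_db = "X",
#'                   entry_type = "Domain", entry_id = c("D1", "D2"),
#'                   interpro_id = NA, description = "",
#'                   start = c(1L, 339L), end = c(249L, 402L))
#' build_regions(prot, ann)$regions
#' @export
build_regions <- function(protein, annotations) {
  L <- as.integer(protein$length)
  .assert(length(L) == 1L && L >= 1L, "zero-length or invalid protein")
  acc <- protein$accession

  ann <- annotations[annotations$protein_accession == acc, , drop = FALSE]
  oob <- ann$start < 1L | ann$end > L | ann$start > ann$end
  if (any(oob)) {
    warning(sprintf("%d out-of-bounds annotation(s) rejected for %s",
                    sum(oob), acc), call. = FALSE)
    ann <- ann[!oob, , drop = FALSE]
  }
  # Repeats and Sites never shape boundaries.
  ann <- ann[!ann$entry_type %in% c("Repeat", "Site", "Other"), , drop = FALSE]

  claimed <- .ir(integer(), integer())
  pieces <- list()
  add_pieces <- function(ir, origin) {
    if (length(ir) == 0L) return()
    pieces[[length(pieces) + 1L]] <<- data.frame(
      start = IRanges::start(ir), end = IRanges::end(ir),
      origin_type = origin, stringsAsFactors = FALSE)
  }
  claim <- function(types, origin) {
    rows <- ann[ann$entry_type %in% types, , drop = FALSE]
    if (nrow(rows) == 0L) return()
    # min.gapwidth = 0: overlapping intervals union-merge, abutting distinct
    # annotations stay separate regions
    merged <- IRanges::reduce(.ir(rows$start, rows$end), min.gapwidth = 0L)
    # clip each consensus interval to unclaimed residues separately --
    # a plain set-difference would normalize away the boundary between
    # abutting intervals
    for (i in seq_along(merged)) {
      fresh <- IRanges::setdiff(merged[i], claimed)
      add_pieces(fresh, origin)
      claimed <<- IRanges::union(claimed, fresh)
    }
  }

  claim("SignalPeptide", "SignalPeptide")
  for (tier in names(REGION_TIERS)) {
    origin <- if (tier == "FamilySuperfamily") "Family" else tier
    claim(REGION_TIERS[[tier]], origin)
  }

  gaps <- IRanges::setdiff(.ir(1L, L), claimed)
  add_pieces(gaps, "Unassigned")

  reg <- do.call(rbind, pieces)
  if (is.null(reg)) {
    reg <- data.frame(start = 1L, end = L, origin_type = "Unassigned",
                      stringsAsFactors = FALSE)
  }
  reg <- reg[order(reg$start), , drop = FALSE]
  rownames(reg) <- NULL

  reg <- .apply_short_region_rules(reg, L)

  reg$protein_accession <- acc
  reg$index <- seq_len(nrow(reg))
  reg$region_id <- paste0(acc, ":", reg$index)
  reg <- reg[, c("region_id", "protein_accession", "index",
                 "start", "end", "origin_type")]
  structure(list(protein = protein, regions = reg), class = "region_set")
}

# Terminal-merge and linker-discard rules for Unassigned stretches.
# `reg` is sorted by start and non-overlapping.
.apply_short_region_rules <- function(reg, L) {
  n <- nrow(reg)
  if (n <= 1L) return(reg)
  width <- reg$end - reg$start + 1L

  # Terminal rule first: an Unassigned region touching either protein end
  # and shorter than 18 residues merges into its immediate neighbour (the
  # neighbour absorbs the residues and keeps its own origin).
  first_u <- reg$origin_type[1L] == "Unassigned" && width[1L] < MIN_TERMINAL_LEN
  if (first_u && n >= 2L && reg$end[1L] + 1L == reg$start[2L]) {
    reg$start[2L] <- reg$start[1L]
    reg <- reg[-1L, , drop = FALSE]
    n <- nrow(reg)
    width <- reg$end - reg$start + 1L
  }
  last_u <- reg$origin_type[n] == "Unassigned" && width[n] < MIN_TERMINAL_LEN
  if (last_u && n >= 2L && reg$start[n] - 1L == reg$end[n - 1L]) {
    reg$end[n - 1L] <- reg$end[n]
    reg <- reg[-n, , drop = FALSE]
    n <- nrow(reg)
    width <- reg$end - reg$start + 1L
  }

  # Linker rule: interior Unassigned regions shorter than 20 residues are
  # discarded outright; their residues belong to no region.
  interior <- seq_len(n) > 1L & seq_len(n) < n
  drop <- interior & reg$origin_type == "Unassigned" & width < MIN_LINKER_LEN
  reg <- reg[!drop, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Build regions for every protein in a set
#'
#' @param proteins Data.frame from [read_fasta()].
#' @param annotations Annotation data.frame covering all proteins.
#' @return A named list of `region_set` objects, one per protein accession.
#' @export
build_regions_all <- function(proteins, annotations) {
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    build_regions(proteins[i, , drop = FALSE], annotations)
  })
  names(out) <- proteins$accession
  out
}

#' Assign feature annotations to regions by the 75%-overlap rule
#'
#' An annotation (all types, including Repeats and Sites — feature
#' assignment is separate from boundary building) is attached to the region
#' with which it shares the greatest overlap, provided the overlap covers at
#' least `min_overlap` of the annotation's length; ties go to the leftmost
#' region.  Annotations that reach the threshold in no region (multi-region
#' spanners) are reported separately — the whole-protein baseline uses them.
#'
#' @param region_set A `region_set` from [build_regions()].
#' @param annotations Annotation data.frame for this protein.
#' @param min_overlap Minimum fraction of the annotation length that must
#'   fall inside a single region (default 0.75).
#' @return The `region_set` with two added elements: `features`, a named
#'   list (by `region_id`) of assigned annotation rows, and `spanners`, the
#'   annotation rows assigned to no region.
#' @export
assign_features_to_regions <- function(region_set, annotations,
                                       min_overlap = 0.75) {
  .assert(inherits(region_set, "region_set"), "not a region_set")
  acc <- region_set$protein$accession
  reg <- region_set$regions
  ann <- annotations[annotations$protein_accession == acc &
                       annotations$start <= annotations$end, , drop = FALSE]
  feats <- setNames(vector("list", nrow(reg)), reg$region_id)
  for (rid in reg$region_id) feats[[rid]] <- ann[0, , drop = FALSE]
  span_idx <- integer()

  if (nrow(ann) > 0L && nrow(reg) > 0L) {
    for (i in seq_len(nrow(ann))) {
      ov <- pmin(ann$end[i], reg$end) - pmax(ann$start[i], reg$start) + 1L
      ov[ov < 0L] <- 0L
      frac <- ov / (ann$end[i] - ann$start[i] + 1L)
      best <- which.max(frac)  # ties -> leftmost (regions sorted by start)
      if (frac[best] >= min_overlap) {
        rid <- reg$region_id[best]
        feats[[rid]] <- rbind(feats[[rid]], ann[i, , drop = FALSE])
      } else {
        span_idx <- c(span_idx, i)
      }
    }
  } else if (nrow(ann) > 0L) {
    span_idx <- seq_len(nrow(ann))
  }
  for (rid in names(feats)) rownames(feats[[rid]]) <- NULL
  region_set$features <- feats
  region_set$spanners <- ann[span_idx, , drop = FALSE]
  rownames(region_set$spanners) <- NULL
  region_set
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %s (%d aa, %d region(s))\n",
              x$protein$accession, x$protein$length, nrow(x$regions)))
  print(x$regions, ...)
  invisible(x)
}

#' Serialize region sets as BED-like TSV
#'
#' Columns: accession, 0-based half-open start, end, region index,
#' origin type.  The 1-based inclusive internal convention is converted at
#' this boundary.
#'
#' @param region_sets A list of `region_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(region_sets, path) {
  reg <- do.call(rbind, lapply(region_sets, `[[`, "regions"))
  out <- data.frame(reg$protein_accession, reg$start - 1L, reg$end,
                    reg$index, reg$origin_type, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read region sets back from BED-like TSV
#'
#' @param path Path written by [write_regions_bed()].
#' @return A data.frame of regions in the 1-based inclusive convention.
#' @export
read_regions_bed <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(raw) == 5L, "expected 5 BED-like columns in %s", path)
  data.frame(
    region_id = paste0(raw[[1]], ":", raw[[4]]),
    protein_accession = raw[[1]],
    index = as.integer(raw[[4]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]]),
    origin_type = raw[[5]],
    stringsAsFactors = FALSE
  )
}
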