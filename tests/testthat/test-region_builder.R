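# Consensus boundary building: precedence, merge and discard rules.

test_that("two-domain example yields the four canonical regions", {
  prot <- toy_protein("Q9UHR4", 511L)
  ann <- rbind(
    toy_annotation("Q9UHR4", "Domain", 1, 249, id = "PF08397",
                   desc = "IMD/I-BAR domain"),
    toy_annotation("Q9UHR4", "Domain", 339, 402, id = "PF14604",
                   desc = "SH3 domain"))
  reg <- build_regions(prot, ann)$regions
  expect_equal(reg$start, c(1L, 250L, 339L, 403L))
  expect_equal(reg$end, c(249L, 338L, 402L, 511L))
  expect_equal(reg$origin_type,
               c("Domain", "Unassigned", "Domain", "Unassigned"))
  expect_equal(reg$index, 1:4)
  expect_equal(sum(reg$end - reg$start + 1L), 511L)
})

test_that("boundary edge rules: no annotations, short terminals, linkers", {
  # nothing to split on -> one Unassigned region
  reg <- build_regions(toy_protein("P1", 100L), toy_annotation("P1", "Domain", 5, 10)[0, ])$regions
  expect_equal(reg[, c("start", "end", "origin_type")],
               data.frame(start = 1L, end = 100L, origin_type = "Unassigned"))

  # terminal gap of 5 < 18 merges into the neighbouring domain
  reg <- build_regions(toy_protein("P1", 100L),
                       toy_annotation("P1", "Domain", 1, 95))$regions
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(1L, 100L))
  expect_equal(reg$origin_type, "Domain")

  # terminal gap of exactly 18 is kept ("less than 18")
  reg <- build_regions(toy_protein("P1", 100L),
                       toy_annotation("P1", "Domain", 1, 82))$regions
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start[2], 83L)

  # interior linker of 10 < 20 discarded; its residues belong to no region
  ann <- rbind(toy_annotation("P1", "Domain", 1, 140),
               toy_annotation("P1", "Domain", 151, 300))
  reg <- build_regions(toy_protein("P1", 300L), ann)$regions
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(1L, 151L))
  expect_equal(reg$end, c(140L, 300L))

  # interior gap of exactly 20 kept
  ann <- rbind(toy_annotation("P1", "Domain", 1, 140),
               toy_annotation("P1", "Domain", 161, 300))
  expect_equal(nrow(build_regions(toy_protein("P1", 300L), ann)$regions), 3L)
})

test_that("precedence: earlier tiers claim first, later tiers are clipped", {
  # Family overlapping a Domain only keeps its unclaimed part
  ann <- rbind(toy_annotation("P1", "Domain", 41, 120),
               toy_annotation("P1", "Family", 1, 160))
  reg <- build_regions(toy_protein("P1", 200L), ann)$regions
  expect_equal(reg$origin_type, c("Family", "Domain", "Family", "Unassigned"))
  expect_equal(reg$start, c(1L, 41L, 121L, 161L))
  expect_equal(reg$end, c(40L, 120L, 160L, 200L))

  # Repeats and Sites never shape boundaries
  ann <- rbind(toy_annotation("P1", "Repeat", 1, 80),
               toy_annotation("P1", "Site", 90, 95))
  reg <- build_regions(toy_protein("P1", 200L), ann)$regions
  expect_equal(reg$origin_type, "Unassigned")

  # signal peptide is always kept, ahead of the tiers
  ann <- rbind(toy_annotation("P1", "SignalPeptide", 1, 22),
               toy_annotation("P1", "Domain", 10, 150))
  reg <- build_regions(toy_protein("P1", 200L), ann)$regions
  expect_equal(reg$origin_type[1], "SignalPeptide")
  expect_equal(reg$end[1], 22L)
  expect_equal(reg$start[2], 23L)
})

test_that("overlapping same-tier annotations union-merge; abutting stay apart", {
  ann <- rbind(toy_annotation("P1", "Domain", 10, 60),
               toy_annotation("P1", "Domain", 40, 100),
               toy_annotation("P1", "Domain", 101, 150))
  reg <- build_regions(toy_protein("P1", 150L), ann)$regions
  dom <- reg[reg$origin_type == "Domain", ]
  # 10-60 and 40-100 overlap and merge; 101-150 abuts and stays apart;
  # the short unassigned terminal 1-9 then merges into the first domain
  expect_equal(dom$start, c(1L, 101L))
  expect_equal(dom$end, c(100L, 150L))
  expect_equal(nrow(reg), 2L)
})

test_that("random annotation sets keep the structural invariants", {
  for (seed in 1:20) {
    set.seed(seed)
    L <- sample(60:600, 1)
    n_ann <- sample(0:6, 1)
    ann <- do.call(rbind, lapply(seq_len(n_ann), function(i) {
      s <- sample.int(L, 1)
      toy_annotation("P1", sample(c("Domain", "Family", "Transmembrane",
                                    "Disorder", "Repeat"), 1),
                     s, min(L, s + sample.int(200, 1)),
                     id = paste0("A", i))
    }))
    if (is.null(ann)) ann <- toy_annotation("P1", "Domain", 1, 10)[0, ]
    rs <- build_regions(toy_protein("P1", L), ann)
    reg <- rs$regions
    # identical inputs -> identical output (determinism)
    expect_identical(build_regions(toy_protein("P1", L), ann)$regions, reg)
    # sorted, non-overlapping, within bounds, indexed left to right
    expect_true(all(reg$start <= reg$end))
    expect_true(all(reg$start >= 1 & reg$end <= L))
    if (nrow(reg) > 1) {
      expect_true(all(diff(reg$start) > 0))
      expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
    }
    expect_equal(reg$index, seq_len(nrow(reg)))
    # no short Unassigned terminal or interior linker survives
    w <- reg$end - reg$start + 1L
    un <- reg$origin_type == "Unassigned"
    term <- seq_len(nrow(reg)) %in% c(1L, nrow(reg))
    expect_false(any(un & term & w < 18 & nrow(reg) > 1))
    expect_false(any(un & !term & w < 20))
    # coverage never exceeds the protein
    expect_lte(sum(w), L)
  }
})

test_that("features attach by the 75% overlap rule to a single best region", {
  prot <- toy_protein("P1", 120L)
  ann <- rbind(toy_annotation("P1", "Domain", 1, 17, id = "D1"),
               toy_annotation("P1", "Domain", 18, 120, id = "D2"))
  rs <- build_regions(prot, ann)
  # 8/10 residues inside region 1 -> attached there
  probe <- toy_annotation("P1", "Site", 10, 19, id = "S1")
  out <- assign_features_to_regions(rs, rbind(ann, probe))
  expect_true("S1" %in% out$features[["P1:1"]]$entry_id)
  # 5/10 residues -> below threshold, becomes a spanner
  probe2 <- toy_annotation("P1", "Site", 13, 22, id = "S2")
  out2 <- assign_features_to_regions(rs, rbind(ann, probe2))
  expect_false("S2" %in% out2$features[["P1:1"]]$entry_id)
  expect_false("S2" %in% out2$features[["P1:2"]]$entry_id)
  expect_true("S2" %in% out2$spanners$entry_id)
  # exact match attaches with overlap 1
  probe3 <- toy_annotation("P1", "Site", 18, 120, id = "S3")
  out3 <- assign_features_to_regions(rs, rbind(ann, probe3))
  expect_true("S3" %in% out3$features[["P1:2"]]$entry_id)
})

test_that("region BED round trip converts coordinates at the boundary", {
  prot <- toy_protein("Q1", 300L)
  ann <- rbind(toy_annotation("Q1", "Domain", 1, 140),
               toy_annotation("Q1", "Domain", 161, 300))
  rs <- build_regions(prot, ann)
  tf <- tempfile(fileext = ".bed")
  write_regions_bed(list(rs), tf)
  raw <- read.delim(tf, header = FALSE)
  expect_equal(raw[[2]], rs$regions$start - 1L)  # 0-based half-open start
  back <- read_regions_bed(tf)
  expect_equal(back$start, rs$regions$start)
  expect_equal(back$end, rs$regions$end)
})
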