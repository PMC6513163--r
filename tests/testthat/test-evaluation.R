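# AUPR, bootstrap, Wilcoxon, F1-max, binding labels and baselines.

test_that("average precision equals brute-force enumeration on small sets", {
  # all labelings of up to 8 items with distinct scores
  for (n in 2:8) {
    scores <- seq_len(n) / n
    for (mask in 1:(2^n - 2)) {
      labels <- as.integer(intToBits(mask))[1:n]
      if (sum(labels) == 0 || sum(labels) == n) next
      expect_equal(aupr(scores, labels), oracle_aupr(scores, labels),
                   tolerance = 1e-12)
    }
  }
})

test_that("average precision endpoints and tie handling", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # one positive ranked last of 4 distinct scores
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 0.25)
  # all scores equal -> prevalence
  expect_equal(aupr(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  # invariance under strictly monotone transformation
  s <- runif(50); l <- rbinom(50, 1, 0.3); l[1] <- 1; l[2] <- 0
  expect_equal(aupr(s, l), aupr(qlogis(s), l), tolerance = 1e-12)
  expect_error(aupr(c(1, 2), c(1, 1)), "positive and one negative")
})

test_that("bootstrap is reproducible, paired, and centred on the point AUPR", {
  set.seed(31)
  # the bootstrap mean carries an O(1/n_items) bias relative to the point
  # estimate (duplicated items become tie groups), so the centring check
  # needs a reasonably large item count
  scores <- runif(500)
  labels <- rbinom(500, 1, 0.3); labels[1] <- 1; labels[2] <- 0
  r1 <- bootstrap_aupr(scores, labels, n_boot = 200, seed = 5)
  r2 <- bootstrap_aupr(scores, labels, n_boot = 200, seed = 5)
  expect_identical(r1$boot, r2$boot)  # bit-for-bit reproducible
  expect_length(r1$boot, 200L)
  expect_true(all(r1$boot >= 0 & r1$boot <= 1))
  # paired with another method evaluated under the same seed: identical
  # scores must give identical bootstrap vectors
  r3 <- bootstrap_aupr(scores, labels, n_boot = 200, seed = 5)
  expect_equal(compare_methods(r1, r3)$delta_median, 0)
  expect_equal(compare_methods(r1, r3)$p_value, 1.0)
  # n_boot = 1 equals a plain AUPR of the resample
  r4 <- bootstrap_aupr(scores, labels, n_boot = 1, seed = 9)
  expect_length(r4$boot, 1L)
  # bootstrap mean approaches the point estimate
  big <- bootstrap_aupr(scores, labels, n_boot = 2000, seed = 13)
  se <- sd(big$boot) / sqrt(length(big$boot))
  expect_lt(abs(mean(big$boot) - big$point), max(3 * se, 0.01))
})

test_that("wilcoxon signed rank matches enumeration and saturates", {
  expect_equal(wilcoxon_signed_rank(1:10, 1:10), 1.0)
  # constant positive shift at n = 50 is overwhelmingly significant
  set.seed(2)
  b <- runif(50)
  expect_lt(wilcoxon_signed_rank(b + 0.3, b), 1e-6)
  # exact small-sample case against full 2^n enumeration
  for (seed in 1:5) {
    set.seed(seed)
    x <- round(rnorm(6), 2); y <- round(rnorm(6), 2)
    expect_equal(wilcoxon_signed_rank(x, y), oracle_wilcoxon(x, y),
                 tolerance = 1e-12)
  }
  # cross-check the large-sample tied path against the reference
  # implementation
  set.seed(8)
  a <- sample(seq(0, 1, 0.05), 60, replace = TRUE)
  b <- sample(seq(0, 1, 0.05), 60, replace = TRUE)
  keep <- a != b
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             correct = TRUE))$p.value
  expect_equal(wilcoxon_signed_rank(a, b), ref, tolerance = 1e-6)
})

test_that("F1-max scans thresholds and breaks ties to the sensitive side", {
  # perfectly separated scores
  out <- f1max_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(out$f1, 1.0)
  expect_equal(out$threshold, 0.8)
  # all labels positive: minimal threshold calls everything, F1 = 1
  out <- f1max_threshold(c(0.3, 0.6, 0.9), c(1, 1, 1))
  expect_equal(out$threshold, 0.3)
  expect_equal(out$f1, 1.0)
  # brute-force check over the 3 candidate thresholds
  s <- c(0.9, 0.8, 0.1); l <- c(1, 0, 0)
  f1_at <- function(t) {
    tp <- sum(s >= t & l == 1); fp <- sum(s >= t & l == 0)
    fn <- sum(s < t & l == 1)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  best <- max(vapply(sort(unique(s)), f1_at, 0))
  out <- f1max_threshold(s, l)
  expect_equal(out$f1, best)
  expect_equal(out$threshold, 0.9)
  expect_error(f1max_threshold(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("binding labels follow the contact and coverage rules", {
  prot <- toy_protein("P1", 100L)
  ann <- rbind(toy_annotation("P1", "Domain", 1, 50),
               toy_annotation("P1", "Domain", 51, 100))
  rs <- build_regions(prot, ann)
  mk_contacts <- function(near, covered_res = 1:100) {
    data.frame(protein_accession = "P1", residue = 1:100,
               min_distance = ifelse(1:100 %in% near, 4.0, 20.0),
               ligand_class = "DNA", covered = 1:100 %in% covered_res)
  }
  # 4 contact residues -> positive ("more than 3")
  lab <- label_binding_regions(rs, mk_contacts(c(5, 10, 15, 20)))
  expect_equal(lab$status, c("positive", "negative"))
  # exactly 3 contact residues -> negative (strict inequality)
  lab <- label_binding_regions(rs, mk_contacts(c(5, 10, 15)))
  expect_equal(lab$status[1], "negative")
  # 70% coverage -> excluded regardless of contacts
  lab <- label_binding_regions(rs, mk_contacts(c(5, 10, 15, 20),
                                               covered_res = c(1:35, 51:100)))
  expect_equal(lab$status, c("excluded", "negative"))
  # contacts TSV round trip
  ct <- mk_contacts(c(5, 6, 7, 8))
  tf <- tempfile(fileext = ".tsv")
  write_contacts(ct, tf)
  back <- read_contacts(tf)
  expect_equal(back$min_distance, ct$min_distance)
  expect_equal(back$covered, ct$covered)
  expect_equal(label_binding_regions(rs, back)$status, c("positive", "negative"))
})

test_that("identity baseline computes global-alignment identity", {
  templates <- data.frame(sequence = c("ABCD", "MMMM"), label = c(1, 0))
  expect_equal(identity_baseline("ABCD", templates), 1.0)
  expect_equal(identity_baseline("ABED", templates), 0.75)
  expect_equal(identity_baseline("QQQQ", templates), 0.0)
  # maximum over positive templates only
  t2 <- data.frame(sequence = c("ABCD", "ABEE"), label = c(1, 1))
  expect_equal(identity_baseline("ABEE", t2), 1.0)
  expect_error(identity_baseline("ABCD",
                                 data.frame(sequence = "A", label = 0)),
               "positive template")
})

test_that("BLAST outfmt-6 tables import with fractional identity", {
  tf <- tempfile()
  writeLines(paste(c("q1", "s1", "98.50", "100", "1", "0", "1", "100",
                     "1", "100", "1e-50", "190"), collapse = "\t"), tf)
  out <- read_blast_outfmt6(tf)
  expect_equal(out$identity, 0.985)
  expect_equal(out$query, "q1")
  expect_equal(out$bitscore, 190)
})

test_that("method comparison uses the stated sign convention", {
  set.seed(77)
  scores <- runif(80); labels <- rbinom(80, 1, 0.4)
  labels[1] <- 1; labels[2] <- 0
  better <- pmin(1, scores + 0.4 * labels)  # strictly better ranking
  a <- bootstrap_aupr(better, labels, n_boot = 300, seed = 3)
  b <- bootstrap_aupr(scores, labels, n_boot = 300, seed = 3)
  cmp <- compare_methods(a, b)
  expect_gt(cmp$delta_median, 0)  # region-specific method wins -> positive
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$delta_median, median(a$boot) - median(b$boot))
  expect_error(compare_methods(a, bootstrap_aupr(scores, labels,
                                                 n_boot = 300, seed = 4)),
               "not paired")
})
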