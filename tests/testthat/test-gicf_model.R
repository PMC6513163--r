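# The group-instance cost function: scoring, cost, gradient, seeding, fit.

test_that("logistic scores and max aggregation follow their closed forms", {
  X <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("f1", "f2")))
  expect_equal(unname(score_region(c(0, 0), X)), c(0.5, 0.5))
  expect_equal(unname(score_region(c(log(3), 0), X)), c(0.75, 0.5))
  expect_equal(unname(score_region(c(-log(3), 0), X)), c(0.25, 0.5))
  # stable at extreme linear predictors
  expect_equal(unname(score_region(c(1000, 0), X)), c(1, 0.5))
  expect_error(score_region(c(1, 2, 3), X), "dimension")

  expect_equal(aggregate_protein(c(0.2, 0.8)), 0.8)
  expect_equal(aggregate_protein(0.5), 0.5)
  expect_equal(aggregate_protein(c(0.4, 0.4, 0.4)), 0.4)
  expect_error(aggregate_protein(numeric()), "empty")
})

# shared toy construction: explicit matrices so each term is auditable
toy_data <- function(yhat_target, K, Y, r_plus = character()) {
  n <- length(yhat_target)
  rid <- paste0("P1:", seq_len(n))
  # a diagonal design realizes any target score vector via theta
  X <- diag(n)
  dimnames(X) <- list(rid, paste0("f", seq_len(n)))
  theta <- setNames(log(yhat_target / (1 - yhat_target)), colnames(X))
  dimnames(K) <- list(rid, rid)
  data <- gicf_data(X, rep("P1", n), K, c(P1 = Y), r_plus)
  list(data = data, theta = theta)
}

test_that("cost reproduces hand-computed values exactly", {
  # 1 protein, 1 region, theta = 0, Y = 1, no anchors, lam = 0:
  # J = (0.5 - 1)^2 = 0.25
  td <- toy_data(0.5, matrix(1, 1, 1), Y = 1)
  expect_equal(as.numeric(gicf_cost(td$theta, td$data, w1 = 1, w2 = 1, lam = 0)),
               0.25, tolerance = 1e-12)

  # 2 regions scoring (0.2, 0.8), full kernel, Y = 1, w1 = 1:
  # J = (0.8-1)^2 + (1/4) * 2 * (0.8-0.2)^2 = 0.04 + 0.18 = 0.22
  td <- toy_data(c(0.2, 0.8), matrix(1, 2, 2), Y = 1)
  expect_equal(as.numeric(gicf_cost(td$theta, td$data, w1 = 1, w2 = 1, lam = 0)),
               0.22, tolerance = 1e-12)

  # perfect hard predictions, orthogonal kernel, lam = 0 -> J = 0
  td <- toy_data(c(1 - 1e-16, 1e-16), diag(2), Y = 1)
  expect_equal(as.numeric(gicf_cost(td$theta, td$data, w1 = 1, w2 = 1, lam = 0)),
               0, tolerance = 1e-12)
})

test_that("cost agrees with the brute-force oracle on random instances", {
  for (seed in 1:12) {
    inst <- toy_gicf_instance(seed)
    w1 <- runif(1, 0, 2); w2 <- runif(1, 0, 2); lam <- runif(1, 0, 2)
    data <- gicf_data(inst$X, inst$rp, inst$K, inst$Y, inst$r_plus)
    got <- as.numeric(gicf_cost(inst$theta, data, w1, w2, lam))
    want <- oracle_cost(inst$theta, inst$X, inst$rp, inst$Y, inst$r_plus,
                        inst$K, w1, w2, lam)
    expect_equal(got, want, tolerance = 1e-10)
    expect_gte(got, 0)
  }
})

test_that("the kernel diagonal contributes nothing to the smoothness term", {
  inst <- toy_gicf_instance(5)
  data <- gicf_data(inst$X, inst$rp, inst$K, inst$Y)
  K0 <- inst$K; diag(K0) <- 0
  data0 <- gicf_data(inst$X, inst$rp, K0, inst$Y)
  expect_equal(as.numeric(gicf_cost(inst$theta, data, 1.7, 0, 0.3)),
               as.numeric(gicf_cost(inst$theta, data0, 1.7, 0, 0.3)),
               tolerance = 1e-12)
})

test_that("empty anchor sets zero the third term", {
  inst <- toy_gicf_instance(6)
  d0 <- gicf_data(inst$X, inst$rp, inst$K, inst$Y, character())
  dr <- gicf_data(inst$X, inst$rp, inst$K, inst$Y, inst$r_plus)
  j0 <- as.numeric(gicf_cost(inst$theta, d0, 0, 5, 0))
  jr <- as.numeric(gicf_cost(inst$theta, dr, 0, 5, 0))
  expect_gt(jr, j0)  # anchors add a penalty at imperfect scores
  base <- oracle_cost(inst$theta, inst$X, inst$rp, inst$Y, character(),
                      inst$K, 0, 5, 0)
  expect_equal(j0, base, tolerance = 1e-12)
})

test_that("analytic gradient matches central differences on 100 draws", {
  worst <- 0
  for (seed in 1:100) {
    inst <- toy_gicf_instance(seed, n_prot = 3L, n_feat = 4L)
    w1 <- runif(1, 0, 2); w2 <- runif(1, 0, 2); lam <- runif(1, 0, 2)
    data <- gicf_data(inst$X, inst$rp, inst$K, inst$Y, inst$r_plus)
    g <- gicf_gradient(inst$theta, data, w1, w2, lam)
    num <- numerical_gradient(function(th) {
      as.numeric(gicf_cost(setNames(th, names(inst$theta)), data, w1, w2, lam))
    }, inst$theta)
    rel <- sqrt(sum((g - num)^2)) / max(sqrt(sum(num^2)), 1e-8)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("closed-form gradients: flat scores and ridge-only models", {
  # theta = 0: all scores equal, smoothness term has zero gradient
  inst <- toy_gicf_instance(3)
  data <- gicf_data(inst$X, inst$rp, inst$K, inst$Y)
  th0 <- setNames(rep(0, ncol(inst$X)), colnames(inst$X))
  g <- gicf_gradient(th0, data, w1 = 3, w2 = 0, lam = 0)
  g_nok <- gicf_gradient(th0, data, w1 = 0, w2 = 0, lam = 0)
  expect_equal(g, g_nok, tolerance = 1e-12)

  # ridge-only gradient is 2*lam*theta/Np with the intercept excluded
  g_ridge <- gicf_gradient(inst$theta, data, w1 = 0, w2 = 0, lam = 2) -
    gicf_gradient(inst$theta, data, w1 = 0, w2 = 0, lam = 0)
  Np <- length(unique(inst$rp))
  want <- 2 * 2 * inst$theta / Np
  want["(Intercept)"] <- 0
  expect_equal(g_ridge, want, tolerance = 1e-10)
})

test_that("seed fit separates a separable toy set and honors the grid", {
  set.seed(11)
  X <- Matrix::Matrix(rbind(matrix(rnorm(40, 3), 10, 4),
                            matrix(rnorm(40, -3), 10, 4)), sparse = TRUE)
  rownames(X) <- sprintf("P%02d", 1:20)
  colnames(X) <- paste0("f", 1:4)
  y <- setNames(rep(c(1, 0), each = 10), rownames(X))
  fit <- seed_theta(X, y)
  expect_equal(fit$aupr, 1.0)
  expect_true(fit$lambda %in% c(0.1, 1, 10, 100))
  scores <- score_region(fit$theta, add_intercept(X))
  expect_equal(aupr(scores, y), 1.0)
  expect_error(seed_theta(X, setNames(rep(1, 20), rownames(X))),
               "both classes")
})

test_that("training honors degenerate configurations", {
  inst <- toy_gicf_instance(9)
  data <- gicf_data(inst$X, inst$rp, inst$K, inst$Y)
  # zero learning rate leaves theta unchanged
  m <- gicf_fit(inst$theta, data,
                config = optimizer_config(learning_rate = 0, max_epochs = 3,
                                          early_stop_patience = 100))
  expect_equal(m$theta, inst$theta)
  # w1 = w2 = lam = 0 reduces to MIL logistic regression on the protein
  # term only: its cost equals the oracle with those weights
  j <- as.numeric(gicf_cost(inst$theta, data, 0, 0, 0))
  expect_equal(j, oracle_cost(inst$theta, inst$X, inst$rp, inst$Y,
                              character(), inst$K, 0, 0, 0),
               tolerance = 1e-12)
})

test_that("training reduces the cost on a small instance", {
  inst <- toy_gicf_instance(13, n_prot = 6L, n_feat = 6L)
  data <- gicf_data(inst$X, inst$rp, inst$K, inst$Y)
  j0 <- as.numeric(gicf_cost(inst$theta, data, 1, 1, 0.1))
  m <- gicf_fit(inst$theta, data, w1 = 1, w2 = 1, lam = 0.1,
                config = optimizer_config(learning_rate = 0.3,
                                          max_epochs = 80, batch_size = 6L,
                                          early_stop_patience = 80))
  j1 <- as.numeric(gicf_cost(m$theta, data, 1, 1, 0.1))
  expect_lt(j1, j0)
  expect_true(all(is.finite(m$trace$cost)))
})

test_that("pair-sampled smoothness approximates the exact term", {
  inst <- toy_gicf_instance(21, n_prot = 5L, n_feat = 4L)
  data <- gicf_data(inst$X, inst$rp, inst$K, inst$Y)
  exact <- attr(gicf_cost(inst$theta, data, w1 = 2, w2 = 0, lam = 0),
                "terms")[2]
  # the sampled estimator is unbiased over pair draws: with many pairs a
  # single draw lands close to the exact within-batch term
  approx <- regionprop:::.gicf_terms(inst$theta, data, w1 = 2, w2 = 0,
                                     lam = 0, pair_sample = 20000L,
                                     pair_seed = 3L)
  expect_equal(approx$terms[2], exact, tolerance = 0.05)
  expect_true(all(is.finite(approx$grad)))
})

test_that("prediction projects onto the training vocabulary and aggregates", {
  theta <- c(f1 = 2, f2 = -1, `(Intercept)` = 0.5)
  model <- structure(list(theta = theta), class = "gicf_model")
  X <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("A:1", "A:2"), c("f1", "fX")))
  pred <- gicf_predict(model, X, region_protein = c("A", "A"),
                       aggregate = TRUE)
  # fX is unseen -> dropped; f2 absent -> zero contribution
  expect_equal(unname(pred$region_scores),
               plogis(c(2 + 0.5, 0.5)), tolerance = 1e-12)
  expect_equal(unname(pred$protein_scores["A"]),
               max(pred$region_scores))
  # raising one region score never lowers the protein score
  X2 <- X; X2["A:2", "f1"] <- 5
  pred2 <- gicf_predict(model, X2, region_protein = c("A", "A"),
                        aggregate = TRUE)
  expect_gte(pred2$protein_scores["A"], pred$protein_scores["A"])
})

test_that("model archives round-trip through JSON", {
  inst <- toy_gicf_instance(4)
  data <- gicf_data(inst$X, inst$rp, inst$K, inst$Y)
  m <- gicf_fit(inst$theta, data,
                config = optimizer_config(max_epochs = 2,
                                          early_stop_patience = 5),
                go_id = "GO:0003677", space = "SIG")
  m$idf <- c(f1 = 1.2, f2 = 2.2)
  tf <- tempfile(fileext = ".json")
  write_gicf_model(m, tf)
  back <- read_gicf_model(tf)
  expect_equal(back$theta, m$theta)
  expect_equal(back$go_id, "GO:0003677")
  expect_equal(back$idf, m$idf)
  expect_equal(back$lam, m$lam)
})
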