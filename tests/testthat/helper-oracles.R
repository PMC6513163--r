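# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation (dense loops,
# enumeration) kept separate from the code paths it checks.

# Eq-by-eq brute-force evaluation of the four-term cost: dense loops over
# every protein, every region pair and every anchor.
oracle_cost <- function(theta, X, region_protein, Y, r_plus,
                        K, w1, w2, lam, intercept = "(Intercept)") {
  X <- as.matrix(X)
  yhat <- 1 / (1 + exp(-as.numeric(X %*% theta)))
  names(yhat) <- rownames(X)
  prots <- unique(region_protein)
  t1 <- 0
  for (p in prots) {
    Yhat <- max(yhat[region_protein == p])
    t1 <- t1 + (Yhat - Y[[p]])^2
  }
  t1 <- t1 / length(prots)
  n <- nrow(X)
  t2 <- 0
  Kd <- as.matrix(K)[rownames(X), rownames(X), drop = FALSE]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    t2 <- t2 + Kd[i, j] * (yhat[i] - yhat[j])^2
  }
  t2 <- w1 * t2 / n^2
  t3 <- 0
  if (length(r_plus) > 0) {
    for (i in r_plus) t3 <- t3 + (yhat[[i]] - 1)^2
    t3 <- w2 * t3 / length(r_plus)
  }
  mask <- names(theta) != intercept
  t4 <- lam * sum(theta[mask]^2) / length(prots)
  as.numeric(t1 + t2 + t3 + t4)
}

# Central-difference numerical gradient of any scalar function.
numerical_gradient <- function(f, theta, eps = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}

# Brute-force average precision: walk the full PR curve over all distinct
# thresholds, grouping ties; precision recorded after each whole group.
oracle_aupr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  P <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  tp_prev <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(labels[called])
    prec <- tp / sum(called)
    ap <- ap + (tp - tp_prev) * prec
    tp_prev <- tp
  }
  ap / P
}

# Exact two-tailed signed-rank p-value by enumerating all sign vectors.
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1.0)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    Ws[m + 1] <- sum(r[signs == 1])
  }
  mu <- n * (n + 1) / 4
  p <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
  min(1, p)
}

# A small deterministic protein + annotation builder.
toy_protein <- function(accession = "P1", length = 100L) {
  data.frame(accession = accession,
             sequence = strrep("ACDEFGHIKL", ceiling(length / 10)) |>
               substr(1, length),
             length = as.integer(length), stringsAsFactors = FALSE)
}

toy_annotation <- function(accession, type, start, end, id = "X1",
                           ipr = NA_character_, desc = "toy feature",
                           db = "TOYDB") {
  data.frame(protein_accession = accession, source_db = db,
             entry_type = type, entry_id = id, interpro_id = ipr,
             description = desc, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

# Small dense gicf instance with reproducible randomness.
toy_gicf_instance <- function(seed, n_prot = 3L, n_feat = 5L) {
  set.seed(seed)
  nreg <- sample(1:3, n_prot, replace = TRUE)
  n <- sum(nreg)
  rp <- rep(sprintf("P%d", seq_len(n_prot)), nreg)
  rid <- paste0(rp, ":", unlist(lapply(nreg, seq_len)))
  X <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(rid, sprintf("f%d", seq_len(n_feat))))
  X <- cbind(X, `(Intercept)` = 1)
  K <- crossprod(matrix(runif(n * n), n, n)) / n
  K <- K / max(K)
  diag(K) <- 1
  dimnames(K) <- list(rid, rid)
  Y <- setNames(sample(0:1, n_prot, replace = TRUE), unique(rp))
  if (all(Y == Y[1])) Y[1] <- 1 - Y[1]
  r_plus <- rid[sample.int(n, min(2L, n))]
  theta <- setNames(rnorm(n_feat + 1, sd = 0.5), colnames(X))
  list(X = X, K = K, rp = rp, Y = Y, r_plus = r_plus, theta = theta)
}
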