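# Per-GO-term region scoring with a group-instance cost function.
#
# Regions are scored by a logistic model s(theta' x); a protein's score is
# the maximum over its regions.  Training minimizes a four-term objective:
#
#   J(theta) = (1/Np)   sum_k ( Yhat_k - Y_k )^2                 protein fit
#            + (w1/Nr^2) sum_ij kappa(x_i, x_j) (yhat_i - yhat_j)^2   smoothness
#            + (w2/Nr+)  sum_{i in r+} ( yhat_i - 1 )^2          known anchors
#            + (lam/Np)  ||theta||^2                             ridge
#
# with square loss throughout, max aggregation Yhat_k = max_i yhat_i, and
# the third term defined as 0 when r+ is empty.  The max is handled by a
# subgradient through the argmax region (ties to the lowest region index).
# A constant intercept feature is appended to every vector and excluded
# from the ridge penalty.

INTERCEPT_NAME <- "(Intercept)"

# Append the constant intercept column to a weights matrix.
add_intercept <- function(W) {
  one <- Matrix::Matrix(1, nrow = nrow(W), ncol = 1L, sparse = TRUE,
                        dimnames = list(rownames(W), INTERCEPT_NAME))
  as(as(cbind(W, one), "generalMatrix"), "CsparseMatrix")
}

#' Logistic region scores
#'
#' `yhat_i = 1 / (1 + exp(-theta . x_i))`, numerically stable for large
#' magnitudes of the linear predictor.
#'
#' @param theta Weight vector (named by feature, including the intercept
#'   when `X` carries one).
#' @param X Feature matrix (items x features), dense or sparse.
#' @return Numeric vector of scores in `[0, 1]`, named by row.
#' @export
score_region <- function(theta, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list("x", names(X)))
  .assert(ncol(X) == length(theta),
          "dimension mismatch: %d features vs %d weights", ncol(X), length(theta))
  z <- as.numeric(X %*% theta)
  setNames(plogis(z), rownames(X))
}

#' Aggregate region scores into a protein score
#'
#' Max aggregation: a protein has a function if at least one region does.
#'
#' @param region_scores Nonempty numeric vector of region scores.
#' @return The maximum score.
#' @export
aggregate_protein <- function(region_scores) {
  .assert(length(region_scores) >= 1L, "cannot aggregate an empty score list")
  max(region_scores)
}

#' Bundle training data for the cost function
#'
#' @param X Region weights matrix (regions x features, intercept included),
#'   rownames are region ids.
#' @param region_protein Character vector mapping each row of `X` to its
#'   protein accession.
#' @param kernel A `similarity_kernel` over the same region ids (its
#'   `values` matrix is subset/reordered to match `X`).
#' @param protein_labels Named 0/1 vector of protein labels (Y).
#' @param positive_regions Character vector of known positive region ids
#'   (the anchor set r+); may be empty.
#' @return A list of class `gicf_data`.
#' @export
gicf_data <- function(X, region_protein, kernel, protein_labels,
                      positive_regions = character()) {
  .assert(length(region_protein) == nrow(X),
          "region_protein length must match rows of X")
  .assert(all(region_protein %in% names(protein_labels)),
          "every region must belong to a labelled protein")
  K <- if (inherits(kernel, "similarity_kernel")) kernel$values else kernel
  .assert(all(rownames(X) %in% rownames(K)), "kernel is missing regions")
  K <- K[rownames(X), rownames(X), drop = FALSE]
  .assert(all(positive_regions %in% rownames(X)),
          "positive_regions must be rows of X")
  structure(list(X = X, region_protein = region_protein, K = K,
                 Y = protein_labels[unique(region_protein)],
                 positive_regions = positive_regions),
            class = "gicf_data")
}

# Core evaluation shared by cost and gradient.  `rows` selects a protein
# minibatch (all rows by default); the data-sum normalizers (N_p, N_r^2,
# N_r+) are rescaled to their batch counterparts so term magnitudes stay
# comparable, while the ridge term keeps the full-data N_p (it is not a
# data sum, so its batch gradient would otherwise be inflated by the
# number of batches per epoch).
.gicf_terms <- function(theta, data, w1, w2, lam, rows = NULL,
                        pair_sample = 0L, pair_seed = NULL) {
  X <- data$X; rp <- data$region_protein
  if (!is.null(rows)) {
    X <- X[rows, , drop = FALSE]
    rp <- rp[rows]
  }
  prots <- unique(rp)
  Np <- length(prots)
  Np_full <- length(data$Y)
  Nr <- nrow(X)
  yhat <- as.numeric(X %*% theta)
  yhat <- plogis(yhat)
  g <- yhat * (1 - yhat)

  # term 1: squared error of max-aggregated protein scores, subgradient
  # through the first-attained maximum
  idx_by_prot <- split(seq_len(Nr), factor(rp, levels = prots))
  c1 <- numeric(Nr)
  t1 <- 0
  for (k in seq_len(Np)) {
    idx <- idx_by_prot[[k]]
    j <- idx[which.max(yhat[idx])]
    resid <- yhat[j] - data$Y[[prots[k]]]
    t1 <- t1 + resid^2
    c1[j] <- c1[j] + 2 * resid
  }
  t1 <- t1 / Np
  c1 <- c1 / Np

  # term 2: kernel-weighted smoothness
  if (w1 > 0 && Nr > 1L) {
    if (pair_sample > 0L) {
      np <- as.integer(pair_sample)
      ij <- .with_seed(pair_seed %||% 0L,
                       cbind(sample.int(Nr, np, replace = TRUE),
                             sample.int(Nr, np, replace = TRUE)))
      K <- data$K[rownames(X), rownames(X), drop = FALSE]
      kv <- K[ij]
      dv <- yhat[ij[, 1L]] - yhat[ij[, 2L]]
      t2 <- w1 * mean(kv * dv^2)
      d2 <- numeric(Nr)
      contrib <- 2 * kv * dv / np
      for (s in seq_len(np)) {
        d2[ij[s, 1L]] <- d2[ij[s, 1L]] + contrib[s]
        d2[ij[s, 2L]] <- d2[ij[s, 2L]] - contrib[s]
      }
      c2 <- w1 * d2
    } else {
      K <- data$K[rownames(X), rownames(X), drop = FALSE]
      r <- Matrix::rowSums(K)
      Ky <- as.numeric(K %*% yhat)
      t2 <- (w1 / Nr^2) * (2 * sum(yhat^2 * r) - 2 * sum(yhat * Ky))
      c2 <- (4 * w1 / Nr^2) * (yhat * r - Ky)
    }
  } else {
    t2 <- 0; c2 <- numeric(Nr)
  }

  # term 3: known positive region anchors (0 when the batch carries none)
  rpos <- intersect(data$positive_regions, rownames(X))
  nrp <- length(rpos)
  c3 <- numeric(Nr)
  if (w2 > 0 && nrp > 0L) {
    pi <- match(rpos, rownames(X))
    t3 <- (w2 / nrp) * sum((yhat[pi] - 1)^2)
    c3[pi] <- (2 * w2 / nrp) * (yhat[pi] - 1)
  } else t3 <- 0

  # term 4: ridge, intercept excluded, always normalized by the full
  # protein count
  mask <- rep(1, length(theta))
  ii <- match(INTERCEPT_NAME, colnames(X))
  if (!is.na(ii)) mask[ii] <- 0
  t4 <- (lam / Np_full) * sum((theta * mask)^2)

  grad <- as.numeric(Matrix::crossprod(X, (c1 + c2 + c3) * g)) +
    (2 * lam / Np_full) * theta * mask
  list(cost = t1 + t2 + t3 + t4, terms = c(t1, t2, t3, t4),
       grad = setNames(grad, colnames(X)), yhat = yhat)
}

#' Evaluate the four-term cost
#'
#' @param theta Weight vector aligned with the columns of `data$X`.
#' @param data A `gicf_data` bundle.
#' @param w1,w2,lam Non-negative term weights (smoothness, anchors, ridge).
#' @return The scalar cost `J(theta) >= 0`, with the per-term breakdown in
#'   attribute `"terms"`.
#' @export
gicf_cost <- function(theta, data, w1 = 1, w2 = 1, lam = 1) {
  out <- .gicf_terms(theta, data, w1, w2, lam)
  structure(out$cost, terms = out$terms)
}

#' Analytic gradient of the cost
#'
#' Matches a central-difference numerical gradient to ~1e-5 relative error
#' on small instances (see the test suite).  On a protein minibatch the
#' normalizers are rescaled to batch counts.
#'
#' @inheritParams gicf_cost
#' @param rows Optional integer rows of `data$X` forming the batch (all
#'   regions of a subset of proteins).
#' @return Named gradient vector dJ/dtheta.
#' @export
gicf_gradient <- function(theta, data, w1 = 1, w2 = 1, lam = 1, rows = NULL) {
  .gicf_terms(theta, data, w1, w2, lam, rows = rows)$grad
}

#' Optimizer settings for minibatch SGD with momentum
#'
#' Defaults: learning rate 0.1 with `1/sqrt(epoch)` decay, momentum 0.9,
#' 32 proteins per batch, at most 200 epochs, early stopping after 10
#' epochs without validation improvement, exact within-batch smoothness
#' (`pair_sample = 0`).
#'
#' @param learning_rate,momentum,batch_size,max_epochs,pair_sample,early_stop_patience,seed
#'   See description.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(learning_rate = 0.1, momentum = 0.9,
                             batch_size = 32L, max_epochs = 200L,
                             pair_sample = 0L, early_stop_patience = 10L,
                             seed = 1L) {
  .assert(learning_rate >= 0 && momentum >= 0 && momentum < 1,
          "invalid optimizer settings")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 pair_sample = as.integer(pair_sample),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Seed weights from a whole-protein logistic regression
#'
#' Fits an L2-regularized logistic regression on whole-protein feature
#' vectors and known protein labels, selecting the regularization weight
#' from a grid by validation AUPR (training AUPR when no validation set is
#' given).  The returned weights double as the whole-protein baseline
#' `theta_base` and as the seed `theta` for [gicf_fit()].
#'
#' @param X_protein Protein weights matrix (proteins x features, no
#'   intercept column; one is handled internally), rownames accessions.
#' @param labels Named 0/1 vector over the rows of `X_protein`.
#' @param lam_grid Ridge grid, default `c(0.1, 1, 10, 100)`.
#' @param validation Optional list with `X` and `labels` for model
#'   selection.
#' @return List with `theta` (named, intercept last), `lambda` (chosen
#'   grid value) and `aupr` (selection-set AUPR).
#' @export
seed_theta <- function(X_protein, labels, lam_grid = c(0.1, 1, 10, 100),
                       validation = NULL) {
  y <- labels[rownames(X_protein)]
  .assert(length(unique(y)) == 2L, "seed fit needs both classes")
  n <- nrow(X_protein)
  # glmnet ridge minimizes -(1/n) loglik + lambda_g ||beta||^2 / 2;
  # lambda_g = 2*lam/n matches a (lam/n) ||theta||^2 penalty.
  lam_grid <- sort(lam_grid, decreasing = TRUE)
  fit <- glmnet::glmnet(X_protein, y, family = "binomial", alpha = 0,
                        lambda = 2 * lam_grid / n, standardize = FALSE,
                        thresh = 1e-10)
  sel_X <- if (is.null(validation)) X_protein else validation$X
  sel_y <- if (is.null(validation)) y else validation$labels[rownames(sel_X)]
  best <- NULL
  for (s in seq_along(fit$lambda)) {
    beta <- as.numeric(fit$beta[, s])
    th <- setNames(c(beta, fit$a0[[s]]),
                   c(colnames(X_protein), INTERCEPT_NAME))
    scores <- score_region(th, add_intercept(sel_X))
    a <- aupr(scores, sel_y)
    if (is.null(best) || a > best$aupr) {
      best <- list(theta = th, lambda = lam_grid[s], aupr = a)
    }
  }
  best
}

#' Train the region-scoring model
#'
#' Minibatch stochastic gradient descent with momentum from a seeded
#' `theta`; batches are whole proteins with all their regions.  After each
#' epoch the protein-level AUPR on the validation set is computed and the
#' best-so-far weights are kept (early stopping); without a validation set
#' the training cost is monitored instead.
#'
#' @param theta0 Seed weights (named, aligned with `data$X` columns).
#' @param data A `gicf_data` bundle.
#' @param w1,w2,lam Term weights (defaults 1, 1, 1).
#' @param config An [optimizer_config()].
#' @param validation Optional list with `X` (regions x features, intercept
#'   included), `region_protein` and `labels` (named 0/1 per protein).
#' @return A list of class `gicf_model`: `go_id`, `space`, `theta`,
#'   hyperparameters, the optimizer config, and a per-epoch `trace`
#'   data.frame (cost and selection metric).
#' @export
gicf_fit <- function(theta0, data, w1 = 1, w2 = 1, lam = 1,
                     config = optimizer_config(), validation = NULL,
                     go_id = NA_character_, space = NA_character_) {
  .assert(length(theta0) == ncol(data$X), "theta0/feature dimension mismatch")
  theta <- theta0
  velocity <- numeric(length(theta))
  prots <- unique(data$region_protein)
  rows_by_prot <- split(seq_len(nrow(data$X)),
                        factor(data$region_protein, levels = prots))

  metric_of <- function(th) {
    if (is.null(validation)) {
      return(-as.numeric(gicf_cost(th, data, w1, w2, lam)))
    }
    sc <- score_region(th, validation$X)
    ps <- tapply(sc, validation$region_protein, max)
    aupr(as.numeric(ps), validation$labels[names(ps)])
  }

  best_theta <- theta
  best_metric <- metric_of(theta)
  best_cost <- as.numeric(gicf_cost(theta, data, w1, w2, lam))
  trace <- data.frame(epoch = 0L, cost = best_cost, metric = best_metric)
  stall <- 0L
  last_best_any <- best_metric
  min_cost <- best_cost
  .with_seed(.derive_seed(config$seed, 17L), {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$learning_rate / sqrt(epoch)
      order_p <- sample(length(prots))
      nb <- ceiling(length(prots) / config$batch_size)
      for (b in seq_len(nb)) {
        sel <- order_p[((b - 1L) * config$batch_size + 1L):
                         min(b * config$batch_size, length(prots))]
        rows <- unlist(rows_by_prot[sel], use.names = FALSE)
        out <- .gicf_terms(theta, data, w1, w2, lam, rows = rows,
                           pair_sample = config$pair_sample,
                           pair_seed = .derive_seed(config$seed, epoch * 1000L + b))
        velocity <- config$momentum * velocity - lr * out$grad
        theta <- theta + velocity
      }
      J <- as.numeric(gicf_cost(theta, data, w1, w2, lam))
      if (!is.finite(J)) {
        stop(sprintf("training diverged at epoch %d (learning rate %.4g)",
                     epoch, lr), call. = FALSE)
      }
      m <- metric_of(theta)
      trace <- rbind(trace, data.frame(epoch = epoch, cost = J, metric = m))
      # selection: best validation metric wins; on a tied metric (e.g. a
      # saturated protein-level AUPR) the lower training cost breaks the
      # tie, so optimization can keep refining region scores
      if (m > best_metric + 1e-12 ||
          (m >= best_metric - 1e-12 && J < best_cost - 1e-12)) {
        best_metric <- max(m, best_metric)
        best_cost <- J
        best_theta <- theta
      }
      # patience: training continues while either the validation metric or
      # the training cost is still improving (a transient metric dip must
      # not freeze the optimizer at the seed)
      if (m > last_best_any + 1e-12 || J < min_cost - 1e-9) {
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
      last_best_any <- max(last_best_any, m)
      min_cost <- min(min_cost, J)
    }
  })
  structure(list(go_id = go_id, space = space, theta = best_theta,
                 w1 = w1, w2 = w2, lam = lam, config = config,
                 best_metric = best_metric, trace = trace),
            class = "gicf_model")
}

#' @export
print.gicf_model <- function(x, ...) {
  cat(sprintf(
    "gicf_model [%s, %s]: %d weights, w1=%g w2=%g lambda=%g, %d epoch(s)\n",
    x$go_id, x$space, length(x$theta), x$w1, x$w2, x$lam,
    max(x$trace$epoch)))
  invisible(x)
}

#' Score regions and/or proteins with a trained model
#'
#' Feature matrices over a different vocabulary are projected onto the
#' training vocabulary (unseen features dropped, missing ones zero).
#'
#' @param model A `gicf_model` (or any list with a named `theta`).
#' @param X Regions x features weights matrix; an intercept column is
#'   appended when absent.
#' @param region_protein Optional protein accession per row; required for
#'   `aggregate = TRUE`.
#' @param aggregate Also return max-aggregated protein scores.
#' @return A list with `region_scores` and (optionally) `protein_scores`.
#' @export
gicf_predict <- function(model, X, region_protein = NULL, aggregate = FALSE) {
  theta <- model$theta
  if (!INTERCEPT_NAME %in% colnames(X)) X <- add_intercept(X)
  pos <- match(colnames(X), names(theta))
  Xp <- X[, !is.na(pos), drop = FALSE]
  th <- theta[match(colnames(Xp), names(theta))]
  rs <- score_region(th, Xp)
  out <- list(region_scores = rs)
  if (aggregate) {
    .assert(!is.null(region_protein), "aggregate = TRUE needs region_protein")
    ps <- tapply(rs, region_protein, max)
    out$protein_scores <- setNames(as.numeric(ps), names(ps))
  }
  out
}

#' Serialize a trained model to JSON
#'
#' The archive holds the GO term, feature space, vocabulary (via the theta
#' names), weights, hyperparameters, optimizer config and loss trace.
#'
#' @param model A `gicf_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gicf_model <- function(model, path) {
  obj <- list(
    format = "regionprop-gicf-1",
    go_id = model$go_id, space = model$space,
    theta = as.list(model$theta),
    w1 = model$w1, w2 = model$w2, lam = model$lam,
    config = unclass(model$config),
    trace = model$trace
  )
  if (!is.null(model$idf)) obj$idf <- as.list(model$idf)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_gicf_model()]
#'
#' @param path Path to the JSON archive.
#' @return A `gicf_model`.
#' @export
read_gicf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  .assert(identical(obj$format, "regionprop-gicf-1"),
          "unrecognized model archive format in %s", path)
  structure(list(go_id = obj$go_id, space = obj$space,
                 theta = unlist(obj$theta),
                 w1 = obj$w1, w2 = obj$w2, lam = obj$lam,
                 config = do.call(optimizer_config, obj$config),
                 trace = obj$trace,
                 idf = if (!is.null(obj$idf)) unlist(obj$idf)),
            class = "gicf_model")
}
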