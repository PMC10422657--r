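DETECTOR_KINDS <- c("decision_tree", "random_forest", "svm", "autoencoder")

#' Lightweight detector configuration
#'
#' Default hyperparameters follow the grid-search optima reported for
#' window-level MW-PPG artifact detection:
#' * decision tree — Gini split criterion, maximum depth 15;
#' * random forest — Gini, maximum depth 10, 10 estimators,
#'   `floor(sqrt(p))` features tried per split;
#' * SVM — Gaussian (RBF) kernel with `gamma = 1e-4`, misclassification
#'   penalty `C = 1` (trained by dual coordinate descent; prediction is by
#'   decision-function sign, so the reported probability-estimate switch has
#'   no effect on binary window labels);
#' * autoencoder — four fully connected layers with five-neuron ReLU hidden
#'   layers and linear input/output of width equal to the feature-vector
#'   length, trained full-batch for a fixed epoch budget (default 1000).
#'
#' @param kind one of `r paste(DETECTOR_KINDS, collapse = ", ")`.
#' @param max_depth tree depth cap (default 15 for the decision tree, 10 for
#'   forest members).
#' @param n_estimators forest size (default 10).
#' @param minsplit,minbucket minimum node size to split / minimum leaf size.
#' @param gamma RBF kernel width (default 1e-4).
#' @param cost SVM misclassification penalty (default 1).
#' @param svm_epochs dual-coordinate-descent epoch cap (default 400; sweeps
#'   stop early once the maximum projected-gradient violation is below
#'   1e-3).
#' @param hidden autoencoder hidden width (default 5).
#' @param epochs autoencoder training epochs (default 1000; full-batch Adam
#'   needs on the order of 500 epochs to reach its reconstruction-loss
#'   plateau on standardized custom-set features, so a few hundred epochs
#'   underfits).
#' @param lr autoencoder learning rate (default 0.01, Adam).
#' @param seed training seed (bootstrap draws, feature sampling, weight
#'   init).
#' @return an object of class `mwppg_detector_config`.
#' @export
detector_config <- function(kind = DETECTOR_KINDS, max_depth = NULL,
                            n_estimators = 10, minsplit = 20, minbucket = 7,
                            gamma = 1e-4, cost = 1, svm_epochs = 400,
                            hidden = 5, epochs = 1000, lr = 0.01,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(max_depth)) {
    max_depth <- if (kind == "decision_tree") 15L else 10L
  }
  abort_if(max_depth < 1 || n_estimators < 1,
           "depths and estimator counts must be positive")
  structure(list(kind = kind, max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators),
                 minsplit = minsplit, minbucket = minbucket, gamma = gamma,
                 cost = cost, svm_epochs = svm_epochs, hidden = hidden,
                 epochs = epochs, lr = lr, seed = seed),
            class = "mwppg_detector_config")
}

#' Train an anomaly detector on a feature matrix
#'
#' Supervised kinds (tree, forest, SVM) fit the train labels directly and
#' require both classes in the train split. The autoencoder fits its
#' reconstruction on the normal-labeled training rows only; its decision
#' threshold on the mean squared reconstruction error is chosen on the
#' validation split to maximize F1 (falling back to the 95th percentile of
#' the normal training errors when no validation rows are supplied).
#' Training is deterministic under a fixed config seed.
#'
#' @param cfg an [detector_config()].
#' @param train an `mwppg_features` (the train split).
#' @param val optional `mwppg_features` used for autoencoder threshold
#'   calibration.
#' @return an object of class `mwppg_detector`.
#' @export
train_detector <- function(cfg, train, val = NULL) {
  abort_if(!inherits(cfg, "mwppg_detector_config"), "cfg must be a config")
  x <- train$x
  y <- train$labels
  abort_if(nrow(x) == 0, "train matrix is empty")
  if (cfg$kind != "autoencoder") {
    abort_if(length(unique(y)) < 2,
             "supervised detectors need both classes in the train split")
  }
  fit <- with_seed(cfg$seed, switch(cfg$kind,
    decision_tree = cart_fit(x, y, max_depth = cfg$max_depth,
                             minsplit = cfg$minsplit,
                             minbucket = cfg$minbucket, mtry = ncol(x)),
    random_forest = rf_fit(x, y, n_trees = cfg$n_estimators,
                           max_depth = cfg$max_depth,
                           minsplit = cfg$minsplit,
                           minbucket = cfg$minbucket),
    svm = svm_fit(x, y, gamma = cfg$gamma, cost = cfg$cost,
                  epochs = cfg$svm_epochs),
    autoencoder = {
      normal <- x[y == 0, , drop = FALSE]
      abort_if(nrow(normal) == 0,
               "autoencoder needs normal-labeled training rows")
      ae <- ae_fit(normal, hidden = cfg$hidden, epochs = cfg$epochs,
                   lr = cfg$lr)
      thr <- if (!is.null(val) && nrow(val$x) > 0 &&
                   any(val$labels == 1)) {
        ae_calibrate_threshold(ae, val$x, val$labels)
      } else {
        stats::quantile(ae_mse(ae, normal), 0.95, names = FALSE)
      }
      ae$threshold <- thr
      ae
    }))
  structure(list(kind = cfg$kind, config = cfg, fit = fit,
                 schema = colnames(x)),
            class = "mwppg_detector")
}

#' @export
print.mwppg_detector <- function(x, ...) {
  cat(sprintf("<mwppg_detector> %s on %d attributes\n", x$kind,
              length(x$schema)))
  invisible(x)
}

#' Predict binary anomaly labels
#'
#' @param object an `mwppg_detector`.
#' @param newdata an `mwppg_features` or a numeric matrix whose columns
#'   match the training schema.
#' @param ... unused.
#' @return integer vector of 0/1 labels (1 = anomalous window).
#' @export
predict.mwppg_detector <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "mwppg_features")) newdata$x else newdata
  abort_if(!identical(colnames(x), object$schema),
           "feature schema mismatch between model and input")
  if (nrow(x) == 0) return(integer(0))
  switch(object$kind,
    decision_tree = cart_predict(object$fit, x),
    random_forest = rf_predict(object$fit, x),
    svm = svm_predict(object$fit, x),
    autoencoder = as.integer(ae_mse(object$fit, x) >=
                               object$fit$threshold))
}

#' Accuracy and F1 of a prediction
#'
#' F1 treats the anomaly class (1) as positive and is 0 when positives exist
#' but none are predicted.
#'
#' @param pred,truth equal-length binary vectors.
#' @return list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate <- function(pred, truth) {
  abort_if(length(pred) != length(truth), "pred/truth length mismatch")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(accuracy = mean(pred == truth), precision = precision,
       recall = recall, f1 = f1)
}

## ---- CART decision tree (Gini) -------------------------------------------

# Vectorized greedy CART: per node, per candidate feature, sort the node's
# values once and score every midpoint split by the Gini decrease.
cart_fit <- function(x, y, max_depth, minsplit = 20, minbucket = 7,
                     mtry = ncol(x)) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  grow <- function(idx, depth) {
    id <- new_node()
    pos <- sum(y[idx] == 1)
    prob <- pos / length(idx)
    node <- list(leaf = TRUE, prob = prob, n = length(idx))
    nodes[[id]] <<- node
    if (depth >= max_depth || length(idx) < minsplit ||
          pos == 0 || pos == length(idx)) {
      return(id)
    }
    feats <- if (mtry < ncol(x)) sample.int(ncol(x), mtry) else
      seq_len(ncol(x))
    best <- list(gain = 0)
    n <- length(idx)
    base_gini <- 2 * prob * (1 - prob)
    for (j in feats) {
      v <- x[idx, j]
      ord <- order(v)
      vs <- v[ord]
      ys <- y[idx][ord] == 1
      cum_pos <- cumsum(ys)
      k <- seq_len(n - 1L)
      valid <- vs[k] < vs[k + 1L] & k >= minbucket & (n - k) >= minbucket
      if (!any(valid)) next
      pl <- cum_pos[k] / k
      pr <- (pos - cum_pos[k]) / (n - k)
      child_gini <- (k * 2 * pl * (1 - pl) +
                       (n - k) * 2 * pr * (1 - pr)) / n
      gain <- base_gini - child_gini
      gain[!valid] <- -Inf
      b <- which.max(gain)
      if (gain[b] > best$gain + 1e-12) {
        best <- list(gain = gain[b], feature = j,
                     threshold = (vs[b] + vs[b + 1L]) / 2)
      }
    }
    if (best$gain <= 0) return(id)
    left_idx <- idx[x[idx, best$feature] <= best$threshold]
    right_idx <- idx[x[idx, best$feature] > best$threshold]
    node$leaf <- FALSE
    node$feature <- best$feature
    node$threshold <- best$threshold
    nodes[[id]] <<- node
    node$left <- grow(left_idx, depth + 1L)
    node$right <- grow(right_idx, depth + 1L)
    nodes[[id]] <<- node
    id
  }
  root <- grow(seq_along(y), 0L)
  list(nodes = nodes, root = root)
}

cart_prob <- function(tree, x) {
  n <- nrow(x)
  out <- numeric(n)
  cur <- rep(tree$root, n)
  active <- seq_len(n)
  while (length(active)) {
    done <- logical(length(active))
    for (u in unique(cur[active])) {
      node <- tree$nodes[[u]]
      sel <- active[cur[active] == u]
      if (node$leaf) {
        out[sel] <- node$prob
        done[match(sel, active)] <- TRUE
      } else {
        go_left <- x[sel, node$feature] <= node$threshold
        cur[sel[go_left]] <- node$left
        cur[sel[!go_left]] <- node$right
      }
    }
    active <- active[!done]
  }
  out
}

cart_predict <- function(tree, x) as.integer(cart_prob(tree, x) >= 0.5)

## ---- Random forest of CART trees -----------------------------------------

rf_fit <- function(x, y, n_trees = 10, max_depth = 10, minsplit = 20,
                   minbucket = 7) {
  mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    trees[[b]] <- cart_fit(x[idx, , drop = FALSE], y[idx],
                           max_depth = max_depth, minsplit = minsplit,
                           minbucket = minbucket, mtry = mtry)
  }
  list(trees = trees)
}

rf_predict <- function(forest, x) {
  probs <- vapply(forest$trees, cart_prob, numeric(nrow(x)), x = x)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  as.integer(rowMeans(probs) >= 0.5)
}

## ---- Gaussian-kernel SVM via dual coordinate descent ---------------------

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# L1-loss SVM dual with the bias absorbed into the kernel (K + 1);
# coordinate ascent over a random permutation per epoch, stopping when the
# maximum projected-gradient violation falls below `tol`. Training sets
# larger than `max_n` are subsampled (seeded upstream) to bound the kernel
# matrix.
svm_fit <- function(x, y, gamma = 1e-4, cost = 1, epochs = 400,
                    tol = 1e-3, max_n = 6000L) {
  yy <- ifelse(y == 1, 1, -1)
  if (nrow(x) > max_n) {
    keep <- sample.int(nrow(x), max_n)
    x <- x[keep, , drop = FALSE]
    yy <- yy[keep]
  }
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma) + 1
  alpha <- numeric(n)
  f <- numeric(n)  # f_i = sum_j alpha_j y_j K_ij
  for (ep in seq_len(epochs)) {
    viol_max <- 0
    for (i in sample.int(n)) {
      g <- yy[i] * f[i] - 1
      pg <- if (alpha[i] <= 0) min(g, 0) else
        if (alpha[i] >= cost) max(g, 0) else g
      viol_max <- max(viol_max, abs(pg))
      if (pg == 0) next
      a_new <- min(max(alpha[i] - g / K[i, i], 0), cost)
      d <- a_new - alpha[i]
      if (d != 0) {
        alpha[i] <- a_new
        f <- f + d * yy[i] * K[, i]
      }
    }
    if (viol_max < tol) break
  }
  sv <- alpha > 1e-12
  list(sv_x = x[sv, , drop = FALSE], sv_coef = (alpha * yy)[sv],
       gamma = gamma)
}

svm_predict <- function(model, x) {
  if (!nrow(model$sv_x)) return(integer(nrow(x)))
  dec <- (rbf_kernel(x, model$sv_x, model$gamma) + 1) %*% model$sv_coef
  as.integer(dec >= 0)
}

## ---- Reconstruction autoencoder ------------------------------------------

# Four fully connected layers p -> h -> h -> h -> p, ReLU on the hidden
# layers, linear output; full-batch Adam on the mean squared reconstruction
# error for a fixed epoch budget.
ae_fit <- function(x, hidden = 5, epochs = 1000, lr = 0.01) {
  p <- ncol(x)
  sizes <- c(p, hidden, hidden, hidden, p)
  W <- list()
  b <- list()
  for (l in 1:4) {
    sd0 <- sqrt(2 / sizes[l])
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sd0),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0)
  vW <- mW
  mB <- lapply(b, function(v) v * 0)
  vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    a <- list(x)
    z <- list()
    for (l in 1:4) {
      z[[l]] <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1]] <- if (l < 4) pmax(z[[l]], 0) else z[[l]]
    }
    delta <- 2 * (a[[5]] - x) / (n * ncol(x))
    gW <- list(); gB <- list()
    for (l in 4:1) {
      gW[[l]] <- crossprod(a[[l]], delta)
      gB[[l]] <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(W[[l]])) * (z[[l - 1]] > 0)
      }
    }
    for (l in 1:4) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
      vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
      c1 <- 1 - beta1^ep
      c2 <- 1 - beta2^ep
      W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
      b[[l]] <- b[[l]] - lr * (mB[[l]] / c1) / (sqrt(vB[[l]] / c2) + eps)
    }
  }
  list(W = W, b = b, hidden = hidden)
}

ae_reconstruct <- function(model, x) {
  a <- x
  for (l in 1:4) {
    a <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    if (l < 4) a <- pmax(a, 0)
  }
  a
}

# Per-row mean squared reconstruction error.
ae_mse <- function(model, x) {
  rowMeans((ae_reconstruct(model, x) - x)^2)
}

# Threshold on the validation reconstruction errors maximizing F1.
ae_calibrate_threshold <- function(model, x_val, y_val) {
  mse <- ae_mse(model, x_val)
  cand <- unique(stats::quantile(mse, probs = seq(0, 1, length.out = 201),
                                 names = FALSE))
  best_thr <- cand[1]
  best_f1 <- -1
  for (thr in cand) {
    f1 <- evaluate(as.integer(mse >= thr), y_val)$f1
    if (f1 > best_f1) {
      best_f1 <- f1
      best_thr <- thr
    }
  }
  best_thr
}
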