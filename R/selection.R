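#' Information gain of an attribute with respect to a binary class
#'
#' The attribute is discretized into equal-frequency bins (attributes with at
#' most `bins` distinct values are used as-is, so already-discrete inputs are
#' scored exactly); the returned value is
#' `H(class) - H(class | binned attribute)` in bits (log base 2), clipped at
#' zero. A single-class label vector yields 0 by definition.
#'
#' @param values numeric attribute values.
#' @param labels binary class labels, same length.
#' @param bins number of equal-frequency bins (default 10).
#' @return information gain in bits (>= 0).
#' @export
info_gain <- function(values, labels, bins = 10) {
  abort_if(length(values) != length(labels), "length mismatch")
  n <- length(values)
  abort_if(n < 2, "need at least 2 observations")
  if (length(unique(labels)) < 2) return(0)
  g <- discretize_ef(values, bins)
  h_class <- entropy_bits(table(labels))
  tab <- table(g, labels)
  h_cond <- sum(rowSums(tab) / n *
                  apply(tab, 1, entropy_bits))
  max(h_class - h_cond, 0)
}

entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Equal-frequency discretization; returns a grouping factor.
discretize_ef <- function(x, bins) {
  ux <- unique(x)
  if (length(ux) <= bins) return(factor(x))
  breaks <- unique(stats::quantile(x, probs = seq(0, 1,
                                                  length.out = bins + 1L),
                                   names = FALSE))
  if (length(breaks) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks, include.lowest = TRUE)
}

#' Rank attributes of a feature matrix by information gain
#'
#' @param fm an `mwppg_features` (ranking uses train-split rows when a split
#'   is present, to avoid leakage).
#' @param bins equal-frequency bin count (default 10).
#' @return an object of class `mwppg_ranking`: data frame
#'   (`attribute`, `info_gain_bits`) sorted descending, attribute-name
#'   lexical order breaking ties.
#' @export
rank_attributes <- function(fm, bins = 10) {
  idx <- if (!is.null(fm$split)) which(fm$split == "train") else
    seq_len(nrow(fm$x))
  if (!length(idx)) idx <- seq_len(nrow(fm$x))
  gains <- vapply(colnames(fm$x), function(a) {
    info_gain(fm$x[idx, a], fm$labels[idx], bins = bins)
  }, numeric(1))
  df <- data.frame(attribute = names(gains), info_gain_bits = unname(gains))
  df <- df[order(-df$info_gain_bits, df$attribute), ]
  rownames(df) <- NULL
  class(df) <- c("mwppg_ranking", "data.frame")
  df
}

#' Aggregate a sensor-level feature matrix across channels
#'
#' Replaces each feature's per-channel attribute columns
#' (`feature__channel`) by their row-wise mean, yielding one column per
#' feature (the combined-channels analysis mode). Row count and labels are
#' unchanged.
#'
#' @param fm a sensor-level `mwppg_features`.
#' @return an `mwppg_features` with `mode = "aggregated"`.
#' @export
aggregate_channels <- function(fm) {
  abort_if(fm$mode != "sensor",
           "aggregate_channels needs a sensor-level feature matrix")
  feats <- unique(vapply(strsplit(colnames(fm$x), "__", fixed = TRUE),
                         `[[`, character(1), 1L))
  agg <- vapply(feats, function(f) {
    cols <- grep(paste0("^", f, "__"), colnames(fm$x))
    rowMeans(fm$x[, cols, drop = FALSE])
  }, numeric(nrow(fm$x)))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1L,
                                       dimnames = list(NULL, feats))
  fm$x <- agg
  fm$mode <- "aggregated"
  fm
}

# Stratified k-fold assignment (fold ids per row), deterministic per seed.
stratified_folds <- function(y, k, seed = NULL) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated F1 of a wrapper classifier on an attribute subset
#'
#' Stratified k-fold cross-validation with predictions pooled over folds
#' before computing F1 (anomaly positive).
#'
#' @param fm an `mwppg_features`.
#' @param attributes attribute subset (default all columns).
#' @param cfg wrapper [detector_config()] (default the random forest).
#' @param cv_folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return pooled F1 in `[0, 1]`.
#' @export
cv_f1 <- function(fm, attributes = colnames(fm$x), cfg = NULL,
                  cv_folds = 5, seed = 1L) {
  cfg <- cfg %||% detector_config("random_forest", seed = seed)
  x <- fm$x[, attributes, drop = FALSE]
  y <- fm$labels
  folds <- stratified_folds(y, cv_folds, seed)
  pred <- integer(length(y))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    sub <- fm
    sub$x <- x[tr, , drop = FALSE]
    sub$labels <- y[tr]
    sub$split <- NULL
    model <- train_detector(cfg, sub)
    pred[!tr] <- predict(model, x[!tr, , drop = FALSE])
  }
  evaluate(pred, y)$f1
}

#' Random-forest recursive feature elimination
#'
#' Computes the full-set cross-validated F1 with the default random forest,
#' then repeatedly removes the attribute with the lowest information gain
#' (ties broken by attribute-name lexical order) and re-evaluates, stopping
#' before the first removal that would drop the CV F1 more than `tol` below
#' the full-set F1. By construction the retained subset's CV F1 is within
#' `tol` of the full set.
#'
#' @param fm an `mwppg_features` with at least 2 attributes.
#' @param ranked optional [rank_attributes()] result (recomputed otherwise).
#' @param cv_folds stratified CV folds (default 5).
#' @param tol allowed F1 decrease (default 0.025, i.e. 2.5%).
#' @param bins information-gain discretization bins (default 10).
#' @param seed CV/wrapper seed.
#' @return an object of class `mwppg_selection`: list with `retained`
#'   attribute names, `cutoff` (information gain of the weakest retained
#'   attribute), `cv_f1` of the retained subset, `full_f1`, and the
#'   elimination `trace`.
#' @export
rfe_select <- function(fm, ranked = NULL, cv_folds = 5, tol = 0.025,
                       bins = 10, seed = 1L) {
  p <- ncol(fm$x)
  ranked <- ranked %||% rank_attributes(fm, bins = bins)
  if (p < 2) {
    return(structure(list(retained = colnames(fm$x),
                          cutoff = if (p) ranked$info_gain_bits[p] else
                            NA_real_,
                          cv_f1 = NA_real_, full_f1 = NA_real_,
                          trace = data.frame()),
                     class = "mwppg_selection"))
  }
  full_f1 <- cv_f1(fm, cv_folds = cv_folds, seed = seed)
  retained <- ranked$attribute  # descending gain; weakest last
  current_f1 <- full_f1
  trace <- data.frame(removed = character(0), cv_f1 = numeric(0))
  while (length(retained) > 1) {
    candidate <- retained[-length(retained)]
    f1 <- cv_f1(fm, attributes = candidate, cv_folds = cv_folds,
                seed = seed)
    if (f1 < full_f1 - tol) break
    trace <- rbind(trace, data.frame(removed = retained[length(retained)],
                                     cv_f1 = f1))
    retained <- candidate
    current_f1 <- f1
  }
  gains <- ranked$info_gain_bits[match(retained, ranked$attribute)]
  structure(list(retained = retained, cutoff = min(gains),
                 cv_f1 = current_f1, full_f1 = full_f1, trace = trace),
            class = "mwppg_selection")
}

#' @export
print.mwppg_selection <- function(x, ...) {
  cat(sprintf(
    "<mwppg_selection> %d attributes retained (cutoff %.4g bits)\n",
    length(x$retained), x$cutoff))
  if (!is.na(x$full_f1)) {
    cat(sprintf("  CV F1 %.4f (full set %.4f)\n", x$cv_f1, x$full_f1))
  }
  invisible(x)
}

#' Best-first greedy forward attribute selection
#'
#' Starts from the empty set and repeatedly adds the attribute that
#' maximizes the wrapper's cross-validated F1, terminating after `patience`
#' consecutive non-improving expansions (or pool exhaustion) and returning
#' the best subset seen.
#'
#' @param fm an `mwppg_features` pooling the candidate attributes.
#' @param cfg wrapper [detector_config()] (default random forest).
#' @param cv_folds stratified CV folds (default 5).
#' @param patience non-improving expansions tolerated (default 5).
#' @param seed CV/wrapper seed.
#' @return an `mwppg_selection` with the selected attributes (empty pool
#'   selects nothing).
#' @export
best_first_select <- function(fm, cfg = NULL, cv_folds = 5, patience = 5,
                              seed = 1L) {
  pool <- colnames(fm$x)
  selected <- character(0)
  best_set <- character(0)
  best_f1 <- 0
  fails <- 0L
  while (length(pool) && fails < patience) {
    scores <- vapply(pool, function(a) {
      cv_f1(fm, attributes = c(selected, a), cfg = cfg,
            cv_folds = cv_folds, seed = seed)
    }, numeric(1))
    add <- pool[which.max(scores)]
    selected <- c(selected, add)
    pool <- setdiff(pool, add)
    if (max(scores) > best_f1 + 1e-12) {
      best_f1 <- max(scores)
      best_set <- selected
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
  }
  structure(list(retained = best_set, cutoff = NA_real_, cv_f1 = best_f1,
                 full_f1 = NA_real_, trace = data.frame()),
            class = "mwppg_selection")
}

#' Write an attribute ranking report as CSV
#'
#' Columns `attribute,info_gain_bits,retained`.
#' @param ranked an `mwppg_ranking`.
#' @param selection optional `mwppg_selection` marking retained attributes.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranked, selection = NULL, path) {
  df <- as.data.frame(ranked)
  df$retained <- if (is.null(selection)) TRUE else
    df$attribute %in% selection$retained
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
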