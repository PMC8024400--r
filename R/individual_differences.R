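#' Behavioural performance index (first unrotated principal component)
#'
#' Z-scores each task's scores across subjects, takes the first unrotated
#' principal component of the subject x task table, fixes its sign so the
#' mean task loading is non-negative, and standardises the scores to zero
#' mean and unit variance.
#'
#' @param scores subject x task numeric matrix; missing values are
#'   mean-imputed with a warning.
#' @return A `performance_index`: `pi` (per subject), `loadings` (per
#'   task), `var_explained`.
#' @export
performance_index <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3) stop("need at least 3 subjects")
  if (anyNA(scores)) {
    warning("missing scores mean-imputed")
    for (j in seq_len(ncol(scores)))
      scores[is.na(scores[, j]), j] <- mean(scores[, j], na.rm = TRUE)
  }
  sds <- apply(scores, 2, stats::sd)
  if (all(sds == 0)) stop("rank-0 score table")
  sds[sds == 0] <- 1
  Z <- scale(scores, center = TRUE, scale = sds)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  w <- pc$rotation[, 1]
  if (mean(w) < 0) w <- -w
  raw <- drop(Z %*% w)
  out <- list(pi = as.numeric(scale(raw)), loadings = w,
              var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
  class(out) <- "performance_index"
  out
}

#' @export
print.performance_index <- function(x, ...) {
  cat(sprintf("Performance index: PC1 of %d task scores, %.1f%% variance explained\n",
              length(x$loadings), 100 * x$var_explained))
  invisible(x)
}

#' Per-subject classifiability from held-out predictions
#'
#' Counts, per subject, the task blocks correctly classified by models
#' naive to that subject. With 12 tasks x 3 blocks every subject
#' contributes 36 events. When events were predicted multiple times
#' (repeated held-out splits) the per-event majority prediction is scored.
#' Outliers are flagged when accuracy falls below chance + 2/total or more
#' than 3 SD below the cohort mean.
#'
#' @param predictions data frame with columns `subject`, `block`, `truth`,
#'   `pred` (e.g. the `predictions` element of [repeated_heldout_eval()]).
#' @return A data frame, one row per subject: `subject`, `correct`,
#'   `total`, `accuracy`, `outlier_flag`.
#' @export
subject_classifiability <- function(predictions) {
  need <- c("subject", "truth", "pred")
  if (!all(need %in% names(predictions)))
    stop("predictions must have subject, truth and pred columns")
  key <- interaction(predictions$subject, predictions$truth,
                     predictions$block, drop = TRUE)
  agg <- lapply(split(predictions, key), function(d)
    data.frame(subject = d$subject[1], truth = d$truth[1],
               correct = vote_mode(d$pred) == d$truth[1]))
  agg <- do.call(rbind, agg)
  res <- lapply(split(agg, agg$subject), function(d)
    data.frame(subject = d$subject[1], correct = sum(d$correct),
               total = nrow(d)))
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$accuracy <- res$correct / res$total
  n_class <- length(unique(predictions$truth))
  chance <- 1 / n_class
  res$outlier_flag <- res$accuracy < chance + 2 / res$total |
    res$accuracy < mean(res$accuracy) - 3 * stats::sd(res$accuracy)
  res
}

#' Association between classifiability and the performance index
#'
#' Right-tailed Pearson correlation between per-subject classification
#' accuracy and the behavioural performance index, with
#' Benjamini-Hochberg correction across a declared family of models.
#' Outlier-flagged subjects are excluded.
#'
#' @param acc a data frame from [subject_classifiability()], or a list of
#'   them (the FDR family).
#' @param pi_obj a `performance_index` (its `pi` ordered by subject id).
#' @param labels optional family member names.
#' @return Data frame with `r`, `p`, `p_fdr`, `n` per family member.
#' @export
accuracy_pi_association <- function(acc, pi_obj, labels = NULL) {
  fam <- if (is.data.frame(acc)) list(acc) else acc
  res <- lapply(fam, function(a) {
    keep <- !a$outlier_flag
    x <- a$accuracy[keep]
    y <- pi_obj$pi[a$subject[keep]]
    if (length(x) < 10) stop("need at least 10 non-outlier subjects")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero-variance input to the association test")
    ct <- stats::cor.test(x, y, alternative = "greater")
    data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  })
  out <- do.call(rbind, res)
  if (!is.null(labels)) out$model <- labels
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Boosted regression trees predicting the performance index
#'
#' Least-squares gradient boosting (shrinkage `learn_rate`, trees limited
#' to `max_splits` branch-node splits) over the 28 network-reduced
#' connectivity features. The tree structure is selected by a
#' leave-one-subject-out grid search over (max_splits, n_trees) scored by
#' LOO mean squared error; the chosen spec's LOO predictions are reported
#' together with a full-sample ensemble's split-gain feature importance.
#'
#' @param features subject x feature matrix (e.g.
#'   [subject_rsn_features()]).
#' @param pi_obj a `performance_index` aligned to the feature rows (or a
#'   plain numeric target).
#' @param grid list with `max_splits` and `n_trees` vectors (defaults
#'   bracket a 3-split, 3-tree optimum).
#' @param learn_rate boosting shrinkage (default 1).
#' @return A `tree_eval`: `loo_predictions`, `mse`, `r` (Pearson of
#'   predicted vs actual), `importance` (full-sample split-gain),
#'   `chosen` (max_splits, n_trees), `grid_mse`.
#' @export
boosted_tree_regression <- function(features, pi_obj,
                                    grid = list(max_splits = c(1, 2, 3, 5),
                                                n_trees = c(3, 5, 10, 25)),
                                    learn_rate = 1) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- if (inherits(pi_obj, "performance_index")) pi_obj$pi else
    as.numeric(pi_obj)
  n <- nrow(X)
  if (n != length(y)) stop("features and target misaligned")
  if (n < 10) stop("need at least 10 subjects")
  if (stats::sd(y) == 0) stop("constant target")
  if (length(grid$max_splits) == 0 || length(grid$n_trees) == 0)
    stop("empty grid")

  fit_one <- function(Xtr, ytr, max_splits, n_trees) {
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = learn_rate,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_depth = 0, max_leaves = max_splits + 1,
                    base_score = mean(ytr), lambda = 0,
                    min_child_weight = 1, subsample = 1,
                    colsample_bytree = 1, nthread = 1),
      data = xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1),
      nrounds = n_trees, verbose = 0)
  }
  loo_pred <- function(max_splits, n_trees) {
    vapply(seq_len(n), function(i) {
      m <- fit_one(X[-i, , drop = FALSE], y[-i], max_splits, n_trees)
      stats::predict(m, xgboost::xgb.DMatrix(X[i, , drop = FALSE],
                                             nthread = 1))
    }, numeric(1))
  }

  combos <- expand.grid(max_splits = grid$max_splits,
                        n_trees = grid$n_trees)
  ## prefer simpler structures on MSE ties: fewer trees, then fewer splits
  combos <- combos[order(combos$n_trees, combos$max_splits), ]
  preds <- vector("list", nrow(combos))
  mses <- numeric(nrow(combos))
  for (g in seq_len(nrow(combos))) {
    preds[[g]] <- loo_pred(combos$max_splits[g], combos$n_trees[g])
    mses[g] <- mean((preds[[g]] - y)^2)
  }
  best <- which.min(mses)
  chosen <- combos[best, ]
  full <- fit_one(X, y, chosen$max_splits, chosen$n_trees)
  imp <- xgboost::xgb.importance(model = full)
  importance <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (nrow(imp) > 0) importance[imp$Feature] <- imp$Gain
  pred_best <- preds[[best]]
  out <- list(loo_predictions = pred_best,
              mse = mses[best],
              r = if (stats::sd(pred_best) > 0) stats::cor(pred_best, y)
                  else NA_real_,
              importance = importance,
              chosen = list(max_splits = chosen$max_splits,
                            n_trees = chosen$n_trees,
                            learn_rate = learn_rate),
              grid_mse = cbind(combos, mse = mses))
  class(out) <- "tree_eval"
  out
}

#' @export
print.tree_eval <- function(x, ...) {
  cat(sprintf("Boosted regression trees: chosen %d splits x %d trees; LOO MSE = %.4f, r = %.3f\n",
              x$chosen$max_splits, x$chosen$n_trees, x$mse, x$r))
  top <- utils::head(sort(x$importance, decreasing = TRUE), 3)
  cat("  top importance:",
      paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
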