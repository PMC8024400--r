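# Subject-level split/scramble helpers. All splits are by subject: every
# event of a subject lands on one side, guarding against identity leakage.

subset_ft <- function(ft, idx) {
  feature_table(ft$X[idx, , drop = FALSE], ft$y[idx], ft$subject[idx],
                ft$block[idx], ft$meta)
}

split_by_subjects <- function(ft, train_subjects) {
  tr <- ft$subject %in% train_subjects
  list(train = subset_ft(ft, which(tr)), test = subset_ft(ft, which(!tr)),
       train_idx = which(tr), test_idx = which(!tr))
}

# Scramble labels within each subject (preserves the per-subject class
# balance and block structure of the null model).
scramble_within_subject <- function(ft) {
  y <- ft$y
  for (s in unique(ft$subject)) {
    i <- which(ft$subject == s)
    y[i] <- y[sample(i)]
  }
  out <- ft
  out$y <- y
  out
}

# Partition subjects into k folds (near-equal, deterministic given RNG).
subject_folds <- function(subjects, k) {
  subjects <- sample(subjects)
  split(subjects, rep_len(seq_len(k), length(subjects)))
}

#' Repeated subject-level held-out evaluation with permutation nulls
#'
#' The main performance protocol: `n_rep` times, subjects are split into
#' independent training (75%) and test (25%) subsets; a true model and a
#' null model (training labels scrambled within subject) are fitted on the
#' training subjects and scored on the held-out subjects by F1-macro.
#' Optionally an internal subject-level k-fold cross-validation estimate is
#' computed inside each training set (the optimistic estimate).
#'
#' @param ft a `feature_table`.
#' @param n_rep repetitions (default 100).
#' @param train_frac fraction of subjects in training (default 0.75).
#' @param scheme ECOC scheme, `"OVA"` or `"OVO"`.
#' @param seed RNG seed.
#' @param cv_folds internal CV folds within training (0 = skip, default 5).
#' @param fit_true,fit_null fit the true / the scrambled-label model.
#' @param keep_predictions keep per-event held-out predictions of the true
#'   model (needed for per-subject classifiability).
#' @return A `heldout_eval`: `true_scores`, `null_scores`, `cv_scores`
#'   (per-repetition F1-macro), `m`, `b` (nulls beating the true mean),
#'   `p` (empirical), `predictions` (long data frame) when requested.
#' @export
repeated_heldout_eval <- function(ft, n_rep = 100, train_frac = 0.75,
                                  scheme = "OVA", seed = 1L, cv_folds = 5,
                                  fit_true = TRUE, fit_null = TRUE,
                                  keep_predictions = FALSE) {
  subjects <- sort(unique(ft$subject))
  ns <- length(subjects)
  if (ns < 8) stop("need at least 8 subjects for the held-out protocol")
  n_train <- round(train_frac * ns)
  if (n_train < 1 || n_train >= ns) stop("train_frac leaves an empty split")
  classes <- sort(unique(ft$y))

  with_seed(seed, {
    true_scores <- rep(NA_real_, n_rep)
    null_scores <- rep(NA_real_, n_rep)
    cv_scores <- rep(NA_real_, n_rep)
    preds <- if (keep_predictions) vector("list", n_rep) else NULL
    for (rep_i in seq_len(n_rep)) {
      tr_sub <- sample(subjects, n_train)
      sp <- split_by_subjects(ft, tr_sub)
      if (fit_true) {
        mod <- fit_ecoc(sp$train, scheme)
        pred <- predict(mod, sp$test)
        true_scores[rep_i] <- f1_scores(pred, sp$test$y, classes)$f1_macro
        if (keep_predictions)
          preds[[rep_i]] <- data.frame(rep = rep_i,
                                       subject = sp$test$subject,
                                       block = sp$test$block,
                                       truth = sp$test$y, pred = pred)
        if (cv_folds > 1) {
          ## event-level folds: within-training CV ignores subject
          ## identity, which is what makes it an optimistic estimate
          ## relative to the subject-level held-out score
          n_tr <- nrow(sp$train$X)
          fold_of <- sample(rep_len(seq_len(cv_folds), n_tr))
          f1s <- vapply(seq_len(cv_folds), function(f) {
            m <- fit_ecoc(subset_ft(sp$train, which(fold_of != f)), scheme)
            hold <- subset_ft(sp$train, which(fold_of == f))
            f1_scores(predict(m, hold), hold$y, classes)$f1_macro
          }, numeric(1))
          cv_scores[rep_i] <- mean(f1s)
        }
      }
      if (fit_null) {
        null_train <- scramble_within_subject(sp$train)
        nmod <- fit_ecoc(null_train, scheme)
        null_scores[rep_i] <- f1_scores(predict(nmod, sp$test),
                                        sp$test$y, classes)$f1_macro
      }
    }
    b <- if (fit_true && fit_null)
      sum(null_scores > mean(true_scores)) else NA_integer_
    out <- list(true_scores = true_scores, null_scores = null_scores,
                cv_scores = cv_scores, m = n_rep, b = b,
                p = if (!is.na(b)) (b + 1) / (n_rep + 1) else NA_real_,
                scheme = scheme, train_frac = train_frac,
                classes = classes,
                predictions = if (keep_predictions)
                  do.call(rbind, preds) else NULL)
    class(out) <- "heldout_eval"
    out
  })
}

#' @export
print.heldout_eval <- function(x, ...) {
  cat(sprintf("Repeated held-out evaluation (%d reps, %s, train %.0f%%)\n",
              x$m, x$scheme, 100 * x$train_frac))
  if (!all(is.na(x$true_scores)))
    cat(sprintf("  true F1-macro: mean %.3f (sd %.3f)\n",
                mean(x$true_scores), stats::sd(x$true_scores)))
  if (!all(is.na(x$null_scores)))
    cat(sprintf("  null F1-macro: mean %.3f (sd %.3f)\n",
                mean(x$null_scores), stats::sd(x$null_scores)))
  if (!all(is.na(x$cv_scores)))
    cat(sprintf("  inner-CV F1-macro: mean %.3f\n",
                mean(x$cv_scores, na.rm = TRUE)))
  if (!is.na(x$b))
    cat(sprintf("  empirical p = (b+1)/(m+1) = (%d+1)/(%d+1) = %.4f\n",
                x$b, x$m, x$p))
  invisible(x)
}

#' Empirical permutation probability
#'
#' p = (b + 1) / (m + 1), where b is the number of null repetitions whose
#' score exceeds the mean true score and m the repetition count; bounded
#' in \[1/(m+1), 1\].
#'
#' @param dist a `heldout_eval` (or any list with `true_scores` and
#'   `null_scores`).
#' @return The empirical probability.
#' @export
empirical_p <- function(dist) {
  true_scores <- dist$true_scores[!is.na(dist$true_scores)]
  null_scores <- dist$null_scores[!is.na(dist$null_scores)]
  if (!length(true_scores) || !length(null_scores))
    stop("empty score distributions")
  m <- length(null_scores)
  b <- sum(null_scores > mean(true_scores))
  (b + 1) / (m + 1)
}

#' Two-stage stacked classification of multiple metrics
#'
#' Stage 1, per metric: an internal subject-level five-fold CV inside the
#' training subjects produces out-of-fold positive binary scores (PBS: the
#' signed decision values of the per-class OVA learners). Stage 2: an ECOC
#' model trained on the concatenated PBS (n_metrics x n_classes features).
#' At test time each of the five stage-1 fold models scores the test
#' events, the stage-2 model labels each scoring, and the final label is
#' the majority vote across the five resulting predictions (ties to the
#' lowest class).
#'
#' @param tables named list of `feature_table`s aligned on events (same
#'   y/subject/block order), e.g. `list(BA = ..., dFC = ...)`.
#' @param n_rep outer repetitions (default 100).
#' @param train_frac training fraction of subjects.
#' @param inner_folds stage-1 folds (default 5).
#' @param seed RNG seed.
#' @param compare_single also fit each single-metric model on the same
#'   split (paired comparison; default TRUE).
#' @return A `stack_eval`: `stack_scores` and, when requested, one score
#'   vector per metric, plus `n_stack_features`.
#' @export
stack_model <- function(tables, n_rep = 100, train_frac = 0.75,
                        inner_folds = 5, seed = 1L, compare_single = TRUE) {
  stopifnot(length(tables) >= 1)
  base <- tables[[1]]
  for (tb in tables[-1]) {
    if (!identical(tb$y, base$y) || !identical(tb$subject, base$subject))
      stop("event misalignment between metric tables")
  }
  subjects <- sort(unique(base$subject))
  n_train <- round(train_frac * length(subjects))
  classes <- sort(unique(base$y))
  k <- length(classes)

  with_seed(seed, {
    stack_scores <- numeric(n_rep)
    single <- matrix(NA_real_, n_rep, length(tables),
                     dimnames = list(NULL, names(tables)))
    for (rep_i in seq_len(n_rep)) {
      tr_sub <- sample(subjects, n_train)
      folds <- subject_folds(tr_sub, inner_folds)
      tr_idx <- which(base$subject %in% tr_sub)
      te_idx <- which(!base$subject %in% tr_sub)
      pbs_train <- matrix(NA_real_, length(tr_idx), length(tables) * k)
      fold_models <- vector("list", inner_folds)
      for (f in seq_len(inner_folds)) {
        fold_models[[f]] <- vector("list", length(tables))
        hold_sub <- folds[[f]]
        for (mi in seq_along(tables)) {
          ft <- tables[[mi]]
          fit_idx <- which(ft$subject %in% setdiff(tr_sub, hold_sub))
          hold_idx_local <- which(base$subject[tr_idx] %in% hold_sub)
          mod <- fit_ecoc(subset_ft(ft, fit_idx), "OVA")
          fold_models[[f]][[mi]] <- mod
          sc <- predict(mod, ft$X[tr_idx[hold_idx_local], , drop = FALSE],
                        type = "scores")
          pbs_train[hold_idx_local, (mi - 1) * k + seq_len(k)] <- sc
        }
      }
      stage2 <- fit_ecoc(feature_table(pbs_train, base$y[tr_idx],
                                       base$subject[tr_idx]), "OVA")
      votes <- matrix(NA_integer_, length(te_idx), inner_folds)
      for (f in seq_len(inner_folds)) {
        pbs_test <- do.call(cbind, lapply(seq_along(tables), function(mi)
          predict(fold_models[[f]][[mi]],
                  tables[[mi]]$X[te_idx, , drop = FALSE], type = "scores")))
        votes[, f] <- predict(stage2, pbs_test)
      }
      final <- apply(votes, 1, vote_mode)
      stack_scores[rep_i] <- f1_scores(final, base$y[te_idx],
                                       classes)$f1_macro
      if (compare_single) {
        for (mi in seq_along(tables)) {
          ft <- tables[[mi]]
          mod <- fit_ecoc(subset_ft(ft, tr_idx), "OVA")
          single[rep_i, mi] <- f1_scores(
            predict(mod, ft$X[te_idx, , drop = FALSE]),
            base$y[te_idx], classes)$f1_macro
        }
      }
    }
    out <- list(stack_scores = stack_scores, single_scores = single,
                n_stack_features = length(tables) * k, classes = classes)
    class(out) <- "stack_eval"
    out
  })
}

#' @export
print.stack_eval <- function(x, ...) {
  cat(sprintf("Stacked classification (%d stage-2 features): mean F1-macro = %.3f\n",
              x$n_stack_features, mean(x$stack_scores)))
  if (!all(is.na(x$single_scores)))
    for (nm in colnames(x$single_scores))
      cat(sprintf("  %s alone: %.3f\n", nm,
                  mean(x$single_scores[, nm])))
  invisible(x)
}

#' Pairwise binary task classification and its psychometric association
#'
#' For each unordered task pair (66 for 12 tasks) a binary linear SVM is
#' evaluated with the subject-level held-out protocol; the pairwise
#' accuracies are then correlated (left-tailed) with the corresponding
#' psychometric similarities.
#'
#' @param ft a `feature_table` with all tasks present.
#' @param psychometric_sim a `similarity_matrix` (psychometric kernel).
#' @param n_rep held-out repetitions per pair (default 20).
#' @param train_frac training fraction of subjects.
#' @param seed RNG seed.
#' @return A `pairwise_eval`: `accuracy` (task x task symmetric matrix of
#'   mean held-out accuracy) and `association` (left-tailed Pearson test).
#' @export
pairwise_binary_eval <- function(ft, psychometric_sim, n_rep = 20,
                                 train_frac = 0.75, seed = 1L) {
  classes <- sort(unique(ft$y))
  k <- length(classes)
  subjects <- sort(unique(ft$subject))
  n_train <- round(train_frac * length(subjects))
  acc <- matrix(NA_real_, k, k)
  diag(acc) <- NA
  with_seed(seed, {
    splits <- lapply(seq_len(n_rep), function(i) sample(subjects, n_train))
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      idx <- which(ft$y %in% classes[c(a, b)])
      sub_ft <- subset_ft(ft, idx)
      accs <- vapply(splits, function(tr_sub) {
        sp <- split_by_subjects(sub_ft, tr_sub)
        mod <- fit_ecoc(sp$train, "OVA")
        mean(predict(mod, sp$test) == sp$test$y)
      }, numeric(1))
      acc[a, b] <- acc[b, a] <- mean(accs)
    }
  })
  acc_sim <- acc
  diag(acc_sim) <- 1
  assoc <- similarity_association_test(acc_sim, psychometric_sim,
                                       tail = "left")
  out <- list(accuracy = acc, association = assoc, n_pairs = k * (k - 1) / 2)
  class(out) <- "pairwise_eval"
  out
}

#' @export
print.pairwise_eval <- function(x, ...) {
  cat(sprintf("Pairwise binary classification: %d pairs, mean accuracy %.3f\n",
              x$n_pairs, mean(ut(x$accuracy), na.rm = TRUE)))
  cat(sprintf("  association with psychometric similarity: r = %.3f, left-tail p = %.4g\n",
              x$association$r[1], x$association$p[1]))
  invisible(x)
}

#' Meta-class classification with class-size-preserving permutations
#'
#' Merges tasks into meta-classes (e.g. by psychometric factor), runs the
#' standard held-out protocol (true and scrambled-label null), and
#' additionally evaluates `n_perm` random task-to-class assignments that
#' preserve the true class sizes; the empirical p compares the mean true
#' score to the permuted distribution.
#'
#' @param ft a `feature_table`.
#' @param mapping integer meta-class per task (length = number of tasks).
#' @param n_rep held-out repetitions for true/null (default 20).
#' @param n_perm size-preserving permutations (default 100; one held-out
#'   split each).
#' @param train_frac training fraction of subjects.
#' @param seed RNG seed.
#' @return A `metaclass_eval`: `true_scores`, `null_scores`,
#'   `perm_scores`, `p_vs_perm`, `class_sizes`.
#' @export
metaclass_eval <- function(ft, mapping, n_rep = 20, n_perm = 100,
                           train_frac = 0.75, seed = 1L) {
  tasks <- sort(unique(ft$y))
  if (length(mapping) != length(tasks))
    stop("mapping must give one meta-class per task")
  if (length(unique(mapping)) < 2) stop("degenerate scheme: single class")
  relabel <- function(ftab, mp) {
    out <- ftab
    out$y <- mp[match(ftab$y, tasks)]
    out
  }
  base <- relabel(ft, mapping)
  ev <- repeated_heldout_eval(base, n_rep = n_rep, train_frac = train_frac,
                              seed = seed, cv_folds = 0)
  subjects <- sort(unique(ft$subject))
  n_train <- round(train_frac * length(subjects))
  perm_scores <- with_seed(seed + 1L, {
    vapply(seq_len(n_perm), function(i) {
      mp <- sample(mapping)  # permuted assignment, class sizes preserved
      pft <- relabel(ft, mp)
      sp <- split_by_subjects(pft, sample(subjects, n_train))
      mod <- fit_ecoc(sp$train, "OVA")
      f1_scores(predict(mod, sp$test), sp$test$y,
                sort(unique(pft$y)))$f1_macro
    }, numeric(1))
  })
  b <- sum(perm_scores > mean(ev$true_scores))
  out <- list(true_scores = ev$true_scores, null_scores = ev$null_scores,
              perm_scores = perm_scores,
              p_vs_perm = (b + 1) / (n_perm + 1),
              class_sizes = table(mapping), mapping = mapping)
  class(out) <- "metaclass_eval"
  out
}

#' @export
print.metaclass_eval <- function(x, ...) {
  cat(sprintf("Meta-class evaluation (%d classes, sizes %s)\n",
              length(x$class_sizes),
              paste(x$class_sizes, collapse = "/")))
  cat(sprintf("  true %.3f | size-preserving perm %.3f | null %.3f; p(true vs perm) = %.4f\n",
              mean(x$true_scores), mean(x$perm_scores),
              mean(x$null_scores), x$p_vs_perm))
  invisible(x)
}
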