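#' Event-level feature table
#'
#' The classification substrate: one row per matched event (subject x task
#' x block) with aligned labels, subject ids and block indices.
#'
#' @param X event x feature numeric matrix.
#' @param y integer task label per event.
#' @param subject integer subject id per event.
#' @param block optional block index per event.
#' @param meta list of metadata (metric, ROI-set tag, ...).
#' @return A `feature_table`.
#' @export
feature_table <- function(X, y, subject, block = NULL, meta = list()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  subject <- as.integer(subject)
  if (nrow(X) != length(y) || length(y) != length(subject))
    stop("X rows, y and subject must be aligned")
  out <- list(X = X, y = y, subject = subject,
              block = if (is.null(block)) rep(NA_integer_, length(y))
                      else as.integer(block),
              meta = meta)
  class(out) <- "feature_table"
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table [%s]: %d events x %d features, %d classes, %d subjects\n",
              if (is.null(x$meta$metric)) "?" else x$meta$metric,
              nrow(x$X), ncol(x$X), length(unique(x$y)),
              length(unique(x$subject))))
  invisible(x)
}

# ECOC code matrix: classes x learners, entries in {-1, 0, 1}.
ecoc_code_matrix <- function(classes, scheme = c("OVA", "OVO")) {
  scheme <- match.arg(scheme)
  k <- length(classes)
  if (scheme == "OVA") {
    M <- matrix(-1, k, k)
    diag(M) <- 1
  } else {
    pairs <- utils::combn(k, 2)
    M <- matrix(0, k, ncol(pairs))
    for (l in seq_len(ncol(pairs))) {
      M[pairs[1, l], l] <- 1
      M[pairs[2, l], l] <- -1
    }
  }
  rownames(M) <- classes
  M
}

# Fit one binary linear SVM; stores an orientation flip so that positive
# decision values always mean the +1 code side.
fit_binary_svm <- function(X, y_signed, cost = 1) {
  f <- factor(ifelse(y_signed > 0, "pos", "neg"), levels = c("pos", "neg"))
  if (length(unique(f)) < 2) stop("a binary learner saw a single class")
  m <- e1071::svm(X, f, kernel = "linear", cost = cost, scale = FALSE)
  dv <- attr(stats::predict(m, X, decision.values = TRUE),
             "decision.values")[, 1]
  flip <- if (mean(dv[y_signed > 0]) >= mean(dv[y_signed < 0])) 1 else -1
  list(model = m, flip = flip)
}

svm_decision <- function(learner, newx) {
  dv <- attr(stats::predict(learner$model, newx, decision.values = TRUE),
             "decision.values")[, 1]
  learner$flip * dv
}

#' Fit an error-correcting output codes (ECOC) multi-class model
#'
#' Reduces the multi-class problem to a code matrix of binary linear
#' support vector machines: one-vs-all (k learners) or one-vs-one
#' (k(k-1)/2 learners), with fixed default regularisation (C = 1, no
#' hyperparameter tuning) and features z-scored on training statistics.
#' Prediction decodes by minimal aggregate hinge loss against the code
#' matrix, ties broken by the lowest class index.
#'
#' @param train a `feature_table`.
#' @param scheme `"OVA"` or `"OVO"`.
#' @param cost SVM regularisation constant (default 1).
#' @return An `ecoc_model`.
#' @export
fit_ecoc <- function(train, scheme = c("OVA", "OVO"), cost = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(train, "feature_table"))
  classes <- sort(unique(train$y))
  if (length(classes) < 2) stop("need at least 2 classes in training data")
  zs <- zscore_fit(train$X)
  M <- ecoc_code_matrix(classes, scheme)
  learners <- vector("list", ncol(M))
  for (l in seq_len(ncol(M))) {
    code <- M[, l]
    keep <- train$y %in% classes[code != 0]
    y_signed <- code[match(train$y[keep], classes)]
    learners[[l]] <- fit_binary_svm(zs$x[keep, , drop = FALSE], y_signed,
                                    cost = cost)
  }
  out <- list(learners = learners, code = M, classes = classes,
              scheme = scheme, center = zs$center, scale = zs$scale,
              cost = cost)
  class(out) <- "ecoc_model"
  out
}

#' @export
print.ecoc_model <- function(x, ...) {
  cat(sprintf("ECOC %s model: %d classes, %d binary linear SVM learners (C = %g)\n",
              x$scheme, length(x$classes), length(x$learners), x$cost))
  invisible(x)
}

# Signed decision values of all learners for new events.
ecoc_scores <- function(model, X) {
  Xz <- zscore_apply(as.matrix(X), list(center = model$center,
                                        scale = model$scale))
  vapply(model$learners, svm_decision, numeric(nrow(Xz)), newx = Xz)
}

# Decode learner scores (events x learners) to class labels by weighted
# mean hinge loss against the code matrix.
ecoc_decode <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  M <- model$code
  loss <- matrix(0, nrow(scores), nrow(M))
  for (k in seq_len(nrow(M))) {
    code <- M[k, ]
    act <- code != 0
    h <- pmax(1 - sweep(scores[, act, drop = FALSE], 2, code[act], "*"), 0)
    loss[, k] <- rowMeans(h)
  }
  model$classes[apply(loss, 1, which.min)]  # which.min: lowest index on ties
}

#' @param object an `ecoc_model`.
#' @param newdata event x feature matrix or a `feature_table`.
#' @param type `"class"` for decoded labels, `"scores"` for the signed
#'   per-learner decision values (the positive binary scores).
#' @param ... unused.
#' @rdname fit_ecoc
#' @export
predict.ecoc_model <- function(object, newdata, type = c("class", "scores"),
                               ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_table")) newdata$X else newdata
  sc <- ecoc_scores(object, X)
  if (type == "scores") return(sc)
  ecoc_decode(object, sc)
}

#' Per-class and macro F1 classification report
#'
#' Per class: precision p, recall r, and f1-minor = 2rp/(p+r) (0 when
#' p + r = 0); F1-macro is the unweighted mean of the per-class scores.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param classes class set (default: classes present in `truth`).
#' @return A `classification_report`: `f1_minor` (named per class),
#'   `f1_macro`, `precision`, `recall`, `confusion` (rows = truth),
#'   `per_event` (predictions).
#' @export
f1_scores <- function(pred, truth, classes = sort(unique(truth))) {
  pred <- factor(pred, levels = classes)
  truth <- factor(truth, levels = classes)
  confusion <- table(truth = truth, pred = pred)
  tp <- diag(confusion)
  p <- tp / pmax(colSums(confusion), 0)
  r <- tp / pmax(rowSums(confusion), 0)
  p[!is.finite(p)] <- 0
  r[!is.finite(r)] <- 0
  f1 <- ifelse(p + r == 0, 0, 2 * r * p / (p + r))
  names(f1) <- classes
  out <- list(f1_minor = f1, f1_macro = mean(f1), precision = p,
              recall = r, confusion = confusion, per_event = pred)
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report: F1-macro = %.3f over %d classes (f1-minor %.3f-%.3f)\n",
              x$f1_macro, length(x$f1_minor), min(x$f1_minor),
              max(x$f1_minor)))
  invisible(x)
}
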