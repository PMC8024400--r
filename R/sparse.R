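#' Sparse (lasso) connection selection via leave-one-subject-out models
#'
#' Replaces the binary learners of the one-vs-all scheme with
#' L1-regularised linear logistic regressions to identify the connections
#' that drive the multi-way classification. One sparse OVA model is fitted
#' per held-out subject; per model and per task the nonzero positive and
#' negative weights are binarised separately, averaged across tasks and
#' then across models. The top set is the edges above the 99.9th
#' percentile of each frequency map. The per-model penalty is the smallest
#' lasso penalty retaining at most `max_nonzero_frac` nonzero weights
#' (recorded in the output).
#'
#' @param ft a dFC `feature_table` (events x edges).
#' @param network_labels optional integer network id per ROI for
#'   within/between annotation of the top edges.
#' @param max_nonzero_frac nonzero-weight budget per learner (default
#'   0.05).
#' @param top_quantile percentile defining the top set (default 0.999).
#' @return A `sparse_weight_summary`: `pos_frequency`, `neg_frequency`
#'   (per edge, in \[0,1\]), `top_pos`, `top_neg` (edge indices),
#'   `annotation` (within/between per edge when labels given),
#'   `lambda_used` (per model x task).
#' @export
sparse_connection_selection <- function(ft, network_labels = NULL,
                                        max_nonzero_frac = 0.05,
                                        top_quantile = 0.999) {
  subjects <- sort(unique(ft$subject))
  if (length(subjects) < 10)
    stop("need at least 10 subjects for leave-one-subject-out selection")
  classes <- sort(unique(ft$y))
  E <- ncol(ft$X)
  budget <- max(1L, floor(max_nonzero_frac * E))
  if (all(ft$X == 0)) {
    warning("all-zero features: empty selection")
    zero <- numeric(E)
    out <- list(pos_frequency = zero, neg_frequency = zero,
                top_pos = integer(0), top_neg = integer(0),
                annotation = NULL, lambda_used = NULL)
    class(out) <- "sparse_weight_summary"
    return(out)
  }
  pos_acc <- numeric(E)
  neg_acc <- numeric(E)
  lambda_used <- matrix(NA_real_, length(subjects), length(classes))
  for (si in seq_along(subjects)) {
    keep <- ft$subject != subjects[si]
    zs <- zscore_fit(ft$X[keep, , drop = FALSE])
    pos_m <- numeric(E)
    neg_m <- numeric(E)
    for (ci in seq_along(classes)) {
      yy <- as.numeric(ft$y[keep] == classes[ci])
      fit <- glmnet::glmnet(zs$x, yy, family = "binomial", alpha = 1,
                            standardize = FALSE)
      ok <- which(fit$df <= budget)
      lam_i <- ok[length(ok)]  # smallest penalty within the budget
      w <- as.numeric(fit$beta[, lam_i])
      lambda_used[si, ci] <- fit$lambda[lam_i]
      pos_m <- pos_m + (w > 0)
      neg_m <- neg_m + (w < 0)
    }
    pos_acc <- pos_acc + pos_m / length(classes)
    neg_acc <- neg_acc + neg_m / length(classes)
  }
  pos_frequency <- pos_acc / length(subjects)
  neg_frequency <- neg_acc / length(subjects)
  top_of <- function(fr) {
    if (all(fr == 0)) return(integer(0))
    which(fr >= stats::quantile(fr, top_quantile) & fr > 0)
  }
  annotation <- NULL
  if (!is.null(network_labels)) {
    K <- (1 + sqrt(1 + 8 * E)) / 2
    ei <- edge_index(as.integer(K))
    annotation <- ifelse(network_labels[ei$i] == network_labels[ei$j],
                         "within", "between")
  }
  out <- list(pos_frequency = pos_frequency, neg_frequency = neg_frequency,
              top_pos = top_of(pos_frequency),
              top_neg = top_of(neg_frequency),
              annotation = annotation, lambda_used = lambda_used)
  class(out) <- "sparse_weight_summary"
  out
}

#' @export
print.sparse_weight_summary <- function(x, ...) {
  cat(sprintf("Sparse connection selection: %d edges; top positive set %d, top negative set %d\n",
              length(x$pos_frequency), length(x$top_pos),
              length(x$top_neg)))
  if (!is.null(x$annotation) && length(x$top_pos))
    cat(sprintf("  top positive set: %d/%d between-network\n",
                sum(x$annotation[x$top_pos] == "between"),
                length(x$top_pos)))
  invisible(x)
}
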