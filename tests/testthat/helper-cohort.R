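# Shared synthetic cohorts, built once per test run and cached so several
# test files can reuse them without re-simulating.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n_subjects = 12, n_roi = 20, seed = 7, ...) {
  key <- paste(n_subjects, n_roi, seed, ..., sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- sim_config(n_subjects = n_subjects, n_roi = n_roi, ...)
  gt <- generate_ground_truth(cfg, seed = seed)
  co <- simulate_cohort(gt, cfg, seed = seed + 1L)
  .cohort_cache[[key]] <- co
  co
}

cached_features <- function(metric = c("ba", "dfc"), n_subjects = 12,
                            n_roi = 20, seed = 7, ...) {
  metric <- match.arg(metric)
  key <- paste("ft", metric, n_subjects, n_roi, seed, ..., sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  co <- cached_cohort(n_subjects, n_roi, seed, ...)
  ft <- if (metric == "ba") cohort_ba_features(co) else
    cohort_dfc_features(co)
  .cohort_cache[[key]] <- ft
  ft
}

# Independent brute-force F1 oracle: per-class precision/recall from raw
# counts, no confusion matrix machinery shared with the implementation.
oracle_f1 <- function(pred, truth, classes = sort(unique(truth))) {
  f1 <- vapply(classes, function(k) {
    tp <- sum(pred == k & truth == k)
    p <- if (sum(pred == k) == 0) 0 else tp / sum(pred == k)
    r <- if (sum(truth == k) == 0) 0 else tp / sum(truth == k)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  list(f1_minor = f1, f1_macro = mean(f1))
}
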