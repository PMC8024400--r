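#' Psychometric task similarity via an RBF kernel
#'
#' Pairwise Euclidean distance pD between task rows of the psychometric
#' factor-loading matrix, mapped to similarity by the radial basis function
#' kernel S = exp(-pD^2). An average-linkage hierarchical clustering order
#' on 1 - S is attached for display.
#'
#' @param loadings task x factor numeric matrix.
#' @return A `similarity_matrix` of kind `"psychometric"` with elements
#'   `values`, `kind`, `order` (hclust leaf order) and `hclust`.
#' @export
psychometric_similarity <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  pD <- as.matrix(stats::dist(loadings))
  S <- exp(-pD^2)
  dimnames(S) <- list(rownames(loadings), rownames(loadings))
  new_similarity(S, "psychometric")
}

new_similarity <- function(S, kind, extra = list()) {
  d <- 1 - S
  d[is.na(d)] <- 2  # undefined similarities cluster as maximally distant
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  out <- c(list(values = S, kind = kind, order = hc$order, hclust = hc),
           extra)
  class(out) <- "similarity_matrix"
  out
}

#' @export
print.similarity_matrix <- function(x, ...) {
  v <- ut(x$values)
  cat(sprintf("%s task similarity: %d tasks, %d pairs, range [%.3f, %.3f]\n",
              x$kind, nrow(x$values), length(v), min(v), max(v)))
  invisible(x)
}

#' Dice overlap coefficient between two binary masks
#'
#' DICE = 2 TP / (2 TP + FN + FP), where TP is the count of shared voxels
#' and FN/FP the one-sided remainders. Defined as 0 (with a warning) when
#' both masks are empty.
#'
#' @param maskA,maskB logical arrays or vectors on the same grid.
#' @return A number in \[0, 1\].
#' @export
dice_coefficient <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)) ||
      length(maskA) != length(maskB))
    stop("grid mismatch between masks")
  a <- as.logical(maskA); b <- as.logical(maskB)
  tp <- sum(a & b)
  fp <- sum(!a & b)
  fn <- sum(a & !b)
  if (tp + fp + fn == 0) {
    warning("both masks empty; Dice defined as 0")
    return(0)
  }
  2 * tp / (2 * tp + fn + fp)
}

#' Pairwise Dice similarity of a list of task masks
#'
#' @param masks list of binary masks on one grid.
#' @return A `similarity_matrix` of kind `"dice"` (diagonal 1).
#' @export
dice_similarity <- function(masks) {
  n <- length(masks)
  S <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    S[i, j] <- S[j, i] <- dice_coefficient(masks[[i]], masks[[j]])
  new_similarity(S, "dice")
}

#' Activation-pattern task similarity
#'
#' Pearson correlation between task mean-activation vectors, with the
#' eigen-spectrum of the similarity matrix attached as a PCA scree
#' (explained-variance fractions).
#'
#' @param task_vectors task x feature matrix of mean activations.
#' @return A `similarity_matrix` of kind `"pattern"` with a `scree`
#'   element. Constant task rows give NA correlations (with a warning).
#' @export
pattern_similarity <- function(task_vectors) {
  task_vectors <- as.matrix(task_vectors)
  if (ncol(task_vectors) < 2) stop("need at least 2 features")
  sds <- apply(task_vectors, 1, stats::sd)
  if (any(sds == 0))
    warning("constant task vector(s): undefined correlations reported as NA")
  S <- suppressWarnings(stats::cor(t(task_vectors)))
  ev <- eigen(ifelse(is.na(S), 0, S), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  scree <- ev / sum(ev)
  new_similarity(S, "pattern", extra = list(scree = scree))
}

#' Association test between two task similarity matrices
#'
#' Vectorises the strict upper triangles (66 pairs for 12 tasks), computes
#' the Pearson correlation, and a one-tailed p-value from the t transform
#' of r. When `B` is a list, one test per element is run and
#' Benjamini-Hochberg correction is applied across that family.
#'
#' @param A a `similarity_matrix` (or plain task x task matrix).
#' @param B a `similarity_matrix`, plain matrix, or list of either
#'   (the FDR family).
#' @param tail `"right"` (positive association) or `"left"`.
#' @return Data frame with one row per family member: `r`, `p`, `p_fdr`,
#'   `n_pairs`, `tail`.
#' @export
similarity_association_test <- function(A, B, tail = c("right", "left")) {
  tail <- match.arg(tail)
  get_vals <- function(x) if (inherits(x, "similarity_matrix")) x$values else as.matrix(x)
  a <- get_vals(A)
  fam <- if (is.list(B) && !inherits(B, "similarity_matrix")) B else list(B)
  n_task <- nrow(a)
  if (n_task < 4) stop("need at least 4 tasks")
  va <- ut(a)
  res <- lapply(fam, function(b) {
    vb <- ut(get_vals(b))
    if (length(vb) != length(va)) stop("task sets differ between matrices")
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
      stop("zero-variance similarity vector")
    r <- stats::cor(va, vb)
    np <- length(va)
    tt <- r * sqrt((np - 2) / (1 - r^2))
    p <- if (tail == "right") stats::pt(tt, np - 2, lower.tail = FALSE)
         else stats::pt(tt, np - 2, lower.tail = TRUE)
    data.frame(r = r, p = p, n_pairs = np, tail = tail)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
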