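#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so no function in the package leaks global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Fisher z-transform with clamping
#'
#' `atanh` of a correlation, with |r| clamped just inside 1 so that
#' numerically perfect correlations stay finite.
#'
#' @param r correlations.
#' @param eps clamp margin.
#' @return Fisher z values.
#' @keywords internal
fisher_z <- function(r, eps = 1e-7) atanh(pmin(pmax(r, -1 + eps), 1 - eps))

# Upper-triangle (i < j) index pairs of a K x K symmetric matrix, in
# column-major order matching `x[upper.tri(x)]`.
edge_index <- function(K) {
  idx <- which(upper.tri(diag(K)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

# Vectorise the strict upper triangle of a symmetric matrix.
ut <- function(m) m[upper.tri(m)]

# Column z-scoring with training statistics; zero-sd columns pass through
# centred only. Returns list(x, center, scale) or applies stored stats.
zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < .Machine$double.eps] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sd, "/"), center = mu, scale = sd)
}
zscore_apply <- function(x, stats) {
  sweep(sweep(x, 2, stats$center), 2, stats$scale, "/")
}

# Deterministic mode: most frequent value, ties broken by the smallest value.
vote_mode <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}
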