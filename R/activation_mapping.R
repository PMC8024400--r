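#' Build a block-design GLM design matrix
#'
#' One HRF-convolved, unit-height boxcar regressor per task block (so the
#' per-block "sum of beta coefficients" reduces to a single coefficient),
#' plus an intercept and optional nuisance columns.
#'
#' @param events data frame with columns `task`, `block`, `onset`,
#'   `duration` (seconds) for one run.
#' @param tr_s repetition time in seconds.
#' @param frame_count number of frames in the run.
#' @param nuisance optional numeric matrix of nuisance columns
#'   (`frame_count` rows).
#' @return A `design_spec`: list with `X` (frame x column matrix), `task`,
#'   `block` (per task column), `task_cols`, `tr_s`, `frame_count`. When
#'   `events` is empty the design holds intercept/nuisance only and
#'   `has_task` is FALSE.
#' @export
build_block_design <- function(events, tr_s, frame_count, nuisance = NULL) {
  run_end <- frame_count * tr_s
  if (nrow(events) > 0) {
    if (any(events$onset < 0) || any(events$onset >= run_end))
      stop("event onsets must lie within the run")
    if (any(events$duration <= 0)) stop("event durations must be > 0")
    for (t in unique(events$task)) {
      ev <- events[events$task == t, ]
      ev <- ev[order(ev$onset), ]
      if (nrow(ev) > 1 &&
          any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)]))
        stop("overlapping blocks of the same task")
    }
  }
  cols <- list(intercept = rep(1, frame_count))
  task <- integer(0); block <- integer(0)
  if (nrow(events) > 0) {
    ord <- order(events$task, events$block)
    events <- events[ord, ]
    for (r in seq_len(nrow(events))) {
      nm <- sprintf("task%d_block%d", events$task[r], events$block[r])
      cols[[nm]] <- hrf_convolve(
        boxcar(events$onset[r], events$duration[r], tr_s, frame_count), tr_s)
      task <- c(task, events$task[r])
      block <- c(block, events$block[r])
    }
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == frame_count)
    colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(do.call(cbind, cols), nuisance)
  } else X <- do.call(cbind, cols)
  if (any(!is.finite(X))) stop("design matrix contains non-finite values")
  task_cols <- which(grepl("^task", colnames(X)))
  if (length(task_cols) && any(colSums(abs(X[, task_cols, drop = FALSE])) == 0))
    stop("all-zero task regressor (block entirely outside the run?)")
  out <- list(X = X, task = task, block = block, task_cols = task_cols,
              tr_s = tr_s, frame_count = frame_count,
              has_task = length(task_cols) > 0)
  class(out) <- "design_spec"
  out
}

#' Estimate per-block GLM betas
#'
#' Ordinary least squares of each channel (voxel or ROI) on the block
#' design; the per-block beta is the coefficient of that block's regressor.
#'
#' @param timeseries frames x channels numeric matrix.
#' @param design a `design_spec` from [build_block_design()].
#' @return A `beta_events` list: `betas` (block-event x channel matrix),
#'   `task`, `block`.
#' @export
estimate_block_betas <- function(timeseries, design) {
  stopifnot(inherits(design, "design_spec"))
  Y <- as.matrix(timeseries)
  if (nrow(Y) != design$frame_count)
    stop("frame count mismatch between time series and design")
  if (!design$has_task)
    stop("design has no task regressors; nothing to estimate")
  qr_x <- qr(design$X)
  if (qr_x$rank < ncol(design$X)) {
    dropped <- colnames(design$X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, Y)
  betas <- coefs[design$task_cols, , drop = FALSE]
  if (!is.null(colnames(Y))) colnames(betas) <- colnames(Y)
  out <- list(betas = betas, task = design$task, block = design$block)
  class(out) <- "beta_events"
  out
}

#' Block-wise activation (BA) features for a whole cohort
#'
#' Runs the block GLM per subject and task run of a synthetic cohort and
#' assembles the event x channel feature table used for classification
#' (one row per subject x task x block).
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param level `"roi"` (default) or `"voxel"` (requires a voxel layer).
#' @return A `feature_table` (see [feature_table()]), metric `"BA"`.
#' @export
cohort_ba_features <- function(cohort, level = c("roi", "voxel")) {
  level <- match.arg(level)
  cfg <- cohort$config
  dat <- if (level == "roi") cohort$ts else {
    if (is.null(cohort$voxel_ts)) stop("cohort has no voxel layer")
    cohort$voxel_ts
  }
  Tn <- run_frames(cfg)
  nb <- cfg$blocks_per_task
  rows <- list(); y <- integer(0); subject <- integer(0); block <- integer(0)
  for (s in seq_len(cfg$n_subjects)) {
    for (t in seq_len(cfg$n_tasks)) {
      ev <- cohort$events[cohort$events$subject == s &
                            cohort$events$task == t, ]
      des <- build_block_design(ev, cfg$tr_s, Tn)
      be <- estimate_block_betas(t(dat[s, t, , ]), des)
      for (b in seq_len(nb)) {
        rows[[length(rows) + 1L]] <- be$betas[be$block == b, ]
        y <- c(y, t); subject <- c(subject, s); block <- c(block, b)
      }
    }
  }
  feature_table(do.call(rbind, rows), y, subject, block,
                meta = list(metric = "BA", level = level))
}

#' Group-level task activation map with FDR and minimal-cluster correction
#'
#' One-sample t-test across subjects per voxel (activation = positive t),
#' Benjamini-Hochberg FDR at `alpha` on right-tailed p-values, and a
#' minimal-cluster rule: clusters are formed on the relaxed uncorrected
#' threshold (`relaxed_p`), cluster sizes are compared to a sign-flip
#' permutation null, clusters pass at BH-FDR < `cluster_alpha`, and the
#' smallest surviving cluster size becomes the minimal cluster size. The
#' final mask keeps FDR-surviving voxels inside relaxed clusters at least
#' that large. When `alpha >= 1` and `relaxed_p >= 1` no thresholding is
#' applied and the mask is simply all positive-t voxels.
#'
#' @param betas subject x voxel matrix of per-subject task mean betas.
#' @param dim volume dimensions of the voxel grid (default: 1-D line of
#'   voxels).
#' @param alpha voxel-level FDR rate (default 0.05).
#' @param relaxed_p relaxed uncorrected threshold for cluster formation
#'   (default 0.01).
#' @param cluster_alpha cluster-level FDR rate (default 0.05).
#' @param n_perm sign-flip permutations for the cluster-size null
#'   (default 200).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param seed RNG seed for the sign flips.
#' @return A `stat_map`: `statistic`, `p` (right-tailed), `mask` (logical),
#'   `df`, and `threshold_meta`.
#' @export
group_task_map <- function(betas, dim = NULL, alpha = 0.05,
                           relaxed_p = 0.01, cluster_alpha = 0.05,
                           n_perm = 200, connectivity = 26, seed = 1L) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (n < 2) stop("need at least 2 subjects")
  if (is.null(dim)) dim <- c(ncol(betas), 1L, 1L)
  if (prod(dim) != ncol(betas)) stop("dim does not match voxel count")

  tstat_map <- function(B) {
    m <- colMeans(B)
    s <- apply(B, 2, stats::sd)
    t <- m / (s / sqrt(n))
    t[s == 0] <- NA_real_
    t
  }
  t <- tstat_map(betas)
  if (anyNA(t))
    warning(sum(is.na(t)), " constant voxel(s) have undefined t and are masked out")
  p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  p_fdr <- stats::p.adjust(p, method = "BH")
  voxel_pass <- !is.na(t) & t > 0 & p_fdr <= alpha

  min_cluster <- 1L
  cluster_note <- "no cluster correction (no-threshold limit)"
  if (!(alpha >= 1 && relaxed_p >= 1)) {
    relaxed <- !is.na(p) & p < relaxed_p & t > 0
    labels <- label_components(array(relaxed, dim), connectivity)
    obs_sizes <- tabulate(labels[labels > 0])
    if (length(obs_sizes) == 0) {
      min_cluster <- Inf
      cluster_note <- "no relaxed-threshold clusters"
    } else {
      null_sizes <- with_seed(seed, {
        unlist(lapply(seq_len(n_perm), function(i) {
          flips <- sample(c(-1, 1), n, replace = TRUE)
          tp <- tstat_map(betas * flips)
          pp <- stats::pt(tp, df = n - 1, lower.tail = FALSE)
          lp <- label_components(array(!is.na(pp) & pp < relaxed_p & tp > 0,
                                       dim), connectivity)
          sz <- tabulate(lp[lp > 0])
          if (length(sz)) sz else 0L
        }))
      })
      cl_p <- vapply(obs_sizes, function(s)
        (sum(null_sizes >= s) + 1) / (length(null_sizes) + 1), numeric(1))
      cl_fdr <- stats::p.adjust(cl_p, method = "BH")
      surviving <- obs_sizes[cl_fdr <= cluster_alpha]
      min_cluster <- if (length(surviving)) min(surviving) else Inf
      cluster_note <- sprintf(
        "sign-flip null (%d perms), %d/%d clusters survive cluster FDR",
        n_perm, length(surviving), length(obs_sizes))
      keep_cl <- which(obs_sizes >= min_cluster)
      in_big_cluster <- labels > 0 & labels %in% keep_cl
      voxel_pass <- voxel_pass & as.vector(in_big_cluster)
    }
    if (is.infinite(min_cluster)) voxel_pass[] <- FALSE
  }

  out <- list(statistic = array(t, dim), p = array(p, dim),
              mask = array(voxel_pass, dim), df = n - 1,
              threshold_meta = list(alpha = alpha, correction = "BH",
                                    relaxed_p = relaxed_p,
                                    cluster_alpha = cluster_alpha,
                                    min_cluster_size = min_cluster,
                                    connectivity = connectivity,
                                    cluster_rule = cluster_note,
                                    per_map = TRUE))
  class(out) <- "stat_map"
  out
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("Statistical map: %s grid, %d/%d voxels suprathreshold\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              length(x$mask)))
  tm <- x$threshold_meta
  cat(sprintf("  alpha = %g (%s), relaxed p = %g, min cluster = %s\n",
              tm$alpha, tm$correction, tm$relaxed_p,
              format(tm$min_cluster_size)))
  invisible(x)
}

#' Conjunction, union and overlap-count algebra of task maps
#'
#' Intersection mask = voxelwise AND of all task masks, carrying the
#' minimum statistic on the conjunction; union = OR; plus the per-voxel
#' count of tasks active and the exact-k overlap percentages over the
#' union (the treemap proportions).
#'
#' @param maps list of `stat_map` objects (or logical arrays) on one grid.
#' @return An `overlap_summary`: `union_mask`, `intersection_mask`,
#'   `intersection_statistic` (min t on the conjunction, 0 elsewhere),
#'   `overlap_count`, and `kway_percent` (named k = 1..n_tasks, summing
#'   to 100 over the union).
#' @export
overlap_maps <- function(maps) {
  get_mask <- function(m) if (inherits(m, "stat_map")) m$mask else as_volume(m)
  masks <- lapply(maps, get_mask)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1))))
    stop("grid mismatch between maps")
  count <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  n <- length(masks)
  inter <- count == n
  uni <- count > 0
  stat_min <- array(0, d)
  if (any(inter) && all(vapply(maps, inherits, logical(1), "stat_map"))) {
    stat_stack <- vapply(maps, function(m) as.vector(m$statistic),
                         numeric(length(inter)))
    stat_min[inter] <- apply(stat_stack[as.vector(inter), , drop = FALSE],
                             1, min)
  }
  kway <- vapply(seq_len(n), function(k) sum(count == k), numeric(1))
  total <- sum(uni)
  kway_percent <- if (total > 0) 100 * kway / total else rep(NA_real_, n)
  names(kway_percent) <- seq_len(n)
  out <- list(union_mask = uni, intersection_mask = inter,
              intersection_statistic = stat_min, overlap_count = count,
              kway_percent = kway_percent, n_tasks = n)
  class(out) <- "overlap_summary"
  out
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Overlap of %d task maps: union %d voxels, intersection %d voxels\n",
              x$n_tasks, sum(x$union_mask), sum(x$intersection_mask)))
  top <- utils::head(sort(x$kway_percent, decreasing = TRUE), 3)
  cat("  largest exact-k shares (%):",
      paste(sprintf("k=%s: %.1f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Temporal signal-to-noise quality control
#'
#' Temporal SNR = mean/SD per voxel, summarised by the run median; runs
#' with median SNR below `cutoff` (default 5) are flagged as outliers.
#'
#' @param timeseries frames x voxels matrix for one run, or a list of such
#'   matrices (one per run).
#' @param cutoff SNR flag threshold (default 5).
#' @return Data frame with `run`, `snr` (run median) and `flag`.
#' @export
tsnr_qc <- function(timeseries, cutoff = 5) {
  runs <- if (is.list(timeseries)) timeseries else list(timeseries)
  res <- lapply(seq_along(runs), function(i) {
    Y <- as.matrix(runs[[i]])
    if (nrow(Y) < 10) stop("need at least 10 frames for tSNR")
    m <- colMeans(Y)
    s <- apply(Y, 2, stats::sd)
    snr <- m / s
    if (any(s == 0)) {
      warning("zero-variance series: infinite tSNR reported")
      snr[s == 0] <- Inf
    }
    data.frame(run = i, snr = stats::median(snr))
  })
  out <- do.call(rbind, res)
  out$flag <- out$snr < cutoff
  out
}
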