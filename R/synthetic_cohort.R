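#' Simulation configuration for a block-design cohort
#'
#' Defines the acquisition geometry of a simulated cohort: every task is one
#' run of `blocks_per_task` one-minute blocks separated by rest, sampled at
#' `tr_s`. Defaults mirror a 60-subject battery of 12 tasks acquired as three
#' 1-min blocks separated by 20 s of rest at TR = 2 s.
#'
#' @param n_subjects number of subjects (default 60).
#' @param n_tasks number of tasks (default 12).
#' @param n_factors number of latent psychometric factors (default 3).
#' @param n_roi number of ROIs (default 40).
#' @param n_networks number of resting-state networks the ROIs tile
#'   (default 7; capped at `floor(n_roi / 2)` so every network holds at
#'   least one within-network ROI pair).
#' @param blocks_per_task task blocks per run (default 3).
#' @param block_s block duration in seconds (default 60).
#' @param rest_s rest duration before each block in seconds (default 20).
#' @param tr_s repetition time in seconds (default 2).
#' @param voxels_per_roi voxels per ROI for the optional voxel layer
#'   (0 = ROI level only).
#' @param noise_sd measurement noise SD in BOLD units added on top of the
#'   unit-variance intrinsic signal (default 0.3).
#' @param ar_rho AR(1) temporal smoothing coefficient mimicking BOLD
#'   autocorrelation (default 0.3).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 60, n_tasks = 12, n_factors = 3,
                       n_roi = 40, n_networks = 7, blocks_per_task = 3,
                       block_s = 60, rest_s = 20, tr_s = 2,
                       voxels_per_roi = 0, noise_sd = 0.3, ar_rho = 0.3) {
  counts <- c(n_subjects = n_subjects, n_tasks = n_tasks,
              n_factors = n_factors, n_roi = n_roi, n_networks = n_networks,
              blocks_per_task = blocks_per_task)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (block_s %% tr_s != 0 || rest_s %% tr_s != 0)
    stop("block_s and rest_s must be divisible by tr_s")
  ## every network needs >= 2 ROIs for within-network edges; small ROI
  ## sets tile fewer networks
  n_networks <- min(n_networks, max(1L, floor(n_roi / 2)))
  cfg <- list(n_subjects = n_subjects, n_tasks = n_tasks,
              n_factors = n_factors, n_roi = n_roi, n_networks = n_networks,
              blocks_per_task = blocks_per_task, block_s = block_s,
              rest_s = rest_s, tr_s = tr_s, voxels_per_roi = voxels_per_roi,
              noise_sd = noise_sd, ar_rho = ar_rho)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Block-design simulation config:\n")
  cat(sprintf("  %d subjects x %d tasks x %d blocks (%ds task / %ds rest, TR %gs)\n",
              x$n_subjects, x$n_tasks, x$blocks_per_task, x$block_s,
              x$rest_s, x$tr_s))
  cat(sprintf("  %d ROIs in %d networks; voxels/ROI = %d; noise SD = %g; AR(1) rho = %g\n",
              x$n_roi, x$n_networks, x$voxels_per_roi, x$noise_sd, x$ar_rho))
  invisible(x)
}

# Block onsets (seconds) of one run: rest precedes every block.
run_onsets <- function(config) {
  config$rest_s +
    (seq_len(config$blocks_per_task) - 1) * (config$block_s + config$rest_s)
}

# Frames per run.
run_frames <- function(config) {
  as.integer(config$blocks_per_task * (config$block_s + config$rest_s) /
               config$tr_s)
}

#' Generate the planted ground truth of a synthetic cohort
#'
#' Builds the latent structure every downstream stage is meant to recover:
#' a task x factor psychometric loading matrix (rows unit-norm, one dominant
#' factor per task), task activation amplitudes and task connectivity
#' perturbations composed of a shared component, a factor-prototype
#' component, and a task-unique component with configurable mixing weights.
#' Task-unique connectivity mass is placed predominantly on between-network
#' edges (controlled by `between_bias`) and shared mass on within-network
#' edges. Every implied condition correlation matrix is checked for positive
#' definiteness at fidelity 1; generation fails with a report if the
#' requested perturbation scale breaks it.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @param w_shared,w_factor,w_unique mixing weights of the three
#'   connectivity components.
#' @param shared_scale,factor_scale,unique_scale Fisher-z magnitudes of the
#'   three components' edge perturbations.
#' @param between_bias probability that a task-unique edge is between-network
#'   (1 = all unique mass between networks).
#' @param fidelity_range range of the per-subject fidelity phi drawn
#'   uniformly; phi in \[0,1\] scales how strongly a subject expresses the
#'   task states.
#' @param behaviour_noise_sd SD of the additive noise on behavioural scores.
#' @param behaviour_slope slope linking fidelity to expected task score.
#' @param loading_jitter maximum off-factor loading before row normalisation.
#' @return A `ground_truth` object.
#' @export
generate_ground_truth <- function(config, seed = 1L,
                                  w_shared = 1, w_factor = 1, w_unique = 1,
                                  shared_scale = 0.25, factor_scale = 0.35,
                                  unique_scale = 0.45, between_bias = 0.8,
                                  fidelity_range = c(0.3, 1),
                                  behaviour_noise_sd = 0.15,
                                  behaviour_slope = 1,
                                  loading_jitter = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(between_bias >= 0, between_bias <= 1,
            all(fidelity_range >= 0), all(fidelity_range <= 1))
  K <- config$n_roi
  nt <- config$n_tasks
  nf <- config$n_factors
  with_seed(seed, {
    ## ROI -> network assignment: contiguous, near-equal blocks of 7 networks
    rsn_names <- c("DM", "DA", "FP", "LI", "SM", "VA", "VS")[
      seq_len(config$n_networks)]
    if (config$n_networks > 7)
      rsn_names <- c(rsn_names, paste0("N", 8:config$n_networks))
    rsn_labels <- sort(rep_len(seq_len(config$n_networks), K))

    ## psychometric loadings: dominant factor + uniform off-factor jitter
    dominant <- rep_len(seq_len(nf), nt)
    loadings <- matrix(0, nt, nf)
    for (t in seq_len(nt)) {
      row <- stats::runif(nf, 0, loading_jitter)
      row[dominant[t]] <- 1
      loadings[t, ] <- row / sqrt(sum(row^2))
    }
    fac_names <- c("VS", "RE", "VR")[seq_len(min(nf, 3))]
    if (nf > 3) fac_names <- c(fac_names, paste0("F", 4:nf))
    dimnames(loadings) <- list(paste0("task", seq_len(nt)), fac_names)

    ## edge bookkeeping
    ei <- edge_index(K)
    E <- nrow(ei)
    within_edge <- rsn_labels[ei$i] == rsn_labels[ei$j]

    ## Every connectivity component is a *matching* (endpoint-disjoint
    ## edge set), and the three components draw their edges from three
    ## vertex-disjoint ROI pools. Any task's total perturbation is then
    ## itself a matching, whose symmetric matrix has eigenvalues +-delta
    ## per edge: positive definiteness of every condition correlation is
    ## guaranteed by construction, for any seed and any ROI count, as long
    ## as the largest per-edge magnitude stays below the baseline's
    ## smallest eigenvalue.
    edge_of <- function(i, j) {
      a <- pmin(i, j); b <- pmax(i, j)
      a + (b - 1) * (b - 2) / 2  # upper.tri column-major linear index
    }
    matching_vec <- function(pool, scale, pos_prob, prefer_between) {
      v <- numeric(E)
      free <- rep(FALSE, K)
      free[pool] <- TRUE
      for (i in sample(pool)) {
        if (!free[i]) next
        want_between <- stats::runif(1) < prefer_between
        cand <- which(free & seq_len(K) != i &
                        ((rsn_labels != rsn_labels[i]) == want_between))
        ## hard constraint at the 0/1 limits; soft preference otherwise
        if (!length(cand) && prefer_between > 0 && prefer_between < 1)
          cand <- which(free & seq_len(K) != i)
        if (!length(cand)) next
        j <- if (length(cand) == 1L) cand else sample(cand, 1)
        free[c(i, j)] <- FALSE
        sgn <- if (stats::runif(1) < pos_prob) 1 else -1
        v[edge_of(i, j)] <- sgn * scale * stats::runif(1, 0.75, 1.25)
      }
      v
    }
    ## ROI pools: shared takes within-network pairs (one per network where
    ## possible), factors ~25% of the remainder, tasks the rest.
    shared_pairs <- ceiling(0.1 * K)
    shared_pool <- integer(0)
    for (n in sample(seq_len(config$n_networks))) {
      if (length(shared_pool) >= 2 * shared_pairs) break
      in_n <- setdiff(which(rsn_labels == n), shared_pool)
      if (length(in_n) >= 2) shared_pool <- c(shared_pool, sample(in_n, 2))
    }
    rest_pool <- setdiff(seq_len(K), shared_pool)
    rest_pool <- sample(rest_pool)
    n_factor_roi <- 2 * max(2L, ceiling(0.125 * K))
    ## the task-unique pool keeps at least 2 ROIs; at tiny K the factor
    ## component may end up empty
    n_factor_roi <- min(n_factor_roi, max(0L, length(rest_pool) - 2L))
    factor_pool <- rest_pool[seq_len(n_factor_roi)]
    unique_pool <- setdiff(rest_pool, factor_pool)

    shared <- w_shared *
      matching_vec(shared_pool, shared_scale, pos_prob = 1,
                   prefer_between = 0)
    factor_conn <- t(vapply(seq_len(nf), function(f)
      w_factor * matching_vec(factor_pool, factor_scale, pos_prob = 0.7,
                              prefer_between = 0.5),
      numeric(E)))
    unique_conn <- t(vapply(seq_len(nt), function(t)
      w_unique * matching_vec(unique_pool, unique_scale, pos_prob = 0.8,
                              prefer_between = between_bias),
      numeric(E)))

    task_connectivity <- matrix(0, nt, E)
    for (t in seq_len(nt))
      task_connectivity[t, ] <- shared + factor_conn[dominant[t], ] +
        unique_conn[t, ]

    ## baseline correlation: stronger within-network coupling
    baseline <- matrix(0.05, K, K)
    for (n in seq_len(config$n_networks)) {
      in_n <- rsn_labels == n
      baseline[in_n, in_n] <- 0.35
    }
    diag(baseline) <- 1

    ## positive-definiteness of every condition correlation at phi = 1
    z_rest <- fisher_z(ut(baseline))
    bad <- character(0)
    for (t in seq_len(nt)) {
      R <- edge_to_matrix(tanh(z_rest + task_connectivity[t, ]), K)
      ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      if (ev <= 1e-8)
        bad <- c(bad, sprintf("task %d (min eigenvalue %.3g)", t, ev))
    }
    if (length(bad))
      stop("condition correlation not positive definite at the requested ",
           "perturbation scale: ", paste(bad, collapse = "; "),
           ". Reduce shared/factor/unique scales.")

    ## task activation: shared multiple-demand-like + factor + unique ROIs
    shared_roi <- sample(K, ceiling(0.3 * K))
    task_activation <- matrix(0, nt, K)
    factor_roi <- lapply(seq_len(nf), function(f) sample(K, ceiling(0.2 * K)))
    for (t in seq_len(nt)) {
      a <- numeric(K)
      a[shared_roi] <- a[shared_roi] + stats::runif(length(shared_roi), 0.75, 1.25)
      fr <- factor_roi[[dominant[t]]]
      a[fr] <- a[fr] + stats::runif(length(fr), 0.2, 0.45)
      ur <- sample(K, max(2L, ceiling(0.1 * K)))
      a[ur] <- a[ur] + stats::runif(length(ur), 0.15, 0.35)
      task_activation[t, ] <- a
    }

    fidelity <- stats::runif(config$n_subjects, fidelity_range[1],
                             fidelity_range[2])

    gt <- list(n_tasks = nt, n_factors = nf, n_roi = K,
               factor_loadings = loadings, dominant_factor = dominant,
               task_activation = task_activation,
               task_connectivity = task_connectivity,
               shared_connectivity = shared,
               factor_connectivity = factor_conn,
               unique_connectivity = unique_conn,
               baseline_correlation = baseline,
               rsn_labels = rsn_labels, rsn_names = rsn_names,
               fidelity = fidelity,
               behaviour_noise_sd = behaviour_noise_sd,
               behaviour_slope = behaviour_slope,
               edge_index = ei, seed = as.integer(seed))
    class(gt) <- "ground_truth"
    check_loading_separation(gt)
    gt
  })
}

# Within-factor loading distances must be strictly smaller than cross-factor
# distances (construction invariant).
check_loading_separation <- function(gt) {
  d <- as.matrix(stats::dist(gt$factor_loadings))
  same <- outer(gt$dominant_factor, gt$dominant_factor, "==")
  diag(same) <- NA
  within <- d[same & upper.tri(d)]
  across <- d[!same & upper.tri(d)]
  if (length(within) && length(across) && max(within) >= min(across))
    stop("factor loading structure violated: a within-factor task pair is ",
         "at least as distant as a cross-factor pair; reduce loading_jitter")
  invisible(TRUE)
}

# Rebuild a symmetric K x K matrix (unit diagonal) from an upper-triangle
# edge vector.
edge_to_matrix <- function(edges, K, diag_value = 1) {
  m <- matrix(0, K, K)
  m[upper.tri(m)] <- edges
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Planted ground truth: %d tasks, %d factors, %d ROIs, %d networks\n",
              x$n_tasks, x$n_factors, x$n_roi, length(x$rsn_names)))
  cat(sprintf("  connectivity perturbation: %d edges; mean |shared| %.3f, mean |task-specific| %.3f (Fisher z)\n",
              ncol(x$task_connectivity),
              mean(abs(x$shared_connectivity[x$shared_connectivity != 0])),
              mean(abs(x$unique_connectivity[x$unique_connectivity != 0]))))
  cat(sprintf("  fidelity phi: %d subjects in [%.2f, %.2f]\n",
              length(x$fidelity), min(x$fidelity), max(x$fidelity)))
  invisible(x)
}

#' Simulate a block-design cohort from planted ground truth
#'
#' Draws per-condition ROI time series from the planted condition
#' correlation structure (rest = baseline; task t = baseline perturbed by
#' the fidelity-scaled task connectivity in Fisher-z space), with AR(1)
#' temporal smoothing, an HRF-convolved activation boxcar scaled by
#' `phi_s * task_activation`, and additive measurement noise. Behavioural
#' scores are an affine function of fidelity plus noise. Fully reproducible
#' from `seed`.
#'
#' @param gt a `ground_truth` from [generate_ground_truth()].
#' @param config the [sim_config()] used to build `gt`.
#' @param seed integer RNG seed.
#' @return A `cohort` object with elements `ts` (subject x task x ROI x
#'   frame array), optional `voxel_ts` and `voxel_map`, `events` (one row
#'   per task block), `behaviour` (subject x task), `gt`, and `config`.
#' @export
simulate_cohort <- function(gt, config, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sim_config"))
  if (gt$n_roi != config$n_roi || gt$n_tasks != config$n_tasks ||
      length(gt$fidelity) != config$n_subjects)
    stop("ground truth dimensions do not match config")
  K <- config$n_roi
  nt <- config$n_tasks
  ns <- config$n_subjects
  Tn <- run_frames(config)
  onsets <- run_onsets(config)
  z_rest <- fisher_z(ut(gt$baseline_correlation))
  chol_rest <- chol(gt$baseline_correlation)
  rho <- config$ar_rho
  innov_scale <- sqrt(1 - rho^2)

  box <- boxcar(onsets, rep(config$block_s, length(onsets)), config$tr_s, Tn)
  reg <- hrf_convolve(box, config$tr_s)
  task_frames <- box > 0

  with_seed(seed, {
    ts <- array(0, dim = c(ns, nt, K, Tn),
                dimnames = list(NULL, NULL, paste0("roi", seq_len(K)), NULL))
    vpr <- config$voxels_per_roi
    voxel_ts <- NULL
    voxel_map <- NULL
    if (vpr > 0) {
      voxel_map <- rep(seq_len(K), each = vpr)
      voxel_ts <- array(0, dim = c(ns, nt, K * vpr, Tn))
    }
    for (s in seq_len(ns)) {
      phi <- gt$fidelity[s]
      for (t in seq_len(nt)) {
        R_task <- edge_to_matrix(tanh(z_rest + phi * gt$task_connectivity[t, ]), K)
        ch <- tryCatch(chol(R_task), error = function(e)
          stop(sprintf("non-finite or non-PD task covariance (subject %d, task %d)",
                       s, t)))
        x <- matrix(0, K, Tn)
        innov <- matrix(stats::rnorm(K * Tn), K, Tn)
        for (f in seq_len(Tn)) {
          L <- if (task_frames[f]) ch else chol_rest
          e_f <- drop(crossprod(L, innov[, f]))
          x[, f] <- if (f == 1) e_f else rho * x[, f - 1] + innov_scale * e_f
        }
        x <- x + phi * outer(gt$task_activation[t, ], reg)
        if (config$noise_sd > 0)
          x <- x + matrix(stats::rnorm(K * Tn, sd = config$noise_sd), K, Tn)
        ts[s, t, , ] <- x
        if (vpr > 0)
          voxel_ts[s, t, , ] <- x[voxel_map, ] +
            matrix(stats::rnorm(K * vpr * Tn, sd = config$noise_sd),
                   K * vpr, Tn)
      }
    }
    behaviour <- gt$behaviour_slope * matrix(gt$fidelity, ns, nt) +
      matrix(stats::rnorm(ns * nt, sd = gt$behaviour_noise_sd), ns, nt)
    dimnames(behaviour) <- list(paste0("sub", seq_len(ns)),
                                paste0("task", seq_len(nt)))
    events <- expand.grid(block = seq_len(config$blocks_per_task),
                          task = seq_len(nt), subject = seq_len(ns))
    events <- events[, c("subject", "task", "block")]
    events$onset <- onsets[events$block]
    events$duration <- config$block_s
    rownames(events) <- NULL

    cohort <- list(ts = ts, voxel_ts = voxel_ts, voxel_map = voxel_map,
                   events = events, behaviour = behaviour, gt = gt,
                   config = config, seed = as.integer(seed))
    class(cohort) <- "cohort"
    cohort
  })
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic block-design cohort: %d subjects x %d tasks x %d blocks = %d events\n",
              cfg$n_subjects, cfg$n_tasks, cfg$blocks_per_task,
              nrow(x$events)))
  cat(sprintf("  %d ROIs x %d frames per run (TR %gs)%s\n", cfg$n_roi,
              run_frames(cfg), cfg$tr_s,
              if (!is.null(x$voxel_ts))
                sprintf("; voxel layer %d voxels", dim(x$voxel_ts)[3])
              else ""))
  invisible(x)
}

#' Write a cohort to a BIDS-flavoured directory layout
#'
#' Writes per-subject, per-task events as TSV, ROI time series as TSV,
#' `participants.tsv`, `behaviour.csv`, and the ground truth and config as
#' JSON. If the cohort carries a voxel layer and the RNifti package is
#' available, voxel runs are written as NIfTI volumes.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort$config
  for (s in seq_len(cfg$n_subjects)) {
    for (t in seq_len(cfg$n_tasks)) {
      stem <- file.path(dir, sprintf("sub-%02d_task-%02d", s, t))
      ev <- cohort$events[cohort$events$subject == s &
                            cohort$events$task == t, ]
      utils::write.table(
        data.frame(onset = ev$onset, duration = ev$duration,
                   trial_type = paste0("task", t)),
        paste0(stem, "_events.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(t(cohort$ts[s, t, , ]), paste0(stem, "_roi.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(cohort$voxel_ts) &&
          requireNamespace("RNifti", quietly = TRUE)) {
        vox <- cohort$voxel_ts[s, t, , ]
        RNifti::writeNifti(array(vox, dim = c(dim(vox)[1], 1, 1, dim(vox)[2])),
                           paste0(stem, "_bold.nii.gz"))
      }
    }
  }
  utils::write.table(
    data.frame(participant_id = sprintf("sub-%02d", seq_len(cfg$n_subjects)),
               fidelity = cohort$gt$fidelity),
    file.path(dir, "participants.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.csv(cohort$behaviour, file.path(dir, "behaviour.csv"))
  gt_json <- unclass(cohort$gt)
  gt_json$edge_index <- NULL
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
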