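#' FIR regression of the mean task-evoked response
#'
#' Builds per-task finite-impulse-response regressors (one indicator per
#' post-onset lag, shared across the task's blocks so the mean evoked
#' response is absorbed), fits OLS per ROI, and returns the residual time
#' series with a per-frame condition label: `"task"` frames (block windows
#' shifted by `hrf_shift` frames for haemodynamic delay), `"rest"` frames,
#' and `"discard"` settling frames after each transition and at run start.
#'
#' @param roi_ts frames x ROI matrix of one run.
#' @param events data frame with `task`, `block`, `onset`, `duration` for
#'   the run.
#' @param tr_s repetition time in seconds.
#' @param lag_count number of FIR lags; default block frames + 8 (covers
#'   the HRF tail at TR 2 s). Must be at least the block length in frames.
#' @param hrf_shift frames to shift task windows for haemodynamic delay
#'   (default 2).
#' @param discard settling frames dropped after each condition transition
#'   (default 2).
#' @return List: `residuals` (frames x ROI), `condition` (character per
#'   frame), `block_id` (integer per frame, 0 outside blocks), `lag_count`.
#' @export
fir_regress <- function(roi_ts, events, tr_s, lag_count = NULL,
                        hrf_shift = 2, discard = 2) {
  Y <- as.matrix(roi_ts)
  Tn <- nrow(Y)
  if (nrow(events) == 0) {
    res <- scale(Y, center = TRUE, scale = FALSE)
    return(list(residuals = res, condition = rep("rest", Tn),
                block_id = integer(Tn), lag_count = 0L))
  }
  block_frames <- as.integer(round(events$duration[1] / tr_s))
  if (is.null(lag_count)) lag_count <- block_frames + 8L
  if (lag_count < block_frames)
    stop("lag_count must cover the block duration")

  onset_f <- as.integer(round(events$onset / tr_s))  # 0-based frames
  tasks <- sort(unique(events$task))
  X <- matrix(0, Tn, length(tasks) * lag_count)
  col <- 0L
  truncated <- FALSE
  for (tk in tasks) {
    ons <- onset_f[events$task == tk]
    for (lag in 0:(lag_count - 1L)) {
      col <- col + 1L
      fr <- ons + lag + 1L
      out_of_run <- fr > Tn
      if (any(out_of_run)) truncated <- TRUE
      X[fr[!out_of_run], col] <- 1
    }
  }
  X <- cbind(1, X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient FIR design (overlapping lag windows); ",
            "dropping ", ncol(X) - qr_x$rank, " redundant column(s)")
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
    qr_x <- qr(X)
  }
  res <- Y - X %*% qr.coef(qr_x, Y)

  condition <- rep("rest", Tn)
  block_id <- integer(Tn)
  for (r in seq_len(nrow(events))) {
    bf <- as.integer(round(events$duration[r] / tr_s))
    st <- onset_f[r] + hrf_shift + 1L
    en <- min(onset_f[r] + hrf_shift + bf, Tn)
    condition[st:en] <- "task"
    block_id[st:en] <- events$block[r]
    if (hrf_shift > 0)  # onset ramp before the shifted window
      condition[(onset_f[r] + 1L):(onset_f[r] + hrf_shift)] <- "discard"
    if (en < Tn && discard > 0)
      condition[(en + 1L):min(en + discard, Tn)] <- "discard"
  }
  if (discard > 0) condition[seq_len(min(discard, Tn))] <- "discard"
  list(residuals = res, condition = condition, block_id = block_id,
       lag_count = as.integer(lag_count))
}

#' Block-wise dynamic functional connectivity contrast
#'
#' Per task block: Pearson correlation of the FIR residuals over the
#' block's task frames, Fisher z-transformed; the pooled rest frames of
#' the run give a baseline z; the dFC edge value is
#' `z_task_block - z_rest`. One edge vector per block event.
#'
#' @param fir output of [fir_regress()] for one run.
#' @param min_frames minimum frames required per window (default 10).
#' @return List: `edges` (block x edge matrix, upper-triangle order),
#'   `block` (block index per row), `edge_index` (i, j ROI pairs).
#' @export
block_dfc <- function(fir, min_frames = 10) {
  res <- fir$residuals
  K <- ncol(res)
  rest_fr <- fir$condition == "rest"
  if (sum(rest_fr) < min_frames)
    stop("fewer than ", min_frames, " rest frames in the run")
  check_constant <- function(M, what) {
    if (any(apply(M, 2, stats::sd) == 0))
      stop("constant residual series in ", what, " window")
  }
  rest_m <- res[rest_fr, , drop = FALSE]
  check_constant(rest_m, "rest")
  z_rest <- fisher_z(ut(stats::cor(rest_m)))
  blocks <- sort(unique(fir$block_id[fir$block_id > 0]))
  edges <- matrix(NA_real_, length(blocks), K * (K - 1) / 2)
  for (bi in seq_along(blocks)) {
    fr <- fir$block_id == blocks[bi] & fir$condition == "task"
    if (sum(fr) < min_frames)
      stop("task block ", blocks[bi], " has fewer than ", min_frames,
           " frames")
    bm <- res[fr, , drop = FALSE]
    check_constant(bm, "task")
    edges[bi, ] <- fisher_z(ut(stats::cor(bm))) - z_rest
  }
  list(edges = edges, block = blocks, edge_index = edge_index(K))
}

#' Dynamic functional connectivity features for a whole cohort
#'
#' Runs FIR removal and block-wise dFC per subject and task run, producing
#' the event x edge feature table (one row per subject x task x block;
#' K(K-1)/2 edges for K ROIs).
#'
#' @param cohort a `cohort`.
#' @param lag_count,hrf_shift,discard passed to [fir_regress()].
#' @return A `feature_table`, metric `"dFC"`.
#' @export
cohort_dfc_features <- function(cohort, lag_count = NULL, hrf_shift = 2,
                                discard = 2) {
  cfg <- cohort$config
  K <- cfg$n_roi
  rows <- list(); y <- integer(0); subject <- integer(0); block <- integer(0)
  for (s in seq_len(cfg$n_subjects)) {
    for (t in seq_len(cfg$n_tasks)) {
      ev <- cohort$events[cohort$events$subject == s &
                            cohort$events$task == t, ]
      fir <- fir_regress(t(cohort$ts[s, t, , ]), ev, cfg$tr_s,
                         lag_count = lag_count, hrf_shift = hrf_shift,
                         discard = discard)
      dfc <- block_dfc(fir)
      for (bi in seq_along(dfc$block)) {
        rows[[length(rows) + 1L]] <- dfc$edges[bi, ]
        y <- c(y, t); subject <- c(subject, s)
        block <- c(block, dfc$block[bi])
      }
    }
  }
  ei <- edge_index(K)
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("edge_", ei$i, "_", ei$j)
  feature_table(X, y, subject, block,
                meta = list(metric = "dFC", edge_index = ei))
}

#' Reduce edge-level dFC to within/between-network features
#'
#' Averages edges into one feature per network (both endpoints inside)
#' plus one per unordered network pair: 7 + 21 = 28 features for 7
#' networks. Each edge contributes to exactly one feature.
#'
#' @param edges event x edge matrix (or a single edge vector), edges in
#'   upper-triangle order for K ROIs.
#' @param network_labels integer network id per ROI.
#' @param network_names optional network names (default N1..N7).
#' @return Event x feature matrix with named columns (`within_DM`,
#'   `between_DM_DA`, ...). Networks with fewer than 2 ROIs yield an NA
#'   within-feature with a warning.
#' @export
rsn_reduce <- function(edges, network_labels, network_names = NULL) {
  if (is.null(dim(edges))) edges <- matrix(edges, nrow = 1)
  K <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
  if (K != round(K) || length(network_labels) != K)
    stop("edge count does not match an ROI set labelled by network_labels")
  nets <- sort(unique(network_labels))
  nn <- length(nets)
  if (is.null(network_names)) network_names <- paste0("N", nets)
  ei <- edge_index(as.integer(K))
  li <- network_labels[ei$i]; lj <- network_labels[ei$j]
  lo <- pmin(li, lj); hi <- pmax(li, lj)

  feats <- list(); nms <- character(0)
  for (a in seq_len(nn)) {
    sel <- lo == nets[a] & hi == nets[a]
    if (!any(sel)) {
      warning("network ", network_names[a],
              " has < 2 ROIs; within feature is NA")
      feats[[length(feats) + 1L]] <- rep(NA_real_, nrow(edges))
    } else {
      feats[[length(feats) + 1L]] <- rowMeans(edges[, sel, drop = FALSE])
    }
    nms <- c(nms, paste0("within_", network_names[a]))
  }
  for (a in seq_len(nn - 1)) for (b in (a + 1):nn) {
    sel <- lo == nets[a] & hi == nets[b]
    feats[[length(feats) + 1L]] <-
      if (any(sel)) rowMeans(edges[, sel, drop = FALSE])
      else rep(NA_real_, nrow(edges))
    nms <- c(nms, paste0("between_", network_names[a], "_",
                         network_names[b]))
  }
  out <- do.call(cbind, feats)
  colnames(out) <- nms
  out
}

#' Subject-level 28-feature RSN connectome
#'
#' Reduces a dFC feature table to network features and averages across
#' each subject's events (all tasks and blocks), yielding one reduced
#' connectome row per subject.
#'
#' @param ft a dFC `feature_table`.
#' @param network_labels integer network id per ROI.
#' @param network_names optional network names.
#' @return Subject x feature matrix (rownames = subject ids).
#' @export
subject_rsn_features <- function(ft, network_labels, network_names = NULL) {
  red <- rsn_reduce(ft$X, network_labels, network_names)
  subs <- sort(unique(ft$subject))
  out <- t(vapply(subs, function(s)
    colMeans(red[ft$subject == s, , drop = FALSE]), numeric(ncol(red))))
  rownames(out) <- subs
  out
}
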