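make_events <- function() {
  data.frame(task = 1, block = 1:3, onset = c(20, 100, 180), duration = 60)
}

test_that("three 60 s blocks with 20 s rest at TR 2 give 3 task columns
           over 120 frames", {
  des <- build_block_design(make_events(), tr_s = 2, frame_count = 120)
  expect_equal(length(des$task_cols), 3)
  expect_equal(nrow(des$X), 120)
  expect_true("intercept" %in% colnames(des$X))
})

test_that("empty event table yields an intercept-only design flagged as
           taskless", {
  des <- build_block_design(make_events()[0, ], tr_s = 2, frame_count = 120)
  expect_false(des$has_task)
  expect_error(estimate_block_betas(matrix(rnorm(120), 120), des),
               "no task regressors")
})

test_that("design construction rejects malformed events", {
  ev <- make_events()
  ev$onset[2] <- 70  # overlaps block 1 (20-80 s)
  expect_error(build_block_design(ev, 2, 120), "overlapping")
  ev2 <- make_events(); ev2$onset[3] <- 400
  expect_error(build_block_design(ev2, 2, 120), "within the run")
})

test_that("a single TR-length block at t=0 reproduces the sampled HRF", {
  ev <- data.frame(task = 1, block = 1, onset = 0, duration = 2)
  des <- build_block_design(ev, tr_s = 2, frame_count = 40)
  h <- hrf_double_gamma(2)
  expect_equal(unname(des$X[seq_along(h), 2]), unname(h))
})

test_that("OLS block betas are exact on noiseless data and zero for
           orthogonal signals", {
  des <- build_block_design(make_events(), tr_s = 2, frame_count = 120)
  y <- 2.5 * des$X[, "task1_block2"]
  be <- estimate_block_betas(matrix(y, ncol = 1), des)
  expect_equal(unname(be$betas[be$block == 2, 1]), 2.5)
  expect_equal(unname(be$betas[be$block == 1, 1]), 0)
  ## signal orthogonal to all task regressors
  q <- qr.Q(qr(des$X))
  v <- rnorm(120)
  y2 <- v - q %*% crossprod(q, v)
  be2 <- estimate_block_betas(matrix(y2, ncol = 1), des)
  expect_true(all(abs(be2$betas) < 1e-8))
})

test_that("betas match an independent normal-equations solve", {
  set.seed(31)
  des <- build_block_design(make_events(), tr_s = 2, frame_count = 120)
  Y <- matrix(rnorm(120 * 6), 120)
  be <- estimate_block_betas(Y, des)
  ref <- solve(crossprod(des$X), crossprod(des$X, Y))
  expect_equal(unname(be$betas), unname(ref[des$task_cols, ]),
               tolerance = 1e-10)
})

test_that("noise-free unit-fidelity cohort betas recover the planted
           activation amplitudes", {
  cfg <- sim_config(n_subjects = 6, n_roi = 10, noise_sd = 0)
  gt <- generate_ground_truth(cfg, seed = 9, fidelity_range = c(1, 1))
  co <- simulate_cohort(gt, cfg, seed = 10)
  ## intrinsic fluctuations (sd 1) remain, so single-block betas carry
  ## sampling noise; average blocks and subjects before comparing
  est <- rowMeans(vapply(seq_len(cfg$n_subjects), function(s) {
    ev <- co$events[co$events$subject == s & co$events$task == 1, ]
    des <- build_block_design(ev, cfg$tr_s, 120)
    colMeans(estimate_block_betas(t(co$ts[s, 1, , ]), des)$betas)
  }, numeric(10)))
  expect_equal(unname(est), unname(gt$task_activation[1, ]),
               tolerance = 0.3)
  expect_gt(cor(est, gt$task_activation[1, ]), 0.9)
})

test_that("rank-deficient designs are reported with the collinear column", {
  ev <- make_events()
  des <- build_block_design(ev, 2, 120)
  des$X <- cbind(des$X, dup = des$X[, "task1_block1"])
  expect_error(estimate_block_betas(matrix(rnorm(120), 120), des),
               "collinear")
})

test_that("group map covers planted voxels and excludes null voxels", {
  set.seed(21)
  n <- 24
  B <- matrix(rnorm(n * 120), n)
  B[, 1:30] <- B[, 1:30] + 1.2
  sm <- group_task_map(B, alpha = 0.05, n_perm = 100, seed = 1)
  expect_gt(mean(sm$mask[1:30]), 0.9)      # power on planted voxels
  expect_lt(mean(sm$mask[31:120]), 0.05)   # false positives controlled
})

test_that("constant voxels are masked out with a warning", {
  set.seed(22)
  B <- matrix(rnorm(12 * 20), 12)
  B[, 5] <- 3  # identical beta for every subject: undefined t
  expect_warning(sm <- group_task_map(B, n_perm = 50, seed = 1),
                 "constant")
  expect_false(sm$mask[5])
})

test_that("no-threshold limit masks exactly the positive-t voxels", {
  set.seed(23)
  B <- matrix(rnorm(10 * 50), 10)
  sm <- group_task_map(B, alpha = 1, relaxed_p = 1)
  expect_equal(as.vector(sm$mask), as.vector(sm$statistic > 0))
})

test_that("FDR mask grows monotonically with alpha", {
  set.seed(24)
  B <- matrix(rnorm(16 * 80), 16)
  B[, 1:20] <- B[, 1:20] + 0.8
  m1 <- group_task_map(B, alpha = 0.01, n_perm = 80, seed = 5)
  m2 <- group_task_map(B, alpha = 0.10, n_perm = 80, seed = 5)
  expect_true(all(m2$mask[m1$mask]))  # alpha 0.01 mask inside alpha 0.10
})

test_that("overlap algebra matches brute-force set enumeration", {
  ids <- function(v) { m <- rep(FALSE, 6); m[v] <- TRUE; m }
  ov <- overlap_maps(list(ids(1:3), ids(2:4), ids(3:5)))
  expect_equal(sum(ov$union_mask), 5)
  expect_equal(sum(ov$intersection_mask), 1)
  expect_equal(unname(ov$kway_percent), c(40, 40, 20))
  expect_equal(sum(ov$kway_percent), 100)
})

test_that("identical and disjoint masks hit the overlap limits", {
  m <- c(TRUE, TRUE, FALSE, FALSE)
  ov_same <- overlap_maps(rep(list(m), 12))
  expect_equal(ov_same$intersection_mask, ov_same$union_mask)
  expect_equal(unname(ov_same$kway_percent[12]), 100)
  ov_disj <- overlap_maps(list(c(TRUE, FALSE), c(FALSE, TRUE)))
  expect_equal(sum(ov_disj$intersection_mask), 0)
  expect_equal(unname(ov_disj$kway_percent[1]), 100)
})

test_that("overlap set algebra invariants hold on random masks", {
  set.seed(25)
  for (i in 1:5) {
    masks <- lapply(1:6, function(j) runif(40) < 0.4)
    ov <- overlap_maps(masks)
    sizes <- vapply(masks, sum, numeric(1))
    expect_lte(sum(ov$intersection_mask), min(sizes))
    expect_gte(sum(ov$union_mask), max(sizes))
    counts <- vapply(1:6, function(k) sum(ov$overlap_count == k), numeric(1))
    expect_equal(sum(counts), sum(ov$union_mask))
  }
})

test_that("tSNR flags runs below the cutoff", {
  set.seed(26)
  good <- matrix(100 + rnorm(100 * 20, 0, 10), 100)
  qc <- tsnr_qc(good)
  expect_equal(qc$snr, 10, tolerance = 1)
  expect_false(qc$flag)
  low <- matrix(4 + rnorm(100 * 20, 0, 1), 100)
  expect_true(tsnr_qc(low)$flag)
  noise <- matrix(rnorm(100 * 20), 100)
  expect_true(tsnr_qc(noise)$flag)
})
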