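test_that("sim_config validates geometry", {
  expect_error(sim_config(block_s = 61), "divisible")
  expect_error(sim_config(n_subjects = 0), ">= 1")
  cfg <- sim_config()
  expect_equal(cfg$n_subjects * cfg$n_tasks * cfg$blocks_per_task, 2160)
})

test_that("degenerate mixture: no factor/unique weight collapses all task
           connectivity onto the shared component", {
  cfg <- sim_config(n_subjects = 4, n_roi = 20)
  gt <- generate_ground_truth(cfg, seed = 1, w_factor = 0, w_unique = 0)
  for (t in seq_len(gt$n_tasks))
    expect_equal(gt$task_connectivity[t, ], gt$shared_connectivity)
})

test_that("within-factor loading distances are smaller than cross-factor
           distances (all 66 pairs, brute force)", {
  cfg <- sim_config(n_subjects = 4, n_roi = 20)
  gt <- generate_ground_truth(cfg, seed = 1)
  d <- as.matrix(dist(gt$factor_loadings))
  same <- outer(gt$dominant_factor, gt$dominant_factor, "==")
  within <- d[same & upper.tri(d)]
  across <- d[!same & upper.tri(d)]
  expect_length(within, 18)  # 3 factors x choose(4, 2)
  expect_length(across, 66 - 18)
  expect_lt(mean(within), mean(across))
  expect_lt(max(within), min(across))
})

test_that("between-edge bias 1 puts all task-unique mass on between-network
           edges", {
  cfg <- sim_config(n_subjects = 4, n_roi = 20)
  gt <- generate_ground_truth(cfg, seed = 2, between_bias = 1)
  ei <- gt$edge_index
  between <- gt$rsn_labels[ei$i] != gt$rsn_labels[ei$j]
  for (t in seq_len(gt$n_tasks)) {
    nz <- gt$unique_connectivity[t, ] != 0
    expect_true(all(between[nz]))
  }
})

test_that("condition correlations are positive definite by construction", {
  cfg <- sim_config(n_subjects = 4, n_roi = 30)
  for (seed in 1:3) {
    gt <- generate_ground_truth(cfg, seed = seed)
    z <- netstate:::fisher_z(netstate:::ut(gt$baseline_correlation))
    for (t in seq_len(gt$n_tasks)) {
      R <- netstate:::edge_to_matrix(tanh(z + gt$task_connectivity[t, ]), 30)
      expect_gt(min(eigen(R, only.values = TRUE)$values), 0)
    }
  }
  expect_error(
    generate_ground_truth(sim_config(n_subjects = 4, n_roi = 20), seed = 1,
                          unique_scale = 3),
    "positive definite")
})

test_that("cohort has the full event grid and run geometry", {
  co <- cached_cohort(n_subjects = 6, n_roi = 8)
  cfg <- co$config
  expect_equal(nrow(co$events), 6 * 12 * 3)
  per <- table(co$events$subject, co$events$task)
  expect_true(all(per == cfg$blocks_per_task))
  expect_equal(dim(co$ts)[4], netstate:::run_frames(cfg))
  expect_equal(netstate:::run_frames(cfg), 120)  # 3 x (20 + 60) s at TR 2
})

test_that("identical seeds give bit-identical cohorts, different seeds do not", {
  cfg <- sim_config(n_subjects = 3, n_roi = 8)
  gt <- generate_ground_truth(cfg, seed = 5)
  a <- simulate_cohort(gt, cfg, seed = 9)
  b <- simulate_cohort(gt, cfg, seed = 9)
  c <- simulate_cohort(gt, cfg, seed = 10)
  expect_identical(a$ts, b$ts)
  expect_identical(a$behaviour, b$behaviour)
  expect_false(identical(a$ts, c$ts))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(cached_cohort(n_subjects = 3, n_roi = 8, seed = 42))
  cfg <- sim_config(n_subjects = 3, n_roi = 8)
  gt <- generate_ground_truth(cfg, seed = 1)
  invisible(simulate_cohort(gt, cfg, seed = 2))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("noise-free behaviour is an affine function of fidelity and PC1
           recovers it exactly", {
  cfg <- sim_config(n_subjects = 12, n_roi = 8)
  gt <- generate_ground_truth(cfg, seed = 3, behaviour_noise_sd = 0)
  co <- simulate_cohort(gt, cfg, seed = 4)
  expect_equal(cor(co$behaviour[, 1], gt$fidelity), 1)
  pi <- performance_index(co$behaviour + matrix(rnorm(12 * 12, 0, 1e-9), 12))
  expect_equal(abs(cor(pi$pi, gt$fidelity)), 1, tolerance = 1e-6)
})

test_that("noise-free unit-fidelity task correlations converge to the
           planted condition correlations over long blocks", {
  cfg <- sim_config(n_subjects = 1, n_roi = 10, block_s = 600, rest_s = 60,
                    noise_sd = 0, ar_rho = 0)
  gt <- generate_ground_truth(cfg, seed = 6, fidelity_range = c(1, 1))
  co <- simulate_cohort(gt, cfg, seed = 7)
  box <- netstate:::boxcar(netstate:::run_onsets(cfg), rep(600, 3), 2,
                           netstate:::run_frames(cfg))
  x <- t(co$ts[1, 1, , ])
  ## remove the activation mean before correlating
  reg <- hrf_convolve(box, 2)
  resid <- apply(x, 2, function(col) residuals(lm(col ~ reg)))
  emp <- cor(resid[box > 0, ])
  z <- netstate:::fisher_z(netstate:::ut(gt$baseline_correlation))
  planted <- netstate:::edge_to_matrix(tanh(z + gt$task_connectivity[1, ]), 10)
  diffs <- abs(netstate:::ut(emp) - netstate:::ut(planted))
  expect_lt(mean(diffs), 0.035)
  expect_lt(max(diffs), 0.12)
})

test_that("cohort writes a BIDS-flavoured layout", {
  co <- cached_cohort(n_subjects = 3, n_roi = 8, seed = 42)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_true(file.exists(file.path(dir, "behaviour.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  ev <- read_events_tsv(file.path(dir, "sub-01_task-01_events.tsv"))
  expect_equal(nrow(ev), 3)
  expect_equal(ev$onset, c(20, 100, 180))
  expect_equal(ev$task, rep(1, 3))
})
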