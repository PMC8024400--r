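run_events <- function() {
  data.frame(task = 1, block = 1:3, onset = c(20, 100, 180), duration = 60)
}

test_that("FIR absorbs any response shape repeated across blocks", {
  tr <- 2; Tn <- 120
  shape <- sin(seq(0, pi, length.out = 30))  # arbitrary evoked response
  x <- numeric(Tn)
  for (on in c(10, 50, 90)) x[on + seq_len(30)] <- shape
  fir <- fir_regress(matrix(x, ncol = 1), run_events(), tr)
  expect_lt(max(abs(fir$residuals[fir$condition == "task", 1])), 1e-8)
})

test_that("without events the residuals are the mean-centred input", {
  set.seed(61)
  y <- matrix(rnorm(50 * 3) + 5, 50)
  fir <- fir_regress(y, run_events()[0, ], 2)
  expect_equal(unname(fir$residuals), unname(scale(y, scale = FALSE)),
               tolerance = 1e-12)
  expect_true(all(fir$condition == "rest"))
})

test_that("FIR residual correlations recover the planted noise correlation,
           not the co-activation", {
  set.seed(62)
  tr <- 2; Tn <- 120
  rho_true <- 0.4
  Sigma <- matrix(c(1, rho_true, rho_true, 1), 2)
  L <- chol(Sigma)
  noise <- matrix(rnorm(Tn * 2), Tn) %*% L
  evoked <- hrf_convolve(boxcar(c(20, 100, 180), rep(60, 3), tr, Tn), tr)
  x <- noise + 3 * cbind(evoked, evoked)  # strong shared activation
  ## correlating across the run without removing the evoked response lets
  ## the shared boxcar variance masquerade as connectivity
  raw_r <- cor(scale(x, scale = FALSE))[1, 2]
  fir <- fir_regress(x, run_events(), tr)
  fir_r <- cor(fir$residuals[fir$condition == "task", ])[1, 2]
  expect_gt(raw_r, 0.7)
  expect_equal(fir_r, rho_true, tolerance = 0.12)
})

test_that("lag window must cover the block and rank problems are reported", {
  y <- matrix(rnorm(120 * 2), 120)
  expect_error(fir_regress(y, run_events(), 2, lag_count = 10),
               "cover the block")
})

test_that("dFC edge vector has K(K-1)/2 entries per block event", {
  co <- cached_cohort(n_subjects = 3, n_roi = 8)
  ev <- co$events[co$events$subject == 1 & co$events$task == 1, ]
  fir <- fir_regress(t(co$ts[1, 1, , ]), ev, 2)
  d <- block_dfc(fir)
  expect_equal(dim(d$edges), c(3, 8 * 7 / 2))
  expect_true(all(is.finite(d$edges)))
})

test_that("null contrast: without connectivity perturbation dFC edges
           shrink toward zero as blocks lengthen", {
  base_cfg <- list(n_subjects = 1, n_roi = 10, noise_sd = 0)
  mean_abs <- vapply(c(60, 300), function(bs) {
    ## rest scales with the blocks so both window estimates tighten
    cfg <- do.call(sim_config, c(base_cfg, list(block_s = bs,
                                                rest_s = bs / 3)))
    gt <- generate_ground_truth(cfg, seed = 63, w_shared = 0, w_factor = 0,
                                w_unique = 0)
    co <- simulate_cohort(gt, cfg, seed = 64)
    ev <- co$events[co$events$subject == 1 & co$events$task == 1, ]
    fir <- fir_regress(t(co$ts[1, 1, , ]), ev, 2)
    mean(abs(block_dfc(fir)$edges))
  }, numeric(1))
  expect_lt(mean_abs[2], mean_abs[1])
  expect_lt(mean_abs[2], 0.15)
})

test_that("condition swap negates every dFC edge", {
  co <- cached_cohort(n_subjects = 3, n_roi = 8)
  ev <- co$events[co$events$subject == 2 & co$events$task == 2, ]
  fir <- fir_regress(t(co$ts[2, 2, , ]), ev, 2)
  d <- block_dfc(fir)
  swapped <- fir
  task_fr <- fir$condition == "task"
  rest_fr <- fir$condition == "rest"
  swapped$condition[task_fr] <- "rest"
  swapped$condition[rest_fr] <- "task"
  swapped$block_id <- integer(length(fir$block_id))
  swapped$block_id[rest_fr] <- 1L
  d_sw <- block_dfc(swapped)
  ## one pooled pseudo-block of former rest vs former task as baseline
  pooled_task <- netstate:::fisher_z(
    netstate:::ut(cor(fir$residuals[task_fr, ])))
  pooled_rest <- netstate:::fisher_z(
    netstate:::ut(cor(fir$residuals[rest_fr, ])))
  expect_equal(as.vector(d_sw$edges[1, ]), pooled_rest - pooled_task,
               tolerance = 1e-10)
})

test_that("RSN reduction: 7 networks give 28 features, constants pass
           through, toy blocks match hand-computed means", {
  edges28 <- rsn_reduce(matrix(0.3, 2, 21 * 20 / 2), rep(1:7, each = 3))
  expect_equal(ncol(edges28), 28)
  expect_true(all(edges28 == 0.3))
  ## 6 ROIs, 3 networks of 2: hand-computed block means
  lab <- c(1, 1, 2, 2, 3, 3)
  ei <- netstate:::edge_index(6)
  v <- seq_len(15) / 10
  red <- rsn_reduce(v, lab, network_names = c("A", "B", "C"))
  hand <- function(sel) mean(v[sel])
  w11 <- which(lab[ei$i] == 1 & lab[ei$j] == 1)
  w12 <- which(pmin(lab[ei$i], lab[ei$j]) == 1 &
                 pmax(lab[ei$i], lab[ei$j]) == 2)
  expect_equal(unname(red[1, "within_A"]), hand(w11))
  expect_equal(unname(red[1, "between_A_B"]), hand(w12))
  expect_equal(ncol(red), 3 + 3)
})

test_that("every edge contributes to exactly one RSN feature", {
  lab <- rep(1:7, length.out = 21)
  ei <- netstate:::edge_index(21)
  counted <- 0
  for (a in 1:7) for (b in a:7) {
    lo <- pmin(lab[ei$i], lab[ei$j]); hi <- pmax(lab[ei$i], lab[ei$j])
    counted <- counted + sum(lo == a & hi == b)
  }
  expect_equal(counted, nrow(ei))
})

test_that("a network with a single ROI yields NA within-feature with a
           warning", {
  lab <- c(1, 1, 2)
  expect_warning(red <- rsn_reduce(c(0.1, 0.2, 0.3), lab), "< 2 ROIs")
  expect_true(is.na(red[1, "within_N2"]))
})

test_that("subject-level RSN features average all of a subject's events", {
  dfc <- cached_features("dfc", n_subjects = 3, n_roi = 8)
  co <- cached_cohort(n_subjects = 3, n_roi = 8)
  subj <- subject_rsn_features(dfc, co$gt$rsn_labels)
  expect_equal(nrow(subj), 3)
  red <- rsn_reduce(dfc$X, co$gt$rsn_labels)
  expect_equal(unname(subj[1, ]),
               unname(colMeans(red[dfc$subject == 1, ])))
})

test_that("FIR-residual dFC suppresses the co-activation inflation that
           unregressed dFC suffers", {
  ## shared evoked response, no planted connectivity difference: any
  ## deviation of estimated connectivity from the planted baseline is
  ## co-activation leakage
  cfg <- sim_config(n_subjects = 50, n_tasks = 1, n_roi = 6, noise_sd = 0.2)
  gt <- generate_ground_truth(cfg, seed = 65, w_shared = 0, w_factor = 0,
                              w_unique = 0, fidelity_range = c(1, 1))
  ## give every ROI the same strong evoked response
  gt$task_activation[1, ] <- 2
  co <- simulate_cohort(gt, cfg, seed = 66)
  planted <- netstate:::ut(gt$baseline_correlation)
  infl_fir <- numeric(50); infl_raw <- numeric(50)
  for (s in 1:50) {
    x <- t(co$ts[s, 1, , ])
    ev <- co$events[co$events$subject == s, ]
    fir <- fir_regress(x, ev, 2)
    keep <- fir$condition != "discard"
    infl_fir[s] <- mean(abs(netstate:::ut(cor(fir$residuals[keep, ])) -
                              planted))
    infl_raw[s] <- mean(abs(netstate:::ut(cor(x[keep, ])) - planted))
  }
  expect_lt(mean(infl_fir), mean(infl_raw))  # paired, 50 subjects
  expect_gt(mean(infl_raw - infl_fir), 0)
})
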