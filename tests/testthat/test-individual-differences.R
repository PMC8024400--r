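test_that("rank-1 score table recovers the subject factor exactly", {
  netstate:::with_seed(111, {
    phi <- runif(20)
    w <- runif(12, 0.5, 1.5)
    scores <- outer(phi, w)
    pi <- performance_index(scores)
    expect_equal(abs(cor(pi$pi, phi)), 1, tolerance = 1e-10)
    expect_equal(mean(pi$pi), 0, tolerance = 1e-12)
    expect_equal(sd(pi$pi), 1, tolerance = 1e-12)
    expect_true(mean(pi$loadings) >= 0)
  })
})

test_that("i.i.d. noise scores explain roughly 1/12 + O(n^-1/2) variance
           on PC1", {
  netstate:::with_seed(112, {
    n <- 1500
    pi <- performance_index(matrix(rnorm(n * 12), n))
    ## finite-n null: top eigenvalue inflates 1/12 by (1 + sqrt(p/n))^2
    expected_top <- (1 + sqrt(12 / n))^2 / 12
    expect_gt(pi$var_explained, 1 / 12)
    expect_equal(pi$var_explained, expected_top, tolerance = 0.08)
    expect_lt(pi$var_explained, 0.15)
  })
})

test_that("default synthetic behaviour couples PC1 tightly to fidelity", {
  co <- cached_cohort(n_subjects = 12, n_roi = 20)
  pi <- performance_index(co$behaviour)
  expect_gt(abs(cor(pi$pi, co$gt$fidelity)), 0.8)
})

test_that("missing scores are imputed with a warning; degenerate input
           errors", {
  s <- matrix(rnorm(30), 10)
  s[3, 2] <- NA
  expect_warning(performance_index(s), "imputed")
  expect_error(performance_index(matrix(1, 5, 3)), "rank-0")
})

test_that("subject classifiability counts correct blocks out of 36", {
  ev <- expand.grid(block = 1:3, truth = 1:12, subject = 1:4)
  ev$pred <- ev$truth
  sc <- subject_classifiability(ev)
  expect_equal(sc$total, rep(36, 4))
  expect_equal(sc$accuracy, rep(1, 4))
  expect_false(any(sc$outlier_flag[sc$accuracy == 1]))
})

test_that("uniform random predictions land near chance = 3/36 and a
           planted low-fidelity subject is flagged", {
  netstate:::with_seed(113, {
    ev <- expand.grid(block = 1:3, truth = 1:12, subject = 1:30)
    ev$pred <- sample(1:12, nrow(ev), TRUE)
    sc <- subject_classifiability(ev)
    expect_equal(mean(sc$correct), 3, tolerance = 0.8)
    ## strong cohort with one at-chance subject
    ev2 <- expand.grid(block = 1:3, truth = 1:12, subject = 1:12)
    ev2$pred <- ev2$truth
    weak <- ev2$subject == 5
    ev2$pred[weak] <- sample(1:12, sum(weak), TRUE)
    sc2 <- subject_classifiability(ev2)
    expect_true(sc2$outlier_flag[sc2$subject == 5])
    expect_false(any(sc2$outlier_flag[sc2$subject != 5]))
  })
})

test_that("accuracy-PI association is right-tailed, FDR-corrected across
           the family, and excludes outliers", {
  netstate:::with_seed(114, {
    n <- 24
    pi <- list(pi = as.numeric(scale(rnorm(n))))
    acc <- data.frame(subject = 1:n, correct = 0, total = 36,
                      accuracy = plogis(pi$pi + rnorm(n, 0, 0.5)),
                      outlier_flag = FALSE)
    res <- accuracy_pi_association(acc, pi)
    expect_gt(res$r, 0)
    expect_lt(res$p, 0.05)
    anti <- acc; anti$accuracy <- -acc$accuracy
    res2 <- accuracy_pi_association(list(acc, anti), pi)
    expect_equal(res2$p_fdr, p.adjust(res2$p, "BH"))
    expect_gt(res2$p[2], 0.5)  # right tail on a negative association
  })
})

test_that("boosted trees fit a realisable tree target almost perfectly", {
  netstate:::with_seed(115, {
    n <- 24
    X <- matrix(rnorm(n * 28), n)
    colnames(X) <- paste0("f", 1:28)
    y <- ifelse(X[, 7] > 0.5, 2, ifelse(X[, 7] > -0.5, 0, -2))
    te <- boosted_tree_regression(X, y)
    expect_lt(te$mse, 0.25 * var(y))
    expect_gt(te$r, 0.85)
    expect_equal(names(which.max(te$importance)), "f7")
  })
})

test_that("boosted trees on an independent target give near-zero skill", {
  netstate:::with_seed(116, {
    n <- 24
    X <- matrix(rnorm(n * 10), n)
    y <- rnorm(n)
    te <- boosted_tree_regression(
      X, y, grid = list(max_splits = c(1, 3), n_trees = c(3, 10)))
    expect_lt(te$r, 0.6)
    expect_gt(te$mse, 0.4 * var(y))
  })
})

test_that("training loss is non-increasing over boosting iterations", {
  netstate:::with_seed(117, {
    n <- 40
    X <- matrix(rnorm(n * 6), n); colnames(X) <- paste0("f", 1:6)
    y <- X[, 1] + 0.5 * rnorm(n)
    mses <- vapply(1:8, function(nt) {
      m <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = 1,
                      tree_method = "hist", grow_policy = "lossguide",
                      max_depth = 0, max_leaves = 3, lambda = 0,
                      base_score = mean(y), nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = nt, verbose = 0)
      mean((predict(m, xgboost::xgb.DMatrix(X, nthread = 1)) - y)^2)
    }, numeric(1))
    expect_true(all(diff(mses) <= 1e-8))
  })
})

test_that("grid search reports LOO MSE per combination and picks its
           minimum", {
  netstate:::with_seed(118, {
    X <- matrix(rnorm(16 * 5), 16); colnames(X) <- paste0("f", 1:5)
    y <- X[, 2] + rnorm(16, 0, 0.3)
    te <- boosted_tree_regression(
      X, y, grid = list(max_splits = c(1, 2), n_trees = c(2, 4)))
    expect_equal(nrow(te$grid_mse), 4)
    expect_equal(te$mse, min(te$grid_mse$mse))
    chosen_row <- te$grid_mse[te$grid_mse$max_splits == te$chosen$max_splits &
                                te$grid_mse$n_trees == te$chosen$n_trees, ]
    expect_equal(chosen_row$mse, te$mse)
  })
})
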