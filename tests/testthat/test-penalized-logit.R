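test_that("weighted log-likelihood matches closed forms and direct summation", {
  ds <- make_planted(n = 50, p = 4, weights = FALSE)
  p <- ncol(ds$X)
  # null model under unit weights: -n log 2
  expect_equal(weighted_loglik(rep(0, p), 0, ds), -50 * log(2))

  # 4-row toy set with weights (2,1,1,2): term-by-term oracle to 1e-12
  X4 <- matrix(c(1, 0, 1, 0, 0.5, -1, 2, 0.3), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  ds4 <- encoded_dataset(X4, c(1, 0, 1, 0), c(2, 1, 1, 2))
  th <- c(0.7, -0.4)
  expect_equal(weighted_loglik(th, 0.2, ds4),
               loglik_direct(th, 0.2, X4, c(1, 0, 1, 0), c(2, 1, 1, 2)),
               tolerance = 1e-12)

  # single positive row at the eta -> +Inf limit contributes 0
  dsl <- encoded_dataset(matrix(c(1, rep(0, 9)), 10, 1,
                                dimnames = list(NULL, "x")),
                         c(1, rep(0, 9)), rep(1, 10))
  big <- weighted_loglik(500, 0, dsl)
  # row 1 (y=1, eta=500) contributes ~0; rows 2..10 (y=0, eta=0) -log2 each
  expect_equal(big, -9 * log(2), tolerance = 1e-8)
  # and no overflow for huge linear predictors
  expect_true(is.finite(weighted_loglik(5000, 1000, dsl)))
})

test_that("lambda = 0 fits match the Newton-Raphson MLE for both penalties", {
  set.seed(5)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(50, 1, plogis(0.3 + X %*% c(0.8, -0.5, 0)))
  w <- rlnorm(50, 0, 0.3)
  ds <- encoded_dataset(X, y, w)
  oracle <- newton_logistic(X, y, w)
  for (pen in c("L1", "L2")) {
    fit <- fit_penalized(ds, pen, lam = 0)
    expect_true(fit$converged)
    expect_equal(fit$theta, setNames(oracle$theta, colnames(X)),
                 tolerance = 1e-6)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-6)
  }
  # ... and therefore with each other
  f1 <- fit_penalized(ds, "L1", 0); f2 <- fit_penalized(ds, "L2", 0)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
})

test_that("total shrinkage at huge lambda leaves only the weighted base rate", {
  ds <- make_planted(n = 300, p = 6, seed = 8)
  for (pen in c("L1", "L2")) {
    fit <- fit_penalized(ds, pen, lam = 1e6)
    expect_true(all(abs(fit$theta_std) < 1e-4))
    v <- ds$w / mean(ds$w)
    expect_equal(plogis(fit$intercept), sum(v * ds$y) / length(ds$y),
                 tolerance = 1e-3)
  }
})

test_that("L1 fits satisfy the KKT conditions and zero out pure noise", {
  ds <- make_planted(n = 500, p = 8, n_signal = 1, beta = 1.8, seed = 13)
  lam <- 0.15 * lambda_max(ds)
  fit <- fit_penalized(ds, "L1", lam)
  expect_lt(kkt_residual_l1(fit, ds, lam), 1e-6)
  expect_gt(abs(fit$theta_std["v01"]), 0)       # planted signal survives
  expect_true(any(fit$theta_std[-1] == 0))      # noise columns exactly zero

  # KKT across a range of penalties
  for (frac in c(0.5, 0.05, 0.01)) {
    lam <- frac * lambda_max(ds)
    expect_lt(kkt_residual_l1(fit_penalized(ds, "L1", lam), ds, lam), 1e-6)
  }
})

test_that("lambda_max is the exact threshold for the all-zero L1 solution", {
  ds <- make_planted(n = 300, p = 6, seed = 21)
  lmax <- lambda_max(ds)
  expect_equal(fit_penalized(ds, "L1", lmax * 1.001)$n_nonzero, 0)
  expect_gt(fit_penalized(ds, "L1", lmax * 0.9)$n_nonzero, 0)
})

test_that("regularization paths are monotone in lambda", {
  ds <- make_planted(n = 400, p = 10, seed = 17)
  grid <- default_lambda_grid(ds, length = 12)
  ridge_norms <- sapply(grid, function(l)
    sqrt(sum(fit_penalized(ds, "L2", l)$theta_std^2)))
  # grid is decreasing, so norms must be non-decreasing along it
  expect_true(all(diff(ridge_norms) >= -1e-8))
  active <- sapply(grid, function(l) fit_penalized(ds, "L1", l)$n_nonzero)
  expect_true(all(diff(active) >= 0))
})

test_that("doubling all weights leaves the fit unchanged (per-sum objective)", {
  ds <- make_planted(n = 200, p = 5, seed = 31)
  ds2 <- encoded_dataset(ds$X, ds$y, 2 * ds$w)
  lam <- 0.1 * lambda_max(ds)
  f1 <- fit_penalized(ds, "L1", lam)
  f2 <- fit_penalized(ds2, "L1", lam)
  # weights are normalized to mean 1, so the objective (and lambda scale)
  # is invariant to rescaling the weight column
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
  expect_equal(lambda_max(ds), lambda_max(ds2), tolerance = 1e-12)
})

test_that("cross-validation selects the exhaustive-refit argmax", {
  ds <- make_planted(n = 200, p = 6, n_signal = 2, seed = 23)
  grid <- default_lambda_grid(ds, length = 3)
  cv <- cv_select_lambda(ds, "L1", grid, k = 4, seed = 7)

  # independent recomputation: same folds, refit per (fold, lambda), score
  fold <- itascreen:::stratified_folds(ds$y, 4, 7)
  mean_ll <- sapply(grid, function(l) {
    mean(sapply(1:4, function(f) {
      tr <- itascreen:::ed_rows(ds, which(fold != f))
      ho <- itascreen:::ed_rows(ds, which(fold == f))
      fit <- fit_penalized(tr, "L1", l)
      weighted_loglik(fit$theta, fit$intercept, ho)
    }))
  })
  # the CV path runs at a looser solver tolerance than the refit oracle, so
  # the curves agree closely but not to machine precision
  expect_equal(cv$mean_cv_loglik, mean_ll, tolerance = 1e-4)
  expect_equal(cv$chosen_lam, max(grid[mean_ll == max(mean_ll)]))

  # grid of length 1: chosen lambda is that value
  cv1 <- cv_select_lambda(ds, "L2", lam_grid = 0.5, k = 3, seed = 1)
  expect_equal(cv1$chosen_lam, 0.5)

  # k = 5 folds have size n/5 +- 1 and partition the rows
  f5 <- itascreen:::stratified_folds(ds$y, 5, 3)
  expect_equal(sort(unique(f5)), 1:5)
  expect_true(all(abs(table(f5) - 40) <= 1))
})

test_that("predicted probabilities are the logistic transform of eta", {
  X <- matrix(c(1, 2, -1, 0.5), 2, 2, dimnames = list(NULL, c("a", "b")))
  ds <- make_planted(n = 60, p = 2, n_signal = 1, seed = 2)
  fit <- fit_penalized(ds, "L2", 0.5)
  # hand computation on a 2-feature row
  eta <- fit$intercept + X %*% fit$theta
  expect_equal(predict_prob(fit, X), as.numeric(1 / (1 + exp(-eta))),
               tolerance = 1e-12)
  # theta = 0 fit gives a constant vector
  fit0 <- fit_penalized(ds, "L1", 1e6)
  expect_equal(diff(range(predict_prob(fit0, ds$X))), 0, tolerance = 1e-6)
  expect_error(predict_prob(fit, X[, 1, drop = FALSE]), "mismatch")
})

test_that("fits serialize to JSON and back losslessly", {
  ds <- make_planted(n = 100, p = 4, seed = 6)
  fit <- fit_penalized(ds, "L1", 0.3 * lambda_max(ds))
  parsed <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(unlist(parsed$theta), fit$theta)
  expect_equal(parsed$lam, fit$lam)
  expect_equal(parsed$penalty, "L1")
})
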