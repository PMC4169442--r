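# Correlation-based feature selection, OLS, repeated cross-validation.

test_that("feature selection ranks exact and noisy constructions correctly", {
  set.seed(21)
  X <- matrix(rnorm(200 * 12), 200)
  expect_equal(select_features(X, X[, 7], 1), 7L)
  y <- 2 * X[, 3] - X[, 8] + rnorm(200, 0, 0.1)
  expect_setequal(select_features(X, y, 2), c(3L, 8L))
  # k = p returns every index, ordered by |r|
  all_idx <- select_features(X, y, 12)
  expect_setequal(all_idx, 1:12)
  r <- abs(cor(X, y))
  expect_equal(all_idx[1:2], order(-r)[1:2])
  expect_error(select_features(X, y, 0), "k must be")
  expect_error(select_features(X, rep(1, 200), 2), "constant target")
})

test_that("feature-selection ties break toward the lower column index", {
  x <- rnorm(50)
  X <- cbind(x, x, rnorm(50) * 1e-8 + x)[, c(1, 2, 3)]
  expect_equal(select_features(X, x, 2)[1], 1L)
})

test_that("OLS is exact on noiseless linear targets", {
  set.seed(4)
  X <- matrix(rnorm(60 * 5), 60)
  y <- 3 * X[, 1] + 2
  fit <- fit_linear(X, y, indices = 1L)
  expect_equal(fit$beta, 3, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  # constant target: zero betas, intercept = mean
  yc <- rep(4.2, 60)
  fitc <- fit_linear(X, yc, indices = c(2L, 3L))
  expect_equal(fitc$beta, c(0, 0), tolerance = 1e-10)
  expect_equal(fitc$intercept, 4.2, tolerance = 1e-10)
})

test_that("OLS agrees with an independent normal-equations oracle", {
  set.seed(90)
  X <- matrix(rnorm(200 * 5), 200)
  y <- rnorm(200)
  fit <- fit_linear(X, y)
  # oracle: solve the normal equations directly
  A <- cbind(1, X)
  beta_oracle <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(c(fit$intercept, fit$beta), drop(beta_oracle), tolerance = 1e-10)
  r2 <- function(pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(r2(predict(fit, X)), r2(drop(A %*% beta_oracle)),
               tolerance = 1e-10)
  expect_error(fit_linear(X[1:5, ], y[1:5]), "rows > features")
  expect_error(fit_linear(cbind(X, X[, 1]), y), "rank-deficient")
})

test_that("evaluate_prediction matches hand calculations", {
  expect_equal(evaluate_prediction(1:10, 1:10), list(r = 1, rmse = 0))
  ep <- evaluate_prediction(1:10, 1:10 + 1)
  expect_equal(ep$r, 1); expect_equal(ep$rmse, 1)
  obs <- c(1, 2, 3, 4); pred <- c(1.1, 1.9, 3.2, 3.8)
  hand_r <- sum((obs - 2.5) * (pred - mean(pred))) /
    sqrt(sum((obs - 2.5)^2) * sum((pred - mean(pred))^2))
  hand_rmse <- sqrt(mean(c(0.1, 0.1, 0.2, 0.2)^2))
  ep <- evaluate_prediction(obs, pred)
  expect_equal(ep$r, hand_r, tolerance = 1e-10)
  expect_equal(ep$rmse, hand_rmse, tolerance = 1e-10)
  expect_error(evaluate_prediction(1:3, rep(2, 3)), "constant")
})

test_that("cross-validation recovers a noiseless linear target", {
  set.seed(101)
  X <- matrix(rnorm(200 * 40), 200)
  y <- X[, 5] - 2 * X[, 17] + 0.5 * X[, 31]
  cv <- cross_validate(X, y, folds = 20, repeats = 3, seed = 6)
  expect_gte(cv$mean_r, 0.999)
  expect_setequal(cv$model$indices, c(5L, 17L, 31L))
})

test_that("cross-validation stays near zero on average over null targets", {
  # a single null draw carries winner-selection optimism (the feature that
  # wins univariate selection on 95%-overlapping training sets also looks
  # good on the held-out rows of the same finite sample), so the null
  # property is asserted on the average over independent null targets
  rs <- sapply(1:8, function(s) {
    set.seed(550 + s)
    X <- matrix(rnorm(400 * 10), 400)
    y <- rnorm(400)
    cross_validate(X, y, folds = 20, repeats = 3, seed = s)$mean_r
  })
  expect_lte(abs(mean(rs)), 0.1)
  expect_lt(max(abs(rs)), 0.35)
})

test_that("a 40%-signal target lands near its theoretical ceiling", {
  # exact-moment construction: realized R^2 is 0.4, ceiling sqrt(0.4)
  set.seed(14)
  X <- matrix(rnorm(120 * 30), 120)
  signal <- drop(X[, c(2, 9)] %*% c(1, 0.6))
  signal <- signal / sd(signal) * sqrt(0.4)
  e <- rnorm(120); e <- e / sd(e) * sqrt(0.6)
  y <- signal + e
  cv <- cross_validate(X, y, folds = 20, repeats = 5, seed = 3)
  expect_gte(cv$mean_r, 0.53)
  expect_lte(cv$mean_r, 0.73)
})

test_that("no information leaks from test folds into training", {
  set.seed(42)
  X <- matrix(rnorm(80 * 10), 80)
  y <- X[, 1] + rnorm(80, 0, 0.5)
  cv <- cross_validate(X, y, folds = 2, repeats = 1, seed = 77)
  # corrupt the responses of fold 1 and re-run: fold-1 predictions come
  # from a model trained on fold 2 only, so they must be unchanged
  y2 <- y
  y2[cv$fold_id == 1] <- rnorm(sum(cv$fold_id == 1), 100, 5)
  cv2 <- cross_validate(X, y2, folds = 2, repeats = 1, seed = 77)
  expect_identical(cv$fold_id, cv2$fold_id)
  expect_equal(cv$predictions[cv$fold_id == 1, ],
               cv2$predictions[cv$fold_id == 1, ], tolerance = 1e-12)
})

test_that("mean CV r is invariant to affine rescaling of the target", {
  set.seed(31)
  X <- matrix(rnorm(100 * 8), 100)
  y <- X[, 2] + rnorm(100)
  a <- cross_validate(X, y, folds = 10, repeats = 2, seed = 5)
  b <- cross_validate(X, 3 * y + 7, folds = 10, repeats = 2, seed = 5)
  expect_equal(a$mean_r, b$mean_r, tolerance = 1e-10)
  expect_equal(a$best_k, b$best_k)
})

test_that("repeat-to-repeat sd shrinks with more repeats", {
  set.seed(8)
  X <- matrix(rnorm(100 * 10), 100)
  y <- 0.7 * X[, 1] + rnorm(100)
  sds <- sapply(c(4, 16), function(rep_n) {
    cross_validate(X, y, folds = 10, repeats = rep_n, seed = 9,
                   k_grid = 1:3)$sd_r
  })
  # sd of the mean over repeats is stable; per-repeat sd estimates agree
  expect_lt(abs(sds[2] / sds[1] - 1), 1.0)
})

test_that("personality prediction fails on null targets, works on strong ones", {
  set.seed(70)
  X <- matrix(rnorm(120 * 20), 120)
  hits <- 0
  for (i in 1:10) {
    y_null <- runif(120, 1, 10)
    cv <- predict_personality(X, y_null, folds = 10, repeats = 2,
                              seed = i, k_grid = 1:10)
    hits <- hits + (cv$mean_r < 0.20)
    if (i == 1) expect_gt(cv$rmse, 0.8 * sd(y_null))
  }
  expect_gte(hits, 9)
  # positive control: R^2 = 0.9 target is predicted well
  signal <- drop(X[, 1:3] %*% c(1, 1, 1)); signal <- signal / sd(signal)
  y_strong <- sqrt(0.9) * signal + sqrt(0.1) * rnorm(120)
  cv <- predict_personality(X, y_strong, folds = 10, repeats = 2, seed = 1)
  expect_gt(cv$mean_r, 0.8)
})

test_that("alpha-performance correlation behaves at its extremes", {
  rel <- data.frame(trait = rep(RATING_TRAITS, 2),
                    gender = rep(c("F", "M"), each = 12),
                    alpha = seq(0.6, 0.9, length.out = 24))
  cv <- data.frame(trait = rel$trait, gender = rel$gender,
                   mean_r = rel$alpha)        # identical construction
  expect_equal(alpha_performance_correlation(rel, cv)$r, 1, tolerance = 1e-12)
  set.seed(3)
  cv$mean_r <- rnorm(24)
  out <- alpha_performance_correlation(rel, cv)
  expect_lt(abs(out$r), 0.55)   # null width at n = 24
  expect_equal(out$n, 24L)
  expect_error(alpha_performance_correlation(rel[1:2, ], cv[1:2, ]), ">= 3")
})
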