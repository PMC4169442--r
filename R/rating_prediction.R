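# Predicting mean trait ratings from facial components: univariate
# correlation-based feature selection (on the training rows only) feeding
# an ordinary least-squares model, evaluated by Pearson r between observed
# and predicted held-out scores under repeated 20-fold cross-validation.

#' Select the k components most correlated with a target
#'
#' Ranks columns of `X` by `|Pearson r|` against `y` (computed on the rows
#' supplied, i.e. the training rows) and returns the top `k` indices. Ties
#' are broken in favour of the lower column index.
#'
#' @param X numeric matrix, rows = ratees, columns = components.
#' @param y numeric target vector.
#' @param k number of features to keep (1 <= k <= ncol(X)).
#' @return integer vector of column indices, strongest first.
#' @export
select_features <- function(X, y, k) {
  if (k < 1L) stop("k must be >= 1")
  if (k > ncol(X)) stop("k exceeds the component count")
  if (stats::sd(y) < .Machine$double.eps) stop("constant target")
  r <- abs(drop(stats::cor(X, y)))
  r[is.na(r)] <- 0     # constant columns can never be selected
  order(-r, seq_along(r))[seq_len(k)]
}

#' Ordinary least squares fit on selected components
#'
#' @param X full component matrix.
#' @param y target vector.
#' @param indices selected column indices (default: all columns).
#' @param trait,gender optional labels stored with the model.
#' @return object of class `regression_model`: `indices`, `beta` (named by
#'   index), `intercept`, `k`, `trait`, `gender`.
#' @export
fit_linear <- function(X, y, indices = seq_len(ncol(X)),
                       trait = NA_character_, gender = NA_character_) {
  Xs <- X[, indices, drop = FALSE]
  if (nrow(Xs) <= ncol(Xs) + 1L) stop("need rows > features + 1")
  fit <- stats::lm.fit(cbind(1, Xs), y)
  if (fit$rank < ncol(Xs) + 1L) stop("rank-deficient design")
  cf <- fit$coefficients
  structure(list(indices = as.integer(indices), beta = unname(cf[-1]),
                 intercept = unname(cf[1]), k = length(indices),
                 trait = trait, gender = gender),
            class = "regression_model")
}

#' Predict from a fitted regression model
#'
#' @param object `regression_model`.
#' @param newdata full component matrix (same column layout as training).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.regression_model <- function(object, newdata, ...) {
  drop(newdata[, object$indices, drop = FALSE] %*% object$beta) +
    object$intercept
}

#' Pearson r and RMSE between observed and predicted scores
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return list with `r` and `rmse`.
#' @export
evaluate_prediction <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L)
    stop("need equal lengths >= 3")
  if (stats::sd(observed) < .Machine$double.eps ||
      stats::sd(predicted) < .Machine$double.eps)
    stop("constant vector; r undefined")
  list(r = stats::cor(observed, predicted),
       rmse = sqrt(mean((observed - predicted)^2)))
}

#' Repeated k-fold cross-validation with growing feature sets
#'
#' For each repeat a fresh random fold assignment is drawn. Within each
#' fold, features are ranked by training-set correlation only and models
#' with a growing number of the most correlated components are fitted; the
#' held-out predictions of all folds are pooled per repeat and compared to
#' the observed scores by Pearson r (per-fold averaging available via
#' `pooling = "per_fold"`). The best feature count maximises the mean r
#' across repeats; the reported SD is the SD of the per-repeat r at that
#' feature count. A final model with the best k is refitted on all rows.
#'
#' @param X component matrix (ratees x components).
#' @param y target vector (mean ratings, or personality scores).
#' @param folds number of CV folds (default 20).
#' @param repeats number of repeated fold assignments (default 30).
#' @param k_grid candidate feature counts; default `1:min(30, n/5, p)`.
#' @param seed master seed; repeat r uses `derive_seed(seed, r)`.
#' @param pooling "pooled" (default) or "per_fold".
#' @param trait,gender labels carried into the result and final model.
#' @return object of class `cv_result`: `best_k`, `mean_r`, `sd_r`, `rmse`,
#'   `per_k` (data.frame of mean r per candidate k), `model` (final
#'   `regression_model`), `predictions` and `fold_id` (held-out predictions
#'   and fold assignment of the last repeat, for audit), `folds`,
#'   `repeats`, `pooling`.
#' @export
cross_validate <- function(X, y, folds = 20L, repeats = 30L, k_grid = NULL,
                           seed = 1L, pooling = c("pooled", "per_fold"),
                           trait = NA_character_, gender = NA_character_) {
  pooling <- match.arg(pooling)
  X <- as.matrix(X); n <- nrow(X)
  if (n < folds) stop("need at least as many rows as folds")
  if (is.null(k_grid))
    k_grid <- seq_len(max(1L, min(30L, floor(n / 5), ncol(X))))
  if (!length(k_grid)) stop("empty k_grid")
  if (max(k_grid) > ncol(X)) stop("k_grid exceeds the component count")
  r_mat <- matrix(NA_real_, repeats, length(k_grid))
  rmse_mat <- matrix(NA_real_, repeats, length(k_grid))
  for (rep_i in seq_len(repeats)) {
    fold_id <- with_seed(derive_seed(seed, rep_i),
                         sample(rep_len(seq_len(folds), n)))
    pred <- matrix(NA_real_, n, length(k_grid))
    fold_r <- matrix(NA_real_, folds, length(k_grid))
    for (f in seq_len(folds)) {
      test <- fold_id == f
      Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
      ranked <- select_features(Xtr, ytr, max(k_grid))
      for (ki in seq_along(k_grid)) {
        idx <- ranked[seq_len(k_grid[ki])]
        fit <- fit_linear(Xtr, ytr, idx)
        pred[test, ki] <- predict(fit, X[test, , drop = FALSE])
        if (pooling == "per_fold" && sum(test) >= 3L)
          fold_r[f, ki] <- stats::cor(y[test], pred[test, ki])
      }
    }
    for (ki in seq_along(k_grid)) {
      r_mat[rep_i, ki] <- if (pooling == "pooled")
        stats::cor(y, pred[, ki]) else mean(fold_r[, ki], na.rm = TRUE)
      rmse_mat[rep_i, ki] <- sqrt(mean((y - pred[, ki])^2))
    }
  }
  mean_r_by_k <- colMeans(r_mat)
  best <- which.max(mean_r_by_k)
  final_idx <- select_features(X, y, k_grid[best])
  structure(list(best_k = k_grid[best],
                 predictions = pred, fold_id = fold_id,
                 mean_r = mean_r_by_k[best],
                 sd_r = stats::sd(r_mat[, best]),
                 rmse = mean(rmse_mat[, best]),
                 per_k = data.frame(k = k_grid, mean_r = mean_r_by_k),
                 model = fit_linear(X, y, final_idx,
                                    trait = trait, gender = gender),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 pooling = pooling, trait = trait, gender = gender),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV (%d-fold x %d repeats%s): best k = %d, r = %.3f (sd %.3f), RMSE = %.3f\n",
              x$folds, x$repeats,
              if (is.na(x$trait)) "" else paste0(", ", x$trait), x$best_k,
              x$mean_r, x$sd_r, x$rmse))
  invisible(x)
}

#' Attempt to predict personality scores (expected to fail on real-like data)
#'
#' Runs the identical cross-validated machinery with a personality trait as
#' the target, either from facial components or from the 12 mean ratings.
#' On cohorts where personality is only weakly tied to the face (the
#' realistic regime), the resulting r stays low and the RMSE near the
#' target SD; the function exists to measure exactly that.
#'
#' @param X predictor matrix (component scores or mean ratings).
#' @param y personality score vector.
#' @param ... passed to [cross_validate()].
#' @return a `cv_result`.
#' @export
predict_personality <- function(X, y, ...) {
  cross_validate(X, y, ...)
}

#' Correlation between inter-rater reliability and prediction accuracy
#'
#' @param reliability data.frame from [reliability()] (`trait`, `gender`,
#'   `alpha`).
#' @param cv data.frame with `trait`, `gender`, `mean_r` (one row per
#'   trait x gender, e.g. assembled from [cross_validate()] results).
#' @return list with `r`, `p` (two-sided t-based), `n` pairs.
#' @export
alpha_performance_correlation <- function(reliability, cv) {
  m <- merge(reliability, cv, by = c("trait", "gender"))
  if (nrow(m) < 3L) stop("need >= 3 trait x gender pairs")
  ct <- stats::cor.test(m$alpha, m$mean_r)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}
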