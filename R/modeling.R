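#' Fit a PLS regression with cross-validated component choice
#'
#' Builds the evaluation model used throughout the benchmark: a partial
#' least squares regression on all normalized descriptors (never on the
#' selection search space). The number of latent variables is chosen by
#' five-fold cross validation, maximizing the coefficient of determination
#' Q² = 1 - PRESS / TSS pooled over folds, where each fold's TSS is taken
#' against its training-fold mean. Ties (within a numerical tolerance of
#' 1e-8 on Q²) go to the smaller component count.
#' The model is then refit on all training rows with the chosen count.
#'
#' Folds are assigned by a seeded shuffle of the global RNG stream, so the
#' component choice is reproducible under `set.seed()`. The candidate count
#' is capped at `min(max_components, n - ceiling(n/folds) - 1, d)` so every
#' cross-validation fit stays well-posed even for five-compound selections.
#'
#' @param X_train numeric matrix of normalized descriptors.
#' @param y_train numeric endpoint vector (must not be constant).
#' @param max_components upper bound on latent variables; default
#'   `min(10, n - 2, d)` before the fold-size cap.
#' @param folds number of CV folds (default 5); reduced to `n` with a
#'   warning when `n < folds` (leave-one-out).
#' @return Object of class `pls_model`: list with the fitted mixOmics model
#'   (`fit`), `n_latent`, `cv_r2_by_components`, `folds` and the training
#'   dimensions.
#' @export
fit_pls_cv <- function(X_train, y_train, max_components = NULL, folds = 5L) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train); d <- ncol(X_train)
  if (length(y_train) != n) stop("X_train rows and y_train length differ")
  if (stats::sd(y_train) == 0) stop("endpoint is constant on the training set")
  if (n < folds) {
    warning("fewer training compounds than folds; using leave-one-out")
    folds <- n
  }
  if (is.null(colnames(X_train)))
    colnames(X_train) <- paste0("d", seq_len(d))
  assignment <- sample(rep(seq_len(folds), length.out = n))
  min_train <- n - max(tabulate(assignment, folds))
  rank_of <- function(M) qr(sweep(M, 2L, colMeans(M)))$rank
  cap <- min(if (is.null(max_components)) min(10L, n - 2L, d)
             else max_components,
             min_train - 1L, d, max(1L, rank_of(X_train)))
  cap <- max(cap, 1L)
  press <- numeric(cap)
  tss <- 0
  for (f in seq_len(folds)) {
    tr <- assignment != f
    obs <- y_train[!tr]
    # components cannot exceed the rank of the fold's centered matrix
    nc_f <- max(1L, min(cap, rank_of(X_train[tr, , drop = FALSE])))
    pred <- tryCatch({
      fit_f <- suppressWarnings(
        mixOmics::pls(X_train[tr, , drop = FALSE], y_train[tr],
                      ncomp = nc_f, mode = "regression", scale = FALSE))
      suppressWarnings(
        stats::predict(fit_f, X_train[!tr, , drop = FALSE])$predict)
    }, error = function(e) NULL)
    for (c in seq_len(cap)) {
      p_c <- if (is.null(pred)) rep(mean(y_train[tr]), sum(!tr))
             else pred[, 1L, min(c, nc_f)]
      press[c] <- press[c] + sum((p_c - obs)^2)
    }
    tss <- tss + sum((obs - mean(y_train[tr]))^2)
  }
  q2 <- 1 - press / tss
  # smallest component count within numerical tolerance of the best Q2, so
  # noise-free fits do not drift to needlessly complex models
  n_latent <- which(q2 >= max(q2) - 1e-8)[1L]
  fit <- suppressWarnings(
    mixOmics::pls(X_train, y_train, ncomp = n_latent,
                  mode = "regression", scale = FALSE))
  structure(list(fit = fit, n_latent = n_latent,
                 cv_r2_by_components = q2, folds = folds,
                 n_train = n, n_descriptors = d,
                 descriptor_names = colnames(X_train)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variable(s), %d x %d training data, Q2 = %.3f\n",
              x$n_latent, x$n_train, x$n_descriptors,
              x$cv_r2_by_components[x$n_latent]))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a [fit_pls_cv()] model.
#' @param newdata matrix of normalized descriptors (same columns, normalized
#'   with the training normalization parameters).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$descriptor_names
  p <- suppressWarnings(stats::predict(object$fit, newdata)$predict)
  as.numeric(p[, 1L, object$n_latent])
}

#' Evaluate a model on a validation set
#'
#' Scores predictions with the two benchmark criteria: root mean squared
#' error and the Pearson correlation between observed and predicted values.
#' When the predictions (or the observations) are constant the correlation
#' is undefined; it is recorded as 0 and flagged.
#'
#' @param model a `pls_model`.
#' @param X_val validation descriptors, normalized with the *training*
#'   normalization parameters.
#' @param y_val observed endpoint values.
#' @return List with `rmse`, `r` and `r_defined` (FALSE when the correlation
#'   was undefined and substituted by 0).
#' @export
evaluate_model <- function(model, X_val, y_val) {
  if (NROW(X_val) == 0L) stop("empty validation set")
  score_predictions(predict(model, X_val), y_val)
}

# RMSE + Pearson r of a prediction vector; r of constant vectors is
# undefined and recorded as 0 with r_defined = FALSE.
score_predictions <- function(pred, obs) {
  rmse <- sqrt(mean((pred - obs)^2))
  r_defined <- stats::sd(pred) > 0 && stats::sd(obs) > 0
  r <- if (r_defined) stats::cor(pred, obs) else 0
  list(rmse = rmse, r = r, r_defined = r_defined)
}
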