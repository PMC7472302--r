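#' Fit a weighted evidential regression model
#'
#' The main entry point.  Builds the evidence set (min-max normalizing the
#' features), selects the discount radius by grid search when `gamma` is not
#' given, and -- unless `learn_weights = FALSE` -- learns per-feature distance
#' weights by gradient descent on the leave-one-out MSE.  Predictions from the
#' fitted model are Pignistic expectations with lower/upper bounds whose width
#' is the model's own ignorance about each query.
#'
#' @param x feature matrix or data frame (raw units).
#' @param y numeric target vector.
#' @param k neighbour count of the evidence set (default 20).
#' @param gamma discount radius; `NULL` (default) selects it with
#'   [select_gamma()] on the training data.
#' @param alpha learning rate for weight learning.
#' @param epochs number of weight-learning epochs.
#' @param p Minkowski exponent in \[1, 2\].
#' @param form discount form, see [discount()].
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learn_weights set `FALSE` to keep all-ones weights (plain
#'   evidential regression).
#' @param weights optional fixed weight vector (implies
#'   `learn_weights = FALSE`).
#' @return An object of class `wevreg_model` with elements `train`
#'   (the [training_set()]), `w`, `fit` (the [fit_weights()] result or
#'   `NULL`), and `config`.
#' @examples
#' d <- make_friedman(synthetic_spec("friedman", 60, 8, seed = 1))
#' m <- wevreg(d$x, d$y, k = 5, epochs = 3)
#' predict(m, d$x[1:3, ])
#' @seealso [wknn()] for the kernel baseline, [rank_and_select()] for
#'   feature selection from the learned weights.
#' @export
wevreg <- function(x, y, k = 20L, gamma = NULL, alpha = 0.1, epochs = 100L,
                   p = 2, form = c("exp_sq", "exp_raw"),
                   optimizer = c("adam", "sgd"),
                   learn_weights = TRUE, weights = NULL) {
  form <- match.arg(form)
  optimizer <- match.arg(optimizer)
  train <- training_set(x, y)
  q <- ncol(train$X)
  if (is.null(gamma)) {
    gamma <- select_gamma(train, k = k, p = p, form = form,
                          estimator = "wevreg")
  }
  fit <- NULL
  if (!is.null(weights)) {
    check_weights(weights, q)
    w <- weights
  } else if (learn_weights && nrow(train$X) >= 2L) {
    fit <- fit_weights(train, k = k, gamma = gamma, alpha = alpha,
                       epochs = epochs, p = p, form = form,
                       estimator = "wevreg", optimizer = optimizer)
    w <- fit$w_hat
  } else {
    w <- rep(1, q)
  }
  structure(list(train = train, w = stats::setNames(w, train$feature_names),
                 fit = fit,
                 config = list(estimator = "wevreg", k = k, gamma = gamma,
                               alpha = alpha, epochs = epochs, p = p,
                               form = form, optimizer = optimizer)),
            class = "wevreg_model")
}

#' Fit the weighted k-nearest-neighbour kernel baseline
#'
#' The ablation comparator: the same weighted metric, neighbour search and
#' weight-learning loop as [wevreg()], but predictions are plain
#' kernel-weighted neighbour means `sum_j y_j e^(-d_j / beta) / Z` -- no mass
#' combination and no ignorance term.  By convention the kernel radius `beta`
#' occupies the same configuration slot as the evidential `gamma`, and with
#' `gamma_rule = "evidential"` (the default) an unset radius is selected by
#' the evidential grid-search criterion, i.e. the comparator inherits the
#' configuration the evidential model would use on the same data;
#' `gamma_rule = "kernel"` tunes the kernel's own leave-one-out MAE instead.
#'
#' @inheritParams wevreg
#' @param gamma_rule how to select an unset radius, see Details.
#' @return An object of class `c("wknn_model", "wevreg_model")`.
#' @export
wknn <- function(x, y, k = 20L, gamma = NULL, alpha = 0.1, epochs = 100L,
                 p = 2, optimizer = c("adam", "sgd"),
                 learn_weights = TRUE, weights = NULL,
                 gamma_rule = c("evidential", "kernel")) {
  optimizer <- match.arg(optimizer)
  gamma_rule <- match.arg(gamma_rule)
  train <- training_set(x, y)
  q <- ncol(train$X)
  if (is.null(gamma)) {
    gamma <- select_gamma(train, k = k, p = p,
                          estimator = if (gamma_rule == "evidential")
                            "wevreg" else "wknn")
  }
  fit <- NULL
  if (!is.null(weights)) {
    check_weights(weights, q)
    w <- weights
  } else if (learn_weights && nrow(train$X) >= 2L) {
    fit <- fit_weights(train, k = k, gamma = gamma, alpha = alpha,
                       epochs = epochs, p = p, estimator = "wknn",
                       optimizer = optimizer)
    w <- fit$w_hat
  } else {
    w <- rep(1, q)
  }
  structure(list(train = train, w = stats::setNames(w, train$feature_names),
                 fit = fit,
                 config = list(estimator = "wknn", k = k, gamma = gamma,
                               alpha = alpha, epochs = epochs, p = p,
                               form = "exp_sq", optimizer = optimizer)),
            class = c("wknn_model", "wevreg_model"))
}

#' Predict from a fitted evidential or kernel model
#'
#' @param object a `wevreg_model` or `wknn_model`.
#' @param newdata feature matrix or data frame in raw units.
#' @param ... unused.
#' @return A data frame with one row per query.  For the evidential model:
#'   `fit` (Pignistic point estimate), `lwr`, `upr` (bounds) and
#'   `uncertainty` (domain mass in \[0, 1\]).  For the kernel baseline: `fit`
#'   only.
#' @export
predict.wevreg_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, object$train$feature_names, drop = FALSE])
  }
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  cfg <- object$config
  Xq <- normalize_features(newdata, object$train)
  batch_predict(object$train$X, object$train$y, object$train$y_inf,
                object$train$y_sup, Xq, unname(object$w), cfg$k, cfg$gamma,
                cfg$p, cfg$form, cfg$estimator)
}

#' @export
print.wevreg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s model: %d examples, %d features\n",
              if (cfg$estimator == "wevreg") "Weighted evidential regression"
              else "Weighted k-NN kernel", nrow(x$train$X), ncol(x$train$X)))
  cat(sprintf("  k = %d, gamma = %.4g, p = %g", cfg$k, cfg$gamma, cfg$p))
  if (!is.null(x$fit)) {
    cat(sprintf(", learned weights (best loss %.4g at epoch %d)",
                min(x$fit$loss_history), x$fit$best_epoch))
  }
  cat("\n")
  invisible(x)
}

#' Kernel-weighted k-NN point prediction
#'
#' One-query form of the baseline predictor: the kernel-weighted mean
#' of the `k` nearest neighbours' targets, with kernel `e^(-d / beta)` on the
#' weighted distance.  The estimate always lies within the range of the
#' neighbours' targets.
#'
#' @param x query vector in raw feature units.
#' @param train a [training_set()].
#' @param w nonnegative per-feature weights (default all ones).
#' @param k neighbour count.
#' @param gamma kernel radius (the `beta` of the kernel).
#' @param p Minkowski exponent in \[1, 2\].
#' @return A single numeric prediction.
#' @export
wknn_predict <- function(x, train, w = NULL, k = 5L, gamma = 1, p = 2) {
  stopifnot(inherits(train, "training_set"))
  if (nrow(train$X) < 1L) stop("empty training set")
  nb <- knn_search(train, x, w = w, k = k, p = p)
  s <- exp(-nb$distances / gamma)
  sum(s * train$y[nb$indices]) / sum(s)
}
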