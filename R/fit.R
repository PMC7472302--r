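#' Mean squared error
#'
#' @param y observed targets.
#' @param y_hat predictions of the same length.
#' @return `mean((y - y_hat)^2)`.
#' @export
loss_mse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  mean((y - y_hat)^2)
}

#' Leave-one-out predictions over a training set
#'
#' Predicts every training row from the remaining `n - 1` rows under the same
#' weights and hyperparameters; this is the training-time prediction used by
#' the weight-learning loss.  Target bounds are recomputed per left-out subset.
#'
#' @param train a [training_set()].
#' @param w nonnegative per-feature weights (default all ones).
#' @param k neighbour count.
#' @param gamma positive discount radius (kernel radius for `"wknn"`).
#' @param p Minkowski exponent in \[1, 2\].
#' @param form discount form, see [discount()].
#' @param estimator `"wevreg"` (evidential) or `"wknn"` (kernel baseline).
#' @return Numeric vector of `n` predictions.
#' @export
loo_predictions <- function(train, w = NULL, k = 20L, gamma = 1, p = 2,
                            form = c("exp_sq", "exp_raw"),
                            estimator = c("wevreg", "wknn")) {
  stopifnot(inherits(train, "training_set"))
  if (nrow(train$X) < 2L) stop("need at least two rows for leave-one-out")
  if (is.null(w)) w <- rep(1, ncol(train$X))
  check_weights(w, ncol(train$X))
  loo_pass(train$X, train$y, w, k, gamma, p, match.arg(form),
           match.arg(estimator), grad = FALSE)$y_hat
}

#' Analytic gradient of the leave-one-out MSE
#'
#' Gradient of [loss_mse()] of the [loo_predictions()] with respect to the
#' per-feature weights, obtained by differentiating the mass combination and
#' the discount kernel along the chain rule; terms outside each row's
#' neighbour set contribute zero.
#'
#' @inheritParams loo_predictions
#' @return Numeric gradient vector of length `ncol(train$X)`.
#' @export
loss_gradient <- function(train, w = NULL, k = 20L, gamma = 1, p = 2,
                          form = c("exp_sq", "exp_raw"),
                          estimator = c("wevreg", "wknn")) {
  stopifnot(inherits(train, "training_set"))
  if (is.null(w)) w <- rep(1, ncol(train$X))
  check_weights(w, ncol(train$X))
  loo_pass(train$X, train$y, w, k, gamma, p, match.arg(form),
           match.arg(estimator), grad = TRUE)$gradient
}

check_weights <- function(w, q) {
  if (length(w) != q) stop("`w` must have length ", q)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  invisible(w)
}

#' Select the discount radius by grid search
#'
#' Evaluates a log-spaced grid of radii by the leave-one-out mean absolute
#' error at the initial all-ones weights and returns the minimizer.  Distances
#' do not depend on the radius, so the whole grid is scored from a single
#' distance computation.
#'
#' @inheritParams loo_predictions
#' @param grid candidate radii; default ten log-spaced points in
#'   \[1e-3, 10\].
#' @return The grid value with the smallest leave-one-out MAE.
#' @export
select_gamma <- function(train, k = 20L, p = 2,
                         form = c("exp_sq", "exp_raw"),
                         estimator = c("wevreg", "wknn"),
                         grid = 10^seq(-3, 1, length.out = 10)) {
  stopifnot(inherits(train, "training_set"))
  form <- match.arg(form)
  estimator <- match.arg(estimator)
  w <- rep(1, ncol(train$X))
  scores <- vapply(grid, function(g) {
    yh <- loo_pass(train$X, train$y, w, k, g, p, form, estimator,
                   grad = FALSE)$y_hat
    mean(abs(train$y - yh))
  }, numeric(1))
  grid[which.min(scores)]
}

#' Learn per-feature distance weights by gradient descent
#'
#' Minimizes the leave-one-out MSE over the weight vector, starting from all
#' ones.  Each epoch recomputes the neighbour sets under the current metric,
#' evaluates the loss and its analytic full-batch gradient, and updates the
#' weights (Adam by default, plain gradient descent with
#' `optimizer = "sgd"`); weights are clipped to be nonnegative after every
#' update.  The returned `w_hat` is the weight state whose measured loss was
#' smallest.
#'
#' @inheritParams loo_predictions
#' @param alpha learning rate.
#' @param epochs number of epochs (full passes).
#' @param optimizer `"adam"` (moment decays 0.9/0.999, epsilon 1e-8) or
#'   `"sgd"`.
#' @return An object of class `fit_result`: list with `w_hat`, `loss_history`
#'   (one entry per epoch, each the loss of the pre-update state), and
#'   `best_epoch`.
#' @export
fit_weights <- function(train, k = 20L, gamma = 1, alpha = 0.1, epochs = 100L,
                        p = 2, form = c("exp_sq", "exp_raw"),
                        estimator = c("wevreg", "wknn"),
                        optimizer = c("adam", "sgd")) {
  stopifnot(inherits(train, "training_set"))
  if (nrow(train$X) < 2L) stop("need at least two rows to fit weights")
  if (alpha <= 0) stop("`alpha` must be positive")
  if (epochs < 1L) stop("`epochs` must be at least 1")
  form <- match.arg(form)
  estimator <- match.arg(estimator)
  optimizer <- match.arg(optimizer)
  q <- ncol(train$X)
  w <- rep(1, q)
  best_loss <- Inf
  best_w <- w
  best_epoch <- 1L
  loss_history <- numeric(epochs)
  m1 <- m2 <- numeric(q)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    out <- loo_pass(train$X, train$y, w, k, gamma, p, form, estimator,
                    grad = TRUE)
    loss <- loss_mse(train$y, out$y_hat)
    if (!is.finite(loss)) {
      stop("training diverged: non-finite loss at epoch ", t,
           " (last finite state available up to epoch ", t - 1L, ")")
    }
    loss_history[t] <- loss
    if (loss < best_loss) {
      best_loss <- loss
      best_w <- w
      best_epoch <- t
    }
    g <- out$gradient
    if (optimizer == "adam") {
      m1 <- b1 * m1 + (1 - b1) * g
      m2 <- b2 * m2 + (1 - b2) * g^2
      step <- (m1 / (1 - b1^t)) / (sqrt(m2 / (1 - b2^t)) + eps)
    } else {
      step <- g
    }
    w <- pmax(w - alpha * step, 0)
  }
  structure(list(w_hat = best_w, loss_history = loss_history,
                 best_epoch = best_epoch, estimator = estimator),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result (", x$estimator, "): ", length(x$loss_history),
      " epochs, best loss ", format(min(x$loss_history)),
      " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Rank features by learned weight and select by threshold
#'
#' Orders features by their learned distance weight (descending; ties by
#' feature index) and marks as selected those whose weight exceeds the
#' threshold.  With the default threshold of 1 -- the weights' common starting
#' value -- any feature whose weight grew during training is retained.
#'
#' @param w learned weight vector, or a fitted [wevreg()]/[wknn()] model.
#' @param names feature names (taken from the model when available).
#' @param threshold selection cutoff (default 1).
#' @return An object of class `feature_ranking`: data frame `ranking` with
#'   columns `feature`, `weight`, `selected`, plus the `threshold` and the
#'   `selected` index vector (positions in the original feature order).
#' @examples
#' rank_and_select(c(a = 65.06, b = 6.19, c = 1.09, d = 0.2))
#' @export
rank_and_select <- function(w, names = NULL, threshold = 1) {
  if (inherits(w, "wevreg_model")) {
    if (is.null(names)) names <- w$train$feature_names
    w <- w$w
  }
  if (is.null(names)) {
    names <- if (!is.null(base::names(w))) base::names(w) else
      paste0("f", seq_along(w) - 1L)
  }
  if (length(names) != length(w)) stop("`names` must match `w` in length")
  ord <- order(-w, seq_along(w))
  ranking <- data.frame(feature = names[ord], weight = unname(w[ord]),
                        selected = unname(w[ord] > threshold))
  structure(list(ranking = ranking, threshold = threshold,
                 selected = which(w > threshold)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10L, ...) {
  cat("feature_ranking:", length(x$selected), "of", nrow(x$ranking),
      "features above threshold", x$threshold, "\n")
  print(utils::head(x$ranking, n), row.names = FALSE)
  if (nrow(x$ranking) > n) cat("... and", nrow(x$ranking) - n, "more\n")
  invisible(x)
}
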