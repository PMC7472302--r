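#' Mean absolute error
#'
#' @param y_hat predictions.
#' @param y observed targets of the same length.
#' @return `mean(abs(y_hat - y))`.
#' @export
mae <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("length mismatch")
  mean(abs(y_hat - y))
}

#' Mean absolute percentage error
#'
#' Undefined when any target is zero; such rows are reported in the error
#' message rather than silently dropped.
#'
#' @inheritParams mae
#' @return `mean(abs(y_hat - y) / y)`.
#' @export
mape <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("length mismatch")
  zero <- which(y == 0)
  if (length(zero) > 0L) {
    stop("MAPE is undefined for zero targets (rows ",
         paste(utils::head(zero, 5L), collapse = ", "),
         if (length(zero) > 5L) ", ..." else "", ")")
  }
  mean(abs(y_hat - y) / y)
}

#' Coefficient of determination
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`.
#'
#' @inheritParams mae
#' @return A scalar no greater than 1 (negative when predictions are worse
#'   than the mean).
#' @export
r_squared <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least two observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("`y` is constant; R^2 is undefined")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Repeated k-fold cross-validation of an estimator
#'
#' For each repetition the rows are shuffled (seeded) into `folds` folds; the
#' estimator is fitted on the training folds -- including any radius selection,
#' which therefore never sees validation rows -- and scored on the held-out
#' fold.  Summaries are the median and standard deviation of each metric over
#' all `folds * repetitions` validation folds.
#'
#' @param x feature matrix or data frame.
#' @param y numeric target vector.
#' @param estimator `"wevreg"`, `"wknn"`, or a function `function(x, y)`
#'   returning an object with a `predict(object, newdata)` method whose result
#'   is either a numeric vector or a data frame with a `fit` column.
#' @param folds number of folds (default 5).
#' @param repetitions number of repeated shuffles (default 5).
#' @param seed RNG seed for the fold assignments.
#' @param metrics metric names among `"mae"`, `"mape"`, `"r_squared"`.
#' @param ... passed on to the estimator (for the built-in names, to
#'   [wevreg()] / [wknn()]).
#' @return An object of class `eval_report`: `per_fold` data frame (one row
#'   per validation fold, with any estimator failure recorded in `error`),
#'   `summary` data frame (median and sd per metric), and the `protocol`.
#' @examples
#' d <- make_friedman(synthetic_spec("friedman", 60, 6, seed = 1))
#' repeated_kfold(d$x, d$y, "wknn", folds = 3, repetitions = 1,
#'                k = 5, epochs = 2)
#' @export
repeated_kfold <- function(x, y, estimator = "wevreg", folds = 5L,
                           repetitions = 5L, seed = 1L,
                           metrics = c("mae", "r_squared"), ...) {
  if (is.data.frame(x)) x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds) stop("need at least as many rows as folds")
  metrics <- match.arg(metrics, c("mae", "mape", "r_squared"),
                       several.ok = TRUE)
  fit_fun <- estimator_function(estimator, ...)
  metric_funs <- list(mae = mae, mape = mape, r_squared = r_squared)
  rows <- list()
  with_seed(seed, {
    for (rep_i in seq_len(repetitions)) {
      assign_fold <- sample(rep(seq_len(folds), length.out = n))
      for (fold_i in seq_len(folds)) {
        hold <- assign_fold == fold_i
        row <- list(repetition = rep_i, fold = fold_i, n_valid = sum(hold))
        res <- tryCatch({
          model <- fit_fun(x[!hold, , drop = FALSE], y[!hold])
          pred <- stats::predict(model, x[hold, , drop = FALSE])
          yh <- if (is.data.frame(pred)) pred$fit else as.numeric(pred)
          vals <- lapply(metric_funs[metrics], function(f) f(yh, y[hold]))
          c(vals, list(error = NA_character_))
        }, error = function(e) {
          warning("estimator failed on repetition ", rep_i, ", fold ", fold_i,
                  ": ", conditionMessage(e), call. = FALSE)
          out <- as.list(rep(NA_real_, length(metrics)))
          names(out) <- metrics
          c(out, list(error = conditionMessage(e)))
        })
        rows[[length(rows) + 1L]] <- c(row, res)
      }
    }
  })
  per_fold <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  summary <- data.frame(
    metric = metrics,
    median = vapply(metrics, function(m)
      stats::median(per_fold[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(m)
      stats::sd(per_fold[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
  structure(list(per_fold = per_fold, summary = summary,
                 protocol = list(folds = folds, repetitions = repetitions,
                                 seed = seed,
                                 estimator = if (is.character(estimator))
                                   estimator else "custom")),
            class = "eval_report")
}

estimator_function <- function(estimator, ...) {
  if (is.function(estimator)) {
    args <- list(...)
    return(function(x, y) do.call(estimator, c(list(x, y), args)))
  }
  estimator <- match.arg(estimator, c("wevreg", "wknn"))
  args <- list(...)
  fitter <- if (estimator == "wevreg") wevreg else wknn
  function(x, y) do.call(fitter, c(list(x, y), args))
}

#' @export
print.eval_report <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("Repeated %d-fold cross-validation, %d repetition(s) (%s, seed %d)\n",
              p$folds, p$repetitions, p$estimator, p$seed))
  fails <- sum(!is.na(x$per_fold$error))
  if (fails > 0L) cat("  !", fails, "fold(s) failed\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-10s median %.4f  (sd %.4f)\n", x$summary$metric[i],
                x$summary$median[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Run the synthetic benchmark protocol
#'
#' Generates the preset datasets, evaluates the requested estimators under the
#' repeated k-fold protocol and tabulates the per-metric medians (+- sd across
#' folds).  The kernel baseline is run with the same configuration as the
#' evidential model, inheriting the evidential radius-selection rule.
#'
#' @param presets character vector of preset names, see [synthetic_presets()].
#' @param estimators character vector among `"wevreg"`, `"wknn"`.
#' @param seed seed used both for dataset generation and fold shuffling.
#' @param k,alpha,epochs training configuration shared by the estimators.
#' @param folds,repetitions protocol size.
#' @return A data frame with one row per (preset, estimator): columns
#'   `preset`, `estimator`, `mae_median`, `mae_sd`, `r2_median`, `r2_sd`.
#' @export
benchmark_synthetic <- function(presets = c("linear_200", "friedman_200"),
                                estimators = c("wevreg", "wknn"),
                                seed = 1L, k = 20L, alpha = 0.1,
                                epochs = 100L, folds = 5L, repetitions = 5L) {
  all_specs <- synthetic_presets(seed)
  presets <- match.arg(presets, names(all_specs), several.ok = TRUE)
  out <- list()
  for (ps in presets) {
    d <- generate_synthetic(all_specs[[ps]])
    for (est in estimators) {
      rep_ev <- repeated_kfold(d$x, d$y, est, folds = folds,
                               repetitions = repetitions, seed = seed,
                               k = k, alpha = alpha, epochs = epochs)
      s <- rep_ev$summary
      out[[length(out) + 1L]] <- data.frame(
        preset = ps, estimator = est,
        mae_median = s$median[s$metric == "mae"],
        mae_sd = s$sd[s$metric == "mae"],
        r2_median = s$median[s$metric == "r_squared"],
        r2_sd = s$sd[s$metric == "r_squared"])
    }
  }
  do.call(rbind, out)
}
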