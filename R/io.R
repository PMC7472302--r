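#' Read a delimited table into features and target
#'
#' Reads a CSV (header row, '.' decimal) and splits it into a numeric feature
#' matrix and the named target column.  Rows with missing or non-numeric
#' entries are rejected with their row numbers, unless `impute_median = TRUE`,
#' in which case missing feature values are replaced by the column median
#' (rows with a missing target are always rejected).
#'
#' @param path file path.
#' @param target name of the target column.
#' @param impute_median replace missing feature cells by column medians
#'   instead of failing (default `FALSE`).
#' @return A list with `x` (numeric matrix), `y` (numeric vector) and
#'   `feature_names`.
#' @export
read_table <- function(path, target = "y", impute_median = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (!target %in% names(df)) {
    stop("target column '", target, "' not found in ", path)
  }
  y <- df[[target]]
  xdf <- df[setdiff(names(df), target)]
  if (ncol(xdf) == 0L) stop("no feature columns in ", path)
  non_num <- names(xdf)[!vapply(xdf, is.numeric, logical(1))]
  if (length(non_num) > 0L) {
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "))
  }
  if (!is.numeric(y)) stop("target column '", target, "' is not numeric")
  x <- as.matrix(xdf)
  if (anyNA(y)) {
    stop("missing target at row(s) ",
         paste(utils::head(which(is.na(y)), 5L), collapse = ", "))
  }
  if (anyNA(x)) {
    if (impute_median) {
      for (j in seq_len(ncol(x))) {
        miss <- is.na(x[, j])
        if (any(miss)) x[miss, j] <- stats::median(x[, j], na.rm = TRUE)
      }
    } else {
      bad <- which(rowSums(is.na(x)) > 0)
      stop("missing feature value at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " (set impute_median = TRUE to median-fill)")
    }
  }
  list(x = x, y = y, feature_names = colnames(x))
}

#' Write a dataset as a delimited table
#'
#' Writes features plus target as a header CSV.  For a `synthetic_data`
#' object a JSON sidecar (`<path>.meta.json`) records the generating spec for
#' provenance.
#'
#' @param data a `synthetic_data` object, or a list with `x` and `y`.
#' @param path output file path.
#' @param target name for the target column.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path, target = "y") {
  df <- as.data.frame(data$x)
  df[[target]] <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  if (inherits(data, "synthetic_data")) {
    jsonlite::write_json(unclass(data$spec), paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

MODEL_FORMAT_VERSION <- "1"

#' Save a fitted model as versioned plain text
#'
#' Serializes everything needed to reproduce predictions -- feature names and
#' normalization ranges, training data, learned weights and the full
#' configuration -- as JSON.
#'
#' @param model a fitted `wevreg_model` or `wknn_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wevreg_model"))
  payload <- list(
    format = "wevreg-model", version = MODEL_FORMAT_VERSION,
    config = model$config,
    feature_names = model$train$feature_names,
    feature_ranges = model$train$feature_ranges,
    w = unname(model$w),
    X = model$train$X, y = model$train$y,
    y_inf = model$train$y_inf, y_sup = model$train$y_sup,
    loss_history = if (!is.null(model$fit)) model$fit$loss_history,
    best_epoch = if (!is.null(model$fit)) model$fit$best_epoch
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path file path.
#' @return A `wevreg_model` (or `wknn_model`) whose predictions are identical
#'   to the saved model's.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "wevreg-model")) {
    stop(path, " is not a wevreg model file")
  }
  if (!identical(as.character(p$version), MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", p$version)
  }
  for (f in c("gamma", "alpha", "p")) p$config[[f]] <- as.numeric(p$config[[f]])
  for (f in c("k", "epochs")) p$config[[f]] <- as.integer(p$config[[f]])
  X <- as.matrix(p$X)
  dimnames(X) <- NULL
  ranges <- as.matrix(p$feature_ranges)
  dimnames(ranges) <- NULL
  train <- structure(
    list(X = X, y = as.numeric(p$y), y_inf = p$y_inf, y_sup = p$y_sup,
         feature_ranges = ranges, feature_names = p$feature_names),
    class = "training_set")
  fit <- NULL
  if (!is.null(p$loss_history)) {
    fit <- structure(list(w_hat = as.numeric(p$w),
                          loss_history = as.numeric(p$loss_history),
                          best_epoch = p$best_epoch,
                          estimator = p$config$estimator),
                     class = "fit_result")
  }
  cls <- if (identical(p$config$estimator, "wknn"))
    c("wknn_model", "wevreg_model") else "wevreg_model"
  structure(list(train = train,
                 w = stats::setNames(as.numeric(p$w), p$feature_names),
                 fit = fit, config = p$config),
            class = cls)
}
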