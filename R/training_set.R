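#' Construct an evidence (training) set
#'
#' Packages a feature matrix and a numeric target into the evidence set used by
#' the evidential and kernel regressors.  Features are min-max normalized to
#' \[0, 1\] column-wise using the training data's own ranges (so that learned
#' per-feature weights are comparable across features); the raw ranges are kept
#' so that new queries can be mapped into the same space.  The observed target
#' range \[`y_inf`, `y_sup`\] is stored as the domain interval that receives the
#' model's residual (ignorance) mass.
#'
#' @param x numeric matrix or data frame of features (rows = examples).
#' @param y numeric target vector, one value per row of `x`.
#' @return An object of class `training_set` with elements
#'   \describe{
#'     \item{X}{normalized feature matrix, all values in \[0, 1\].}
#'     \item{y}{target vector.}
#'     \item{y_inf, y_sup}{observed target minimum and maximum.}
#'     \item{feature_ranges}{2 x q matrix of raw per-feature (min, max).}
#'     \item{feature_names}{column names (generated when absent).}
#'   }
#' @examples
#' ts <- training_set(matrix(rnorm(20), 10, 2), rnorm(10))
#' range(ts$X)
#' @export
training_set <- function(x, y) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) {
    stop("`x` has ", nrow(x), " rows but `y` has length ", length(y))
  }
  if (nrow(x) < 1L) stop("training set must contain at least one row")
  if (!all(is.finite(x))) stop("`x` contains non-finite values")
  if (!all(is.finite(y))) stop("`y` contains non-finite values")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(x)) - 1L)
  rng <- apply(x, 2L, range)           # 2 x q: raw min / max
  Xn <- normalize_features(x, rng)
  structure(
    list(X = Xn, y = y, y_inf = min(y), y_sup = max(y),
         feature_ranges = rng, feature_names = nm),
    class = "training_set"
  )
}

#' Map raw feature values into a training set's normalized space
#'
#' Applies the stored min-max normalization; values outside the training range
#' are clipped to \[0, 1\] so that distant queries cannot leave the space the
#' weights were learned in.
#'
#' @param x numeric matrix (or vector, treated as one row) in raw feature units.
#' @param ranges a 2 x q matrix of (min, max) per feature, or a `training_set`.
#' @return numeric matrix with values in \[0, 1\].
#' @export
normalize_features <- function(x, ranges) {
  if (inherits(ranges, "training_set")) ranges <- ranges$feature_ranges
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(ranges)) {
    stop("feature dimension mismatch: got ", ncol(x), ", expected ", ncol(ranges))
  }
  lo <- ranges[1L, ]
  span <- ranges[2L, ] - ranges[1L, ]
  span[span == 0] <- 1          # constant feature: maps to 0
  Xn <- sweep(sweep(x, 2L, lo, "-"), 2L, span, "/")
  Xn[Xn < 0] <- 0
  Xn[Xn > 1] <- 1
  Xn
}

#' @export
print.training_set <- function(x, ...) {
  cat("Evidence set: ", nrow(x$X), " examples, ", ncol(x$X), " features\n",
      "target range: [", format(x$y_inf), ", ", format(x$y_sup), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.training_set <- function(x) dim(x$X)
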