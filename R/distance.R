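#' Weighted Minkowski distance
#'
#' Distance between two feature vectors under per-feature multiplicative
#' weights: `(sum_k |w_k * (x_ik - x_jk)|^p)^(1/p)`.  With all-ones weights
#' this is the ordinary Minkowski distance; a zero weight erases a feature
#' from the metric.  Nonnegative weights make the weighted distance identical
#' to the unweighted distance between the elementwise-scaled vectors `w * x`,
#' which is how the k-NN search applies it.
#'
#' @param xi,xj numeric vectors of equal length.
#' @param w nonnegative weight vector of the same length (default all ones).
#' @param p Minkowski exponent in \[1, 2\]; 2 gives the Euclidean metric.
#' @return A single nonnegative number.
#' @examples
#' weighted_minkowski(c(1, 1), c(0, 0), w = c(2, 1), p = 1)  # 3
#' weighted_minkowski(c(1, 1), c(0, 0), w = c(2, 1), p = 2)  # sqrt(5)
#' @export
weighted_minkowski <- function(xi, xj, w = rep(1, length(xi)), p = 2) {
  if (length(xi) != length(xj) || length(w) != length(xi)) {
    stop("`xi`, `xj` and `w` must have the same length")
  }
  if (!all(is.finite(xi)) || !all(is.finite(xj)) || !all(is.finite(w))) {
    stop("non-finite input")
  }
  check_p(p)
  if (any(w < 0)) stop("weights must be nonnegative")
  sum(abs(w * (xi - xj))^p)^(1 / p)
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1 || p > 2) {
    stop("`p` must be a single number in [1, 2]")
  }
  invisible(p)
}

#' Exact k-nearest-neighbour search under a weighted metric
#'
#' Exhaustively finds the `k` training rows closest to a query under the
#' weighted Minkowski distance.  The query is given in raw feature units and is
#' normalized (and clipped) into the training set's \[0, 1\] space first.
#' Ties at equal distance are broken by ascending row index, so results are
#' deterministic.
#'
#' @param train a [training_set()].
#' @param x query vector in raw feature units.
#' @param w nonnegative per-feature weights (default all ones).
#' @param k number of neighbours requested; if it exceeds the available rows,
#'   all rows are returned with a warning.
#' @param p Minkowski exponent in \[1, 2\].
#' @param exclude optional row index to leave out (for leave-one-out use).
#' @return An object of class `neighbor_set`: a list with `indices` (row ids,
#'   distance-ordered) and `distances` (non-decreasing weighted distances).
#' @examples
#' ts <- training_set(matrix(0:2), c(0, 1, 2))
#' knn_search(ts, 0.1, k = 2)$indices
#' @export
knn_search <- function(train, x, w = NULL, k = 1L, p = 2, exclude = NULL) {
  stopifnot(inherits(train, "training_set"))
  q <- ncol(train$X)
  if (is.null(w)) w <- rep(1, q)
  if (length(w) != q) stop("`w` must have length ", q)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  check_p(p)
  if (k < 1L) stop("`k` must be at least 1")
  xn <- drop(normalize_features(x, train))
  keep <- seq_len(nrow(train$X))
  if (!is.null(exclude)) keep <- keep[-exclude]
  if (length(keep) == 0L) stop("no training rows left after exclusion")
  d <- minkowski_to_rows(train$X[keep, , drop = FALSE], xn, w, p)
  if (k > length(keep)) {
    warning("k = ", k, " exceeds the ", length(keep),
            " available rows; returning all of them")
    k <- length(keep)
  }
  ord <- order(d)[seq_len(k)]            # order() is stable: ties by row index
  structure(list(indices = keep[ord], distances = d[ord]),
            class = "neighbor_set")
}

# distances from one normalized query to each row of a normalized matrix
minkowski_to_rows <- function(X, xn, w, p) {
  if (p == 2) {
    Z <- X %*% diag(w, length(w))
    zq <- xn * w
    d2 <- rowSums(Z^2) - 2 * drop(Z %*% zq) + sum(zq^2)
    sqrt(pmax(d2, 0))
  } else {
    A <- abs(sweep(X, 2L, xn, "-"))
    rowSums(sweep(A, 2L, w, "*")^p)^(1 / p)
  }
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat("neighbor_set with", length(x$indices), "neighbours\n")
  print(data.frame(index = x$indices, distance = x$distances), ...)
  invisible(x)
}
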