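# Independent oracles used across the suite.  These are deliberately naive
# (loops, literal formula transcriptions) and share no code with the package's
# vectorized implementation.

# brute-force nearest neighbours: all pairwise distances, full sort
brute_knn <- function(Xn, xq, w, k, p = 2) {
  d <- apply(Xn, 1L, function(row) sum(abs(w * (row - xq))^p)^(1 / p))
  ord <- order(d)[seq_len(k)]
  list(indices = ord, distances = d[ord])
}

# literal transcription of the mass formulas: phi * prod-over-others, total
# product, normalization as the sum of both parts
oracle_masses <- function(phi) {
  N <- length(phi)
  m_un <- vapply(seq_len(N), function(i) {
    phi[i] * prod(1 - phi[setdiff(seq_len(N), i)])
  }, numeric(1))
  K <- prod(1 - phi) + sum(m_un)
  list(m = m_un / K, dm = prod(1 - phi) / K, K = K)
}

# central finite differences of the LOO mean squared error
fd_gradient <- function(ts, w, k, gamma, p = 2, estimator = "wevreg",
                        h = 1e-5) {
  vapply(seq_along(w), function(j) {
    wp <- w; wp[j] <- w[j] + h
    wm <- w; wm[j] <- w[j] - h
    lp <- loss_mse(ts$y, loo_predictions(ts, wp, k, gamma, p,
                                         estimator = estimator))
    lm <- loss_mse(ts$y, loo_predictions(ts, wm, k, gamma, p,
                                         estimator = estimator))
    (lp - lm) / (2 * h)
  }, numeric(1))
}

# small random regression instance in normalized units
random_instance <- function(n, q, y_fun = NULL) {
  x <- matrix(runif(n * q), n, q)
  y <- if (is.null(y_fun)) runif(n) else y_fun(x)
  list(x = x, y = y, ts = training_set(x, y))
}

# neighbor_set with chosen distances, for exercising the mass calculus
# directly
fake_neighbors <- function(distances, indices = seq_along(distances)) {
  structure(list(indices = indices, distances = distances),
            class = "neighbor_set")
}

# The LOO loss is piecewise smooth: it is non-differentiable exactly where a
# perturbation of w swaps a neighbour in or out.  Central differences are a
# valid oracle only away from those switch points, so gradient checks draw
# instances until the neighbour sets are stable under the probe step.
knn_stable <- function(ts, w, k, h = 1e-5, p = 2) {
  base_D <- wevreg:::pair_dist(ts$X, w, p)
  diag(base_D) <- Inf
  nb0 <- wevreg:::knn_rows(base_D, k)
  for (j in seq_along(w)) {
    for (s in c(-h, h)) {
      wp <- w
      wp[j] <- wp[j] + s
      D <- wevreg:::pair_dist(ts$X, wp, p)
      diag(D) <- Inf
      nb <- wevreg:::knn_rows(D, k)
      for (i in seq_len(nrow(ts$X))) {
        if (!setequal(nb0[i, ], nb[i, ])) return(FALSE)
      }
    }
  }
  TRUE
}

# a random instance + hyperparameters at which the LOO loss is differentiable
draw_differentiable_instance <- function() {
  repeat {
    n <- sample(10:20, 1)
    q <- sample(2:6, 1)
    inst <- random_instance(n, q, y_fun = function(x)
      rowSums(x) + rnorm(nrow(x), 0, 0.2))
    w <- runif(q, 0.4, 1.6)
    k <- sample(3:min(7, n - 1), 1)
    gamma <- runif(1, 0.3, 1.5)
    if (knn_stable(inst$ts, w, k)) {
      return(list(ts = inst$ts, w = w, k = k, gamma = gamma))
    }
  }
}
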