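# Internal vectorized numeric engine shared by the evidential and kernel
# regressors.  All functions here assume features already normalized to [0, 1]
# and weights finite and nonnegative.

PHI_CAP <- 1 - 1e-12   # keeps 1 - phi > 0 so K > 0 even for duplicated rows

# discount kernel; "exp_sq" is the form consistent with the analytic gradient,
# "exp_raw" the raw-distance variant
phi_kernel <- function(d, gamma, form = c("exp_sq", "exp_raw")) {
  form <- match.arg(form)
  v <- if (form == "exp_sq") exp(-d^2 / gamma) else exp(-d / gamma^2)
  pmin(v, PHI_CAP)
}

# full pairwise weighted-Minkowski distance matrix between rows of X (and Y)
pair_dist <- function(X, w, p, Y = NULL) {
  if (p == 2) {
    Z <- sweep(X, 2L, w, "*")
    if (is.null(Y)) {
      sq <- rowSums(Z^2)
      D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
    } else {
      Zy <- sweep(Y, 2L, w, "*")
      D2 <- outer(rowSums(Z^2), rowSums(Zy^2), "+") - 2 * tcrossprod(Z, Zy)
    }
    D2[D2 < 0] <- 0
    sqrt(D2)
  } else {
    B <- if (is.null(Y)) X else Y
    D <- matrix(0, nrow(X), nrow(B))
    for (i in seq_len(nrow(X))) {
      D[i, ] <- rowSums(sweep(abs(sweep(B, 2L, X[i, ], "-")), 2L, w, "*")^p)^(1 / p)
    }
    D
  }
}

# k smallest entries per row of a distance matrix; ties broken by column index
# (order() is stable).  Returns an n x k index matrix.
knn_rows <- function(D, k) {
  nb <- apply(D, 1L, function(r) order(r)[seq_len(k)])
  if (k == 1L) matrix(nb, ncol = 1L) else t(nb)
}

# target bounds of each leave-one-out subset y[-i]
loo_bounds <- function(y) {
  n <- length(y)
  ys <- sort(y)
  y_inf <- rep(ys[1L], n)
  y_sup <- rep(ys[n], n)
  if (sum(y == ys[1L]) == 1L) y_inf[y == ys[1L]] <- ys[2L]
  if (sum(y == ys[n]) == 1L) y_sup[y == ys[n]] <- ys[n - 1L]
  list(inf = y_inf, sup = y_sup)
}

# One leave-one-out pass over the training matrix: predictions for every row
# from the remaining n-1 rows, and (optionally) the analytic gradient of the
# LOO mean squared error with respect to the feature weights.
loo_pass <- function(X, y, w, k, gamma, p = 2, form = "exp_sq",
                     estimator = c("wevreg", "wknn"), grad = TRUE) {
  estimator <- match.arg(estimator)
  n <- nrow(X)
  if (n < 2L) stop("leave-one-out requires at least two rows")
  D <- pair_dist(X, w, p)
  diag(D) <- Inf
  k_eff <- min(k, n - 1L)
  nb <- knn_rows(D, k_eff)
  ii <- rep(seq_len(n), times = k_eff)
  jj <- as.vector(nb)
  Dn <- matrix(D[cbind(ii, jj)], n, k_eff)
  Yn <- matrix(y[jj], n, k_eff)

  if (estimator == "wevreg") {
    b <- loo_bounds(y)
    cvec <- (b$inf + b$sup) / 2
    phi <- phi_kernel(Dn, gamma, form)
    r <- phi / (1 - phi)
    R <- rowSums(r)
    y_hat <- (cvec + rowSums(r * Yn)) / (1 + R)
    if (!grad) return(list(y_hat = y_hat))
    chain <- (2 / n) * (y_hat - y) * ((Yn - y_hat) / (1 + R)) / (1 - phi)^2
    if (form == "exp_sq") {
      fac <- -(2 / gamma) * phi * Dn^(2 - p)
    } else {
      fac <- -(1 / gamma^2) * phi * Dn^(1 - p)
      fac[Dn < 1e-12] <- 0
    }
    chain[phi >= PHI_CAP] <- 0            # clamped region is flat
    a <- chain * fac
  } else {
    s <- exp(-Dn / gamma)
    Zs <- rowSums(s)
    y_hat <- rowSums(s * Yn) / Zs
    if (!grad) return(list(y_hat = y_hat))
    chain <- (2 / n) * (y_hat - y) * s * (y_hat - Yn) / (gamma * Zs)
    fac <- Dn^(1 - p)
    fac[Dn < 1e-12] <- 0
    a <- chain * fac
  }

  # d(d)/dw_k = d^(1-p) w_k^(p-1) |delta_k|^p; the d-power is already in `fac`
  A <- abs(X[ii, , drop = FALSE] - X[jj, , drop = FALSE])
  A <- if (p == 2) A * A else A^p
  G <- w^(p - 1) * as.vector(crossprod(A, as.vector(a)))
  if (any(!is.finite(G))) {
    stop("non-finite gradient component; check gamma and the weight state")
  }
  list(y_hat = y_hat, gradient = G)
}

# Batch prediction of normalized queries Xq against a normalized training
# matrix.  Returns point estimates and, for the evidential estimator, bounds
# and the domain (ignorance) mass.
batch_predict <- function(Xtr, ytr, y_inf, y_sup, Xq, w, k, gamma, p = 2,
                          form = "exp_sq", estimator = c("wevreg", "wknn")) {
  estimator <- match.arg(estimator)
  n <- nrow(Xtr)
  m <- nrow(Xq)
  k_eff <- min(k, n)
  D <- pair_dist(Xq, w, p, Y = Xtr)
  nb <- knn_rows(D, k_eff)
  jj <- as.vector(nb)
  Dn <- matrix(D[cbind(rep(seq_len(m), k_eff), jj)], m, k_eff)
  Yn <- matrix(ytr[jj], m, k_eff)
  if (estimator == "wevreg") {
    phi <- phi_kernel(Dn, gamma, form)
    r <- phi / (1 - phi)
    R <- rowSums(r)
    m_star <- 1 / (1 + R)
    fit <- (rowSums(r * Yn) + (y_inf + y_sup) / 2) / (1 + R)
    half <- m_star * (y_sup - y_inf) / 2
    data.frame(fit = fit, lwr = fit - half, upr = fit + half,
               uncertainty = m_star)
  } else {
    s <- exp(-Dn / gamma)
    data.frame(fit = rowSums(s * Yn) / rowSums(s))
  }
}
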