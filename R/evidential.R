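#' Distance discount (similarity) function
#'
#' Maps a nonnegative distance to a similarity in (0, 1\] that controls how
#' strongly a training example's evidence counts.  The default form is the
#' radial-basis kernel `exp(-d^2 / gamma)`, whose analytic derivative is the
#' one the weight-learning gradient uses; `form = "exp_raw"` selects the
#' raw-distance variant `exp(-d / gamma^2)`.  Values are capped just below 1
#' so that coincident points cannot produce a degenerate (0/0) mass
#' normalization.
#'
#' @param d nonnegative distance (vectorized).
#' @param gamma positive radius: how far an example's influence reaches.
#' @param form `"exp_sq"` (default) or `"exp_raw"`.
#' @return Similarity values in (0, 1\].
#' @examples
#' discount(1, gamma = 1)  # exp(-1)
#' @export
discount <- function(d, gamma, form = c("exp_sq", "exp_raw")) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be a single positive number")
  }
  if (any(d < 0)) stop("distances must be nonnegative")
  phi_kernel(d, gamma, match.arg(form))
}

#' Dempster-Shafer masses over a k-nearest-neighbour evidence set
#'
#' Combines the discounted evidence of the query's neighbours with the
#' domain-interval evidence.  Each neighbour `i` receives mass
#' `m_i = phi_i * prod_{h != i} (1 - phi_h) / K`; the residual `domain_mass`
#' `m* = prod_i (1 - phi_i) / K` is the model's ignorance, and `K` normalizes
#' the assignment to sum to one.  Product sequences are evaluated with
#' prefix/suffix products (never by dividing a total product), and the
#' computation falls back to the algebraically equivalent odds form
#' `r_i = phi_i / (1 - phi_i)` if the products underflow.
#'
#' @param x query vector in raw feature units (ignored when `neighbors`
#'   carries precomputed distances).
#' @param train a [training_set()].
#' @param neighbors optional `neighbor_set` (as from [knn_search()]); when
#'   `NULL` it is computed from `x` with the parameters below.
#' @param w nonnegative per-feature weights (default all ones).
#' @param gamma positive discount radius.
#' @param k neighbour count used when `neighbors` is `NULL`.
#' @param p Minkowski exponent in \[1, 2\].
#' @param form discount form, see [discount()].
#' @return An object of class `mass_assignment`: list with `neighbor_masses`
#'   (named by training-row index), `domain_mass` and the normalization `K`.
#' @examples
#' ts <- training_set(matrix(runif(20), 10, 2), runif(10))
#' m <- compute_masses(runif(2), ts, k = 3, gamma = 0.5)
#' sum(m$neighbor_masses) + m$domain_mass  # 1
#' @export
compute_masses <- function(x, train, neighbors = NULL, w = NULL, gamma = 1,
                           k = 5L, p = 2, form = c("exp_sq", "exp_raw")) {
  stopifnot(inherits(train, "training_set"))
  form <- match.arg(form)
  if (is.null(neighbors)) {
    neighbors <- knn_search(train, x, w = w, k = k, p = p)
  }
  phi <- discount(neighbors$distances, gamma, form)
  mass_from_phi(phi, neighbors$indices)
}

#' Full-evidence-set masses
#'
#' As [compute_masses()] but with every training row in the evidence set,
#' i.e. the k-nearest-neighbour restriction removed (`k = n`).
#'
#' @inheritParams compute_masses
#' @return A `mass_assignment` over all training rows.
#' @export
compute_masses_full <- function(x, train, w = NULL, gamma = 1, p = 2,
                                form = c("exp_sq", "exp_raw")) {
  stopifnot(inherits(train, "training_set"))
  compute_masses(x, train, w = w, gamma = gamma, k = nrow(train$X), p = p,
                 form = match.arg(form))
}

# masses from discount values, prefix/suffix product evaluation
mass_from_phi <- function(phi, indices) {
  u <- 1 - phi                                   # > 0 by the discount cap
  nk <- length(u)
  pref <- c(1, cumprod(u))[seq_len(nk)]          # prod_{h < i} u_h
  suf <- rev(c(1, cumprod(rev(u))))[-1L]         # prod_{h > i} u_h
  leave_one_out <- pref * suf
  s <- phi * leave_one_out                       # unnormalized neighbour masses
  P <- pref[nk] * u[nk]                          # prod_i u_i
  K <- P + sum(s)
  if (K > 0) {
    nm <- s / K
    dm <- P / K
  } else {                                       # underflow: odds form
    r <- phi / u
    R <- sum(r)
    nm <- r / (1 + R)
    dm <- 1 / (1 + R)
    K <- P
  }
  structure(list(neighbor_masses = stats::setNames(nm, indices),
                 domain_mass = dm, K = K),
            class = "mass_assignment")
}

#' @export
print.mass_assignment <- function(x, ...) {
  cat("mass_assignment over", length(x$neighbor_masses), "neighbours",
      sprintf("(domain mass %.4g)\n", x$domain_mass))
  print(x$neighbor_masses, ...)
  invisible(x)
}

#' Evidential point prediction with uncertainty bounds
#'
#' Runs the forward pass for one query: nearest-neighbour search under the
#' weighted metric, mass combination, and the Pignistic expectation
#' `y_hat = sum_i m_i y_i + m* (y_sup + y_inf) / 2`.  The lower/upper bounds
#' replace the midpoint with `y_inf` / `y_sup`, so the interval width is
#' `m* * (y_sup - y_inf)`: the wider the interval, the less evidence the
#' training set offered about this query.
#'
#' @inheritParams compute_masses
#' @param k neighbour count.
#' @param exclude optional training-row index to leave out (the query's own
#'   row during leave-one-out training); the target bounds are then those of
#'   the remaining rows.
#' @return An object of class `evidential_prediction`: list with `y_hat`,
#'   `y_lower`, `y_upper`, `uncertainty` (the domain mass) and the underlying
#'   `masses`.
#' @examples
#' ts <- training_set(matrix(runif(40), 20, 2), runif(20))
#' predict_point(c(0.5, 0.5), ts, gamma = 0.1, k = 5)
#' @export
predict_point <- function(x, train, w = NULL, k = 5L, gamma = 1, p = 2,
                          form = c("exp_sq", "exp_raw"), exclude = NULL) {
  stopifnot(inherits(train, "training_set"))
  if (nrow(train$X) < 1L) stop("empty training set")
  form <- match.arg(form)
  nb <- knn_search(train, x, w = w, k = k, p = p, exclude = exclude)
  ms <- compute_masses(x, train, neighbors = nb, gamma = gamma, form = form)
  y_pool <- if (is.null(exclude)) train$y else train$y[-exclude]
  point_from_masses(ms, train$y[nb$indices], min(y_pool), max(y_pool))
}

point_from_masses <- function(ms, y_nb, y_inf, y_sup) {
  s <- sum(ms$neighbor_masses * y_nb)
  dm <- ms$domain_mass
  y_hat <- s + dm * (y_sup + y_inf) / 2
  structure(list(y_hat = y_hat,
                 y_lower = s + dm * y_inf,
                 y_upper = s + dm * y_sup,
                 uncertainty = dm,
                 masses = ms),
            class = "evidential_prediction")
}

#' @export
print.evidential_prediction <- function(x, ...) {
  cat(sprintf("prediction %.6g  [%.6g, %.6g]  (ignorance mass %.4g)\n",
              x$y_hat, x$y_lower, x$y_upper, x$uncertainty))
  invisible(x)
}
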