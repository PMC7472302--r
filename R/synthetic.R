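#' Describe a synthetic regression benchmark
#'
#' Captures everything needed to regenerate a benchmark dataset exactly: the
#' family, sizes, noise level and seed.  Two families are provided: a sparse
#' random linear model (Gaussian design, `n_informative` nonzero Gaussian
#' coefficients) and the Friedman function (uniform \[0, 1\] inputs, five
#' relevant features), both padded with irrelevant features and with additive
#' Gaussian output noise.
#'
#' @param family `"linear"` or `"friedman"`.
#' @param n_samples number of rows.
#' @param n_features total number of features (irrelevant ones included).
#' @param n_informative number of features that enter the response (fixed at
#'   5 for `"friedman"`).
#' @param noise_sd standard deviation of the additive Gaussian output noise.
#' @param seed RNG seed; the generators are pure functions of the spec.
#' @param scale_output if `TRUE`, min-max scale the target to \[0, 1\] over
#'   the generated sample.
#' @param coef_sd standard deviation of the nonzero linear-model coefficients
#'   (linear family only).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(family = c("linear", "friedman"), n_samples = 200L,
                           n_features = 500L, n_informative = 5L,
                           noise_sd = 1, seed = 1L, scale_output = TRUE,
                           coef_sd = 100) {
  family <- match.arg(family)
  if (family == "friedman") {
    n_informative <- 5L
    if (n_features < 5L) stop("the Friedman function needs at least 5 features")
  }
  if (n_informative > n_features) stop("n_informative must not exceed n_features")
  if (n_samples < 1L) stop("n_samples must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(family = family, n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 scale_output = isTRUE(scale_output), coef_sd = coef_sd),
            class = "synthetic_spec")
}

#' Noiseless Friedman response
#'
#' `10 sin(pi x0 x1) + 20 (x2 - 0.5)^2 + 10 x3 + 5 x4`, a standard nonlinear
#' regression benchmark in which only the first five features matter.
#'
#' @param x numeric vector (length >= 5) or matrix (>= 5 columns) with the
#'   first five entries/columns in \[0, 1\].
#' @return Numeric response, one value per row.
#' @examples
#' friedman_response(c(0, 0, 0, 0, 0))          # 5
#' friedman_response(c(1, 0.5, 1, 1, 1))        # 30
#' @export
friedman_response <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) < 5L) stop("need at least 5 features")
  drop(10 * sin(pi * x[, 1L] * x[, 2L]) + 20 * (x[, 3L] - 0.5)^2 +
         10 * x[, 4L] + 5 * x[, 5L])
}

#' Generate a Friedman benchmark dataset
#'
#' All features are drawn uniformly on \[0, 1\]; only the first five enter the
#' response, the rest are decoys for feature selection.  Gaussian noise of
#' `spec$noise_sd` is added to the output, which is optionally min-max scaled
#' to \[0, 1\].
#'
#' @param spec a [synthetic_spec()] with `family = "friedman"`.
#' @return A list of class `synthetic_data`: `x` (matrix with columns
#'   `f0..f{q-1}`), `y`, `y_raw` (pre-scaling), `f` (noiseless response) and
#'   `spec`.
#' @export
make_friedman <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$family == "friedman")
  with_seed(spec$seed, {
    X <- matrix(stats::runif(spec$n_samples * spec$n_features),
                spec$n_samples, spec$n_features)
    f <- friedman_response(X)
    y_raw <- f + stats::rnorm(spec$n_samples, sd = spec$noise_sd)
    finish_synthetic(X, y_raw, f, spec)
  })
}

#' Generate a sparse random linear-model dataset
#'
#' A Gaussian design matrix is min-max normalized to \[0, 1\] per column;
#' `n_informative` randomly chosen features receive Gaussian coefficients of
#' standard deviation `coef_sd` (the rest are zero), and Gaussian noise of
#' `spec$noise_sd` is added to the response.
#'
#' @param spec a [synthetic_spec()] with `family = "linear"`.
#' @return A `synthetic_data` list as in [make_friedman()], plus `coef`
#'   (the true coefficient vector).
#' @export
make_linear <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$family == "linear")
  with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$n_samples * spec$n_features),
                spec$n_samples, spec$n_features)
    if (spec$n_samples > 1L) {
      X <- apply(X, 2L, function(col) {
        rng <- range(col)
        if (rng[1L] == rng[2L]) rep(0, length(col))
        else (col - rng[1L]) / (rng[2L] - rng[1L])
      })
    }
    beta <- numeric(spec$n_features)
    inf_idx <- sample.int(spec$n_features, spec$n_informative)
    beta[inf_idx] <- stats::rnorm(spec$n_informative, sd = spec$coef_sd)
    f <- drop(X %*% beta)
    y_raw <- f + stats::rnorm(spec$n_samples, sd = spec$noise_sd)
    out <- finish_synthetic(X, y_raw, f, spec)
    out$coef <- beta
    out
  })
}

#' Generate a synthetic benchmark dataset from its spec
#'
#' Dispatches to [make_linear()] or [make_friedman()].
#'
#' @param spec a [synthetic_spec()].
#' @return A `synthetic_data` list.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$family == "linear") make_linear(spec) else make_friedman(spec)
}

finish_synthetic <- function(X, y_raw, f, spec) {
  colnames(X) <- paste0("f", seq_len(ncol(X)) - 1L)
  y <- y_raw
  if (spec$scale_output) {
    rng <- range(y_raw)
    if (rng[1L] < rng[2L]) y <- (y_raw - rng[1L]) / (rng[2L] - rng[1L])
  }
  structure(list(x = X, y = y, y_raw = y_raw, f = f, spec = spec),
            class = "synthetic_data")
}

#' @export
print.synthetic_data <- function(x, ...) {
  s <- x$spec
  cat(sprintf("synthetic_data (%s): %d x %d, %d informative, noise sd %g, seed %d\n",
              s$family, s$n_samples, s$n_features, s$n_informative,
              s$noise_sd, s$seed))
  invisible(x)
}

#' Benchmark preset specs
#'
#' The four standard benchmark configurations (200 or 5000 samples, linear or
#' Friedman family, 500 total features of which 5 are relevant, output noise
#' sd 1, outputs scaled to \[0, 1\]).
#'
#' @param seed RNG seed shared by the presets.
#' @return Named list of [synthetic_spec()] objects: `linear_200`,
#'   `friedman_200`, `linear_5000`, `friedman_5000`.
#' @export
synthetic_presets <- function(seed = 1L) {
  list(
    linear_200    = synthetic_spec("linear", 200L, 500L, seed = seed),
    friedman_200  = synthetic_spec("friedman", 200L, 500L, seed = seed),
    linear_5000   = synthetic_spec("linear", 5000L, 500L, seed = seed),
    friedman_5000 = synthetic_spec("friedman", 5000L, 500L, seed = seed)
  )
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
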