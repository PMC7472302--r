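test_that("mean squared error matches hand arithmetic", {
  expect_equal(loss_mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(loss_mse(c(0, 2), c(1, 1)), 1)
  expect_equal(loss_mse(c(1, 2, 3), c(1.5, 2, 2)), (0.25 + 0 + 1) / 3)
  expect_error(loss_mse(1:3, 1:2), "length")
})

test_that("leave-one-out predictions match the per-row exclusion oracle", {
  set.seed(51)
  inst <- random_instance(12, 3, y_fun = function(x) rowSums(x))
  w <- runif(3, 0.5, 1.5)
  got <- loo_predictions(inst$ts, w, k = 4, gamma = 0.5)
  want <- vapply(1:12, function(i) {
    predict_point(inst$x[i, ], inst$ts, w = w, k = 4, gamma = 0.5,
                  exclude = i)$y_hat
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("leave-one-out predictions are permutation-equivariant", {
  set.seed(52)
  inst <- random_instance(15, 3)
  perm <- sample(15)
  ts_p <- training_set(inst$x[perm, ], inst$y[perm])
  w <- runif(3, 0.5, 1.5)
  expect_equal(loo_predictions(ts_p, w, k = 5, gamma = 0.7),
               loo_predictions(inst$ts, w, k = 5, gamma = 0.7)[perm],
               tolerance = 1e-12)
})

test_that("identical duplicated rows with matching targets predict themselves", {
  x <- matrix(c(0.2, 0.2, 0.8), 3, 1)
  ts <- training_set(x, c(0.3, 0.3, 0.9))
  got <- loo_predictions(ts, k = 1, gamma = 1e-5)
  expect_equal(got[1:2], c(0.3, 0.3), tolerance = 1e-6)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(53)
  for (rep in 1:50) {
    case <- draw_differentiable_instance()
    g <- loss_gradient(case$ts, case$w, k = case$k, gamma = case$gamma)
    fd <- fd_gradient(case$ts, case$w, case$k, case$gamma)
    expect_equal(g, fd, tolerance = 1e-4)
  }
})

test_that("gradient handles the raw-distance discount and p < 2 as well", {
  set.seed(54)
  inst <- random_instance(15, 4, y_fun = function(x) rowSums(x))
  w <- runif(4, 0.5, 1.5)
  for (p in c(1, 1.4, 2)) {
    g <- loss_gradient(inst$ts, w, k = 5, gamma = 0.8, p = p)
    fd <- vapply(seq_along(w), function(j) {
      h <- 1e-5
      wp <- w; wp[j] <- w[j] + h
      wm <- w; wm[j] <- w[j] - h
      (loss_mse(inst$ts$y, loo_predictions(inst$ts, wp, 5, 0.8, p)) -
         loss_mse(inst$ts$y, loo_predictions(inst$ts, wm, 5, 0.8, p))) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-4)
  }
  g_raw <- loss_gradient(inst$ts, w, k = 5, gamma = 0.8, form = "exp_raw")
  fd_raw <- vapply(seq_along(w), function(j) {
    h <- 1e-5
    wp <- w; wp[j] <- w[j] + h
    wm <- w; wm[j] <- w[j] - h
    (loss_mse(inst$ts$y, loo_predictions(inst$ts, wp, 5, 0.8, form = "exp_raw")) -
       loss_mse(inst$ts$y, loo_predictions(inst$ts, wm, 5, 0.8, form = "exp_raw"))) / (2 * h)
  }, numeric(1))
  expect_equal(g_raw, fd_raw, tolerance = 1e-4)
})

test_that("a constant feature gets a zero gradient; twin columns get equal ones", {
  set.seed(55)
  x <- cbind(runif(12), 0.5, runif(12))
  x <- cbind(x, x[, 1])                     # column 4 duplicates column 1
  ts <- training_set(x, rowSums(x[, c(1, 3)]))
  g <- loss_gradient(ts, rep(1, 4), k = 4, gamma = 0.5)
  expect_equal(g[2], 0)
  expect_equal(g[1], g[4], tolerance = 1e-12)
})

test_that("weight fitting keeps the best observed state and its loss", {
  set.seed(56)
  inst <- random_instance(20, 3, y_fun = function(x) x[, 1] + rnorm(nrow(x), 0, 0.05))
  fit <- fit_weights(inst$ts, k = 5, gamma = 0.5, alpha = 0.05, epochs = 15)
  expect_equal(length(fit$loss_history), 15)
  expect_equal(min(fit$loss_history), fit$loss_history[fit$best_epoch])
  # the stored state reproduces its recorded loss
  re_loss <- loss_mse(inst$ts$y,
                      loo_predictions(inst$ts, fit$w_hat, 5, 0.5))
  expect_equal(re_loss, fit$loss_history[fit$best_epoch], tolerance = 1e-12)
  # never worse than the all-ones start
  expect_lte(min(fit$loss_history), fit$loss_history[1])
  expect_true(all(fit$w_hat >= 0))
  # one epoch: the returned state is the (unstepped) all-ones start
  fit1 <- fit_weights(inst$ts, k = 5, gamma = 0.5, epochs = 1)
  expect_equal(unname(fit1$w_hat), rep(1, 3))
})

test_that("weight learning recovers the informative feature on a toy signal", {
  set.seed(57)
  n <- 40
  x <- matrix(runif(n * 4), n, 4)
  y <- x[, 1]                               # target equals feature 1 exactly
  ts <- training_set(x, y)
  fit <- fit_weights(ts, k = 8, gamma = 0.5, alpha = 0.1, epochs = 40)
  expect_true(all(fit$w_hat[1] > fit$w_hat[2:4]))
})

test_that("plain gradient descent also reduces the loss", {
  set.seed(58)
  inst <- random_instance(25, 3, y_fun = function(x) x[, 1])
  fit <- fit_weights(inst$ts, k = 5, gamma = 0.5, alpha = 0.5, epochs = 25,
                     optimizer = "sgd")
  expect_lt(min(fit$loss_history), fit$loss_history[1])
})

test_that("feature ranking orders by weight and selects above the threshold", {
  fr0 <- rank_and_select(c(1, 1, 1))
  expect_equal(fr0$selected, integer(0))
  w <- c(cost_1 = 65.06, age = 6.19, gender = 1.09, noise = 0.2)
  fr <- rank_and_select(w)
  expect_equal(fr$ranking$feature, c("cost_1", "age", "gender", "noise"))
  expect_equal(unname(fr$selected), 1:3)
  # permuting features permutes the ranking consistently
  perm <- c(3, 1, 4, 2)
  fr_p <- rank_and_select(w[perm])
  expect_equal(fr_p$ranking$feature, fr$ranking$feature)
  expect_setequal(names(w)[perm][fr_p$selected], names(w)[fr$selected])
  # ties resolved by feature index
  fr_tie <- rank_and_select(c(b = 2, a = 2, c = 3))
  expect_equal(fr_tie$ranking$feature, c("c", "b", "a"))
})
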