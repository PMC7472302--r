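test_that("discount kernel has the right closed form and limits", {
  expect_equal(discount(0, gamma = 3), 1, tolerance = 1e-9)
  expect_equal(discount(1, gamma = 1), exp(-1))
  expect_lt(discount(100, gamma = 1), 1e-300)
  expect_equal(discount(2, gamma = 0.5, form = "exp_raw"), exp(-2 / 0.25))
  # strictly decreasing
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(discount(d, gamma = 0.7)) < 0))
  expect_error(discount(1, gamma = 0), "positive")
  expect_error(discount(-1, gamma = 1), "nonnegative")
})

test_that("two equally similar neighbours split the belief in thirds", {
  # phi = 0.5 for both neighbours: each neighbour mass 1/3, ignorance 1/3,
  # normalization 3/4; with targets {0, 1} on domain [0, 1] the prediction is
  # 1/2 with bounds [1/3, 2/3]
  ts <- training_set(matrix(c(0, 1), 2, 1), c(0, 1))
  d_half <- sqrt(log(2))                   # exp(-d^2) = 1/2
  nb <- fake_neighbors(c(d_half, d_half))
  m <- compute_masses(NULL, ts, neighbors = nb, gamma = 1)
  expect_equal(unname(m$neighbor_masses), c(1, 1) / 3)
  expect_equal(m$domain_mass, 1 / 3)
  expect_equal(m$K, 0.75)
  pr <- predict_point(0.5, ts, k = 2, gamma = 1)
  # the two training rows are equidistant from the query midpoint
  expect_equal(pr$y_hat, 0.5)
})

test_that("a single coincident neighbour takes essentially all the mass", {
  ts <- training_set(matrix(c(0, 1), 2, 1), c(0.2, 0.9))
  m <- compute_masses(NULL, ts, neighbors = fake_neighbors(0, indices = 1L),
                      gamma = 1)
  expect_equal(unname(m$neighbor_masses), 1, tolerance = 1e-9)
  expect_equal(m$domain_mass, 0, tolerance = 1e-9)
})

test_that("masses match a literal transcription of the combination formulas", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    phi_target <- runif(n, 0.05, 0.95)
    gamma <- runif(1, 0.2, 3)
    d <- sqrt(-gamma * log(phi_target))
    ts <- random_instance(n, 2)$ts
    m <- compute_masses(NULL, ts, neighbors = fake_neighbors(d), gamma = gamma)
    want <- oracle_masses(discount(d, gamma))
    expect_equal(unname(m$neighbor_masses), want$m, tolerance = 1e-12)
    expect_equal(m$domain_mass, want$dm, tolerance = 1e-12)
    expect_equal(m$K, want$K, tolerance = 1e-12)
  }
})

test_that("masses always sum to one and K stays positive", {
  set.seed(42)
  for (rep in 1:400) {
    n <- sample(2:50, 1)
    q <- sample(1:10, 1)
    gamma <- 10^runif(1, -2, 1)
    inst <- random_instance(n, q)
    k <- sample(1:n, 1)
    m <- compute_masses(runif(q), inst$ts, w = runif(q, 0, 2), gamma = gamma,
                        k = k)
    expect_equal(sum(m$neighbor_masses) + m$domain_mass, 1, tolerance = 1e-9)
    expect_gt(m$K, 0)
    expect_true(all(m$neighbor_masses >= 0 & m$neighbor_masses <= 1))
  }
})

test_that("restricting the evidence set to k = n reproduces the full-set masses", {
  set.seed(43)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    q <- sample(1:6, 1)
    inst <- random_instance(n, q)
    xq <- runif(q)
    w <- runif(q, 0.2, 2)
    gamma <- 10^runif(1, -1.5, 1)
    mk <- compute_masses(xq, inst$ts, w = w, gamma = gamma, k = n)
    mf <- compute_masses_full(xq, inst$ts, w = w, gamma = gamma)
    expect_equal(mk$neighbor_masses[order(as.integer(names(mk$neighbor_masses)))],
                 mf$neighbor_masses[order(as.integer(names(mf$neighbor_masses)))],
                 tolerance = 1e-10)
    expect_equal(mk$domain_mass, mf$domain_mass, tolerance = 1e-10)
  }
})

test_that("duplicated evidence points (distance 0 twice) stay well-defined", {
  ts <- training_set(matrix(c(0, 0, 1), 3, 1), c(0.5, 0.5, 1))
  m <- compute_masses(NULL, ts, neighbors = fake_neighbors(c(0, 0)), gamma = 1)
  expect_equal(sum(m$neighbor_masses) + m$domain_mass, 1, tolerance = 1e-9)
  expect_equal(unname(m$neighbor_masses)[1], unname(m$neighbor_masses)[2])
  expect_gt(m$K, 0)
})

test_that("increasing a neighbour's distance never increases its mass", {
  set.seed(44)
  others <- runif(4, 0.2, 1.5)
  masses <- sapply(seq(0.05, 2, by = 0.05), function(d0) {
    m <- compute_masses(NULL, random_instance(5, 2)$ts,
                        neighbors = fake_neighbors(c(d0, others)), gamma = 0.8)
    unname(m$neighbor_masses)[1]
  })
  expect_true(all(diff(masses) <= 1e-15))
})

test_that("prediction bounds bracket the point estimate with width = ignorance x range", {
  set.seed(45)
  for (rep in 1:30) {
    n <- sample(3:40, 1)
    q <- sample(1:5, 1)
    inst <- random_instance(n, q, y_fun = function(x) rowSums(x) + rnorm(nrow(x), 0, 0.1))
    pr <- predict_point(runif(q), inst$ts, k = min(5, n),
                        gamma = 10^runif(1, -1.5, 0.5))
    expect_lte(pr$y_lower, pr$y_hat)
    expect_lte(pr$y_hat, pr$y_upper)
    scale <- max(1, abs(inst$ts$y_sup), abs(inst$ts$y_inf))
    expect_lt(abs(pr$y_hat - (pr$y_lower + pr$y_upper) / 2), 1e-12 * scale)
    expect_lt(abs((pr$y_upper - pr$y_lower) -
                    pr$uncertainty * (inst$ts$y_sup - inst$ts$y_inf)),
              1e-12 * scale)
  }
})

test_that("a query on top of a training row inherits its target; a distant one is ignorant", {
  set.seed(46)
  x <- matrix(runif(30), 15, 2)
  y <- runif(15)
  ts <- training_set(x, y)
  on_row <- predict_point(x[7, ], ts, k = 3, gamma = 1e-4)
  expect_equal(on_row$y_hat, y[7], tolerance = 1e-6)
  expect_lt(on_row$uncertainty, 1e-6)
  # far query: all similarities vanish, prediction falls back to the midpoint
  far <- predict_point(c(1e6, 1e6), ts, k = 3, gamma = 1e-4)
  expect_equal(far$uncertainty, 1, tolerance = 1e-9)
  expect_equal(far$y_hat, (max(y) + min(y)) / 2, tolerance = 1e-9)
  expect_equal(far$y_upper - far$y_lower, max(y) - min(y), tolerance = 1e-9)
})

test_that("with negligible ignorance the estimate stays inside the neighbour target range", {
  set.seed(47)
  for (rep in 1:20) {
    inst <- random_instance(20, 2)
    xq <- runif(2)
    nb <- knn_search(inst$ts, xq, k = 4)
    pr <- predict_point(xq, inst$ts, k = 4, gamma = 50)  # wide radius: m* ~ 0
    expect_lt(pr$uncertainty, 1e-3)
    ynb <- inst$ts$y[nb$indices]
    expect_gte(pr$y_hat, min(ynb) - 1e-6)
    expect_lte(pr$y_hat, max(ynb) + 1e-6)
  }
})
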