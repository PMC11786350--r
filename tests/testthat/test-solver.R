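random_instance <- function(n, m, seed) {
  set.seed(seed)
  matrix(rgamma(n * m, 2, 0.5), n, m)
}

test_that("objective matches the explicit all-ones-matrix evaluation", {
  for (i in 1:20) {
    set.seed(i)
    n <- 6; m <- 5; R <- 2
    X <- random_instance(n, m, i)
    W <- matrix(runif(n * R), n, R)
    H <- matrix(runif(m * R), m, R)
    sg <- random_graph(m, k = 2, seed = i)
    l1 <- runif(1, 0, 2); l2 <- runif(1, 0, 2)
    expect_equal(fast_objective(X, W, H, sg, l1, l2),
                 objective_explicit(X, W, H, sg$G, l1, l2),
                 tolerance = 1e-10)
  }
})

test_that("objective special cases: zero residual and unit row sums", {
  set.seed(3)
  W <- matrix(runif(12), 6, 2); H <- matrix(runif(10), 5, 2)
  X <- W %*% t(H)
  expect_equal(fast_objective(X, W, H), 0, tolerance = 1e-20)
  Hs <- H / rowSums(H)
  sg <- random_graph(5, k = 2, seed = 1)
  expect_equal(fast_objective(X, W, Hs, sg, 0, 5),
               sum((X - W %*% t(Hs))^2), tolerance = 1e-12)
  expect_error(fast_objective(X, W, H[1:4, ]), "rows")
})

test_that("W update fixes points at zero residual and stays non-negative", {
  set.seed(11)
  W <- matrix(runif(16, 0.1, 1), 8, 2)
  H <- matrix(runif(12, 0.1, 1), 6, 2)
  X <- W %*% t(H)
  expect_equal(fast_update_w(X, W, H), W, tolerance = 1e-8)
  for (i in 1:20) {
    X2 <- random_instance(8, 6, i)
    W2 <- fast_update_w(X2, W, H)
    expect_true(all(W2 >= 0))
  }
})

test_that("updates never increase the objective (random instances)", {
  for (i in 1:25) {
    set.seed(i + 100)
    X <- random_instance(8, 6, i + 100)
    R <- 2
    W <- matrix(runif(8 * R), 8, R)
    H <- matrix(runif(6 * R), 6, R)
    sg <- random_graph(6, k = 2, seed = i)
    l1 <- sample(c(0, 0.01, 1, 10), 1)
    l2 <- sample(c(0, 0.01, 1, 10), 1)
    before <- fast_objective(X, W, H, sg, l1, l2)
    W2 <- fast_update_w(X, W, H)
    mid <- fast_objective(X, W2, H, sg, l1, l2)
    expect_lte(mid, before * (1 + 1e-9))
    H2 <- fast_update_h(X, W2, H, sg, l1, l2)
    expect_lte(fast_objective(X, W2, H2, sg, l1, l2), mid * (1 + 1e-9))
    expect_true(all(H2 >= 0))
  }
})

test_that("H update with no penalties reduces to the classic NMF rule", {
  set.seed(5)
  X <- random_instance(8, 6, 5)
  W <- matrix(runif(16), 8, 2); H <- matrix(runif(12), 6, 2)
  eps <- 1e-12
  classic <- H * (t(X) %*% W) / (H %*% (t(W) %*% W) + eps)
  expect_equal(fast_update_h(X, W, H), classic, tolerance = 1e-14)
})

test_that("a large sum-to-one penalty pulls deficient row sums toward 1", {
  # single spot, tiny residual influence: the update ratio must increase sums < 1
  set.seed(8)
  X <- matrix(1e-6, 4, 3)
  W <- matrix(1e-6, 4, 2)
  H <- matrix(0.2, 3, 2)           # row sums 0.4 < 1
  H2 <- fast_update_h(X, W, H, lambda2 = 100)
  expect_true(all(rowSums(H2) > rowSums(H)))
  expect_true(all(rowSums(H2) < 1.6))
  H3 <- fast_update_h(X, W, matrix(0.9, 3, 2), lambda2 = 100)  # sums 1.8 > 1
  expect_true(all(rowSums(H3) < 1.8))
})

test_that("fit with no penalties matches the plain multiplicative NMF oracle", {
  for (i in 1:5) {
    n <- 20; m <- 15; R <- 3; iters <- 25
    X <- random_instance(n, m, i * 7)
    oracle <- plain_nmf(X, R, seed = i, n_iter = iters)
    fit <- fast_fit(X, graph = NULL, R = R, lambda1 = 0, lambda2 = 0,
                    max_iter = iters, tol = 0, seed = i)
    expect_lt(max(abs(fit$W - oracle$W)), 1e-10)
    expect_lt(max(abs(fit$H - oracle$H)), 1e-10)
    # iterate-for-iterate at a shorter horizon too
    fit5 <- fast_fit(X, NULL, R = R, lambda1 = 0, lambda2 = 0,
                     max_iter = 5, tol = 0, seed = i)
    expect_lt(max(abs(fit5$W - oracle$W_trace[[5]])), 1e-10)
    expect_lt(max(abs(fit5$H - oracle$H_trace[[5]])), 1e-10)
  }
})

test_that("fit recovers a planted well-separated factorization", {
  set.seed(21)
  n <- 40; m <- 30
  Wp <- matrix(0, n, 2)
  Wp[1:20, 1] <- runif(20, 1, 2)     # disjoint marker blocks
  Wp[21:40, 2] <- runif(20, 1, 2)
  Hp <- matrix(runif(m * 2, 0.1, 1), m, 2)
  X <- Wp %*% t(Hp)
  fit <- fast_fit(X, NULL, R = 2, lambda1 = 0, lambda2 = 0,
                  max_iter = 2000, tol = 1e-10, seed = 2)
  rel <- sqrt(sum((X - tcrossprod(fit$W, fit$H))^2) / sum(X^2))
  expect_lt(rel, 0.05)
})

test_that("fitting is deterministic given the seed", {
  X <- random_instance(15, 12, 99)
  sg <- random_graph(12, k = 3, seed = 2)
  f1 <- fast_fit(X, sg, R = 3, seed = 42, max_iter = 50)
  f2 <- fast_fit(X, sg, R = 3, seed = 42, max_iter = 50)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$W, f2$W)
  f3 <- fast_fit(X, sg, R = 3, seed = 43, max_iter = 50)
  expect_false(identical(f1$objective_trace, f3$objective_trace))
})

test_that("objective trace is non-increasing across penalty regimes", {
  X <- random_instance(20, 16, 1)
  sg <- random_graph(16, k = 3, seed = 1)
  for (l1 in c(0, 0.01, 1, 10)) for (l2 in c(0, 0.01, 1, 10)) {
    fit <- fast_fit(X, sg, R = 3, lambda1 = l1, lambda2 = l2,
                    max_iter = 120, tol = 0, seed = 4)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(tr[-length(tr)], 1)),
                info = paste("lambda1 =", l1, "lambda2 =", l2))
  }
})

test_that("stronger sum-to-one penalty tightens row sums monotonically", {
  X <- random_instance(25, 20, 77)
  sg <- random_graph(20, k = 3, seed = 77)
  dev <- vapply(c(0, 0.1, 1, 10, 100), function(l2) {
    fit <- fast_fit(X, sg, R = 2, lambda1 = 1, lambda2 = l2,
                    max_iter = 2000, tol = 1e-9, seed = 5)
    mean(abs(rowSums(fit$H) - 1))
  }, numeric(1))
  expect_true(all(diff(dev) <= 1e-8))
})

test_that("approximate KKT stationarity holds at convergence", {
  # min(H, |grad_H|) elementwise small on planted instances
  for (i in 1:3) {
    set.seed(i * 13)
    n <- 20; m <- 15; R <- 2
    Wp <- matrix(0, n, R)
    Wp[1:10, 1] <- runif(10, 0.5, 1.5); Wp[11:20, 2] <- runif(10, 0.5, 1.5)
    Hp <- matrix(runif(m * R, 0.2, 0.8), m, R)
    X <- Wp %*% t(Hp)
    sg <- random_graph(m, k = 3, seed = i)
    l1 <- 0.5; l2 <- 0.5
    fit <- fast_fit(X, sg, R = R, lambda1 = l1, lambda2 = l2,
                    max_iter = 5000, tol = 0, seed = i)
    H <- fit$H; W <- fit$W
    kkt <- function(W, H) {
      grad <- -2 * t(X) %*% W + 2 * H %*% crossprod(W) +
        2 * l1 * as.matrix(sg$L %*% H) +
        2 * l2 * m * (matrix(rowSums(H), m, R) - 1)
      max(pmin(H, abs(grad)))
    }
    # continue the update sweeps until stationarity is reached
    sweeps <- 5000L
    while (kkt(W, H) >= 1e-3 && sweeps < 2e5) {
      for (s in 1:5000) {
        W <- fast_update_w(X, W, H)
        H <- fast_update_h(X, W, H, sg, l1, l2)
      }
      sweeps <- sweeps + 5000L
    }
    expect_lt(kkt(W, H), 1e-3)
  }
})

test_that("non-negativity is preserved over many randomized update steps", {
  set.seed(1234)
  count <- 0
  while (count < 1000) {
    n <- sample(4:10, 1); m <- sample(4:10, 1); R <- sample(2:3, 1)
    X <- matrix(rgamma(n * m, 1, 1), n, m)
    W <- matrix(runif(n * R), n, R); H <- matrix(runif(m * R), m, R)
    sg <- random_graph(m, k = 2, seed = count + 1)
    steps <- sample(5:20, 1)
    for (s in seq_len(steps)) {
      W <- fast_update_w(X, W, H)
      H <- fast_update_h(X, W, H, sg, lambda1 = runif(1, 0, 2),
                         lambda2 = runif(1, 0, 2))
      count <- count + 2
      expect_true(all(W >= 0) && all(H >= 0))
    }
  }
})

test_that("SVD-based initialization is non-negative and beats random early", {
  X <- random_instance(30, 20, 55)
  ini <- init_factors(X, 3, "nndsvd")
  expect_true(all(ini$W >= 0) && all(ini$H >= 0))
  expect_true(all(ini$W > 0) && all(ini$H > 0))  # zeros replaced by mean/100
  f_svd <- fast_fit(X, NULL, R = 3, lambda1 = 0, lambda2 = 0,
                    max_iter = 10, tol = 0, seed = 1, init = "nndsvd")
  f_rnd <- fast_fit(X, NULL, R = 3, lambda1 = 0, lambda2 = 0,
                    max_iter = 10, tol = 0, seed = 1, init = "random")
  expect_lt(f_svd$objective_trace[1], f_rnd$objective_trace[1])
})

test_that("fit validates rank and negative inputs", {
  X <- random_instance(6, 5, 1)
  expect_error(fast_fit(X, NULL, R = 6, lambda1 = 0, lambda2 = 0), "R must")
  Xn <- X; Xn[1, 1] <- -1
  expect_error(fast_fit(Xn, NULL, R = 2, lambda1 = 0, lambda2 = 0),
               "non-negative")
  expect_error(fast_fit(X, NULL, R = 2, lambda1 = 1, lambda2 = 0), "graph")
})

test_that("spot_proportions normalizes rows and handles zero rows", {
  H <- rbind(c(2, 2), c(0.3, 0.7), c(0, 0))
  expect_warning(P <- spot_proportions(H), "all-zero")
  expect_equal(P[1, ], c(0.5, 0.5))
  expect_equal(P[2, ], c(0.3, 0.7))
  expect_equal(P[3, ], c(0.5, 0.5))
  expect_equal(rowSums(P), rep(1, 3))
  H4 <- rbind(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_warning(P4 <- spot_proportions(H4))
  expect_equal(P4[1, ], rep(0.25, 4))
})
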