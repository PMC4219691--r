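test_that("single-covariate fits obey the soft-thresholding closed form", {
  set.seed(31)
  x <- drop(centred_gaussian(20, 1))
  y <- 2 * x                 # x'y/n = 2 for a population-sd-1 column
  f <- lasso_fit(y, matrix(x), lambda = 0.5)
  expect_equal(unname(f$beta), 1.5, tolerance = 1e-9)
  # below the threshold the coefficient vanishes exactly
  f0 <- lasso_fit(0.3 * x, matrix(x), lambda = 0.5)
  expect_identical(unname(f0$beta), 0)
})

test_that("orthonormal designs reduce to element-wise soft-thresholding", {
  set.seed(32)
  for (rep in 1:10) {
    n <- 4L
    Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
    X <- Q * sqrt(n)          # X'X/n = I
    y <- rnorm(n)
    cc <- drop(crossprod(X, y)) / n
    lam <- runif(1, 0.05, 0.8)
    f <- lasso_fit(y, X, lam)
    oracle <- sign(cc) * pmax(abs(cc) - lam, 0)
    expect_equal(unname(f$beta), oracle, tolerance = 1e-6)
  }
})

test_that("penalties at or above lambda_max shrink every coefficient to exactly zero", {
  set.seed(33)
  X <- centred_gaussian(30, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(30)
  y <- y - mean(y)
  lmax <- lambda_max(y, X)
  expect_true(all(lasso_fit(y, X, lmax)$beta == 0))
  expect_true(all(lasso_fit(y, X, lmax * 1.5)$beta == 0))
  expect_gt(sum(lasso_fit(y, X, lmax * 0.99)$beta != 0), 0)
})

test_that("the penalised fit approaches ordinary least squares as lambda vanishes", {
  set.seed(34)
  X <- centred_gaussian(50, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(50, sd = 0.5)
  y <- y - mean(y)
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  f <- lasso_fit(y, X, lambda = 1e-8)
  expect_equal(unname(f$beta), ols, tolerance = 1e-4)
})

test_that("solutions agree with an independent glmnet oracle on correlated designs", {
  skip_if_not_installed("glmnet")
  set.seed(35)
  for (rep in 1:10) {
    n <- 60L; p <- 15L
    X <- matrix(rnorm(n * p), n, p)
    X <- X + X[, sample(p)] * runif(1, 0, 1.5)   # induce collinearity
    X <- sweep(X, 2, colMeans(X))
    X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")
    y <- drop(X %*% (rnorm(p) * rbinom(p, 1, 0.4))) + rnorm(n)
    y <- y - mean(y)
    lam <- lambda_max(y, X) * 10^runif(1, -2.5, -0.3)
    f <- lasso_fit(y, X, lam)
    expect_equal(unname(f$beta), glmnet_lasso(y, X, lam), tolerance = 1e-4)
  }
})

test_that("sparsity is monotone non-increasing along increasing penalties", {
  set.seed(36)
  for (rep in 1:3) {
    X <- centred_gaussian(40, 10)
    y <- drop(X %*% (rnorm(10) * rbinom(10, 1, 0.5))) + rnorm(40)
    y <- y - mean(y)
    lmax <- lambda_max(y, X)
    grid <- exp(seq(log(lmax), log(0.001 * lmax), length.out = 30))
    nnz <- vapply(grid, function(l) sum(lasso_fit(y, X, l)$beta != 0), integer(1))
    expect_true(all(diff(nnz) >= 0))   # grid descends, support can only grow
  }
})

test_that("lambda estimation is deterministic, draws the stated gene subset and stays on the grid", {
  set.seed(37)
  x <- expression_matrix(matrix(rnorm(60 * 50), 60, 50))
  xs <- standardize(x)
  l1 <- estimate_lambda(xs, seed = 99)
  l2 <- estimate_lambda(xs, seed = 99)
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_length(attr(l1, "responses"), 5L)   # ceiling(0.10 * 50)
  # each per-response optimum lies on its own grid; the median lies within
  # the global grid envelope
  lmaxes <- vapply(attr(l1, "responses"), function(i)
    lambda_max(xs$values[, i], xs$values[, -i]), numeric(1))
  expect_gte(as.numeric(l1), 0.001 * min(lmaxes))
  expect_lte(as.numeric(l1), max(lmaxes))
  expect_error(estimate_lambda(standardize(
    expression_matrix(matrix(rnorm(3 * 5), 3, 5))), cv_folds = 4, seed = 1),
    "folds")
})

test_that("candidate ranking sorts by absolute coefficient and truncates by the best fraction", {
  fit <- structure(list(beta = c(0.9, -1.2, 0.3, 0, 0), lambda = 0.1,
                        response_index = NA_integer_), class = "lasso_fit")
  cand <- select_candidates(fit, best_fraction = 1)
  expect_identical(cand$index, c(2L, 1L, 3L))
  expect_equal(cand$coef, c(-1.2, 0.9, 0.3))

  fit10 <- structure(list(beta = seq(0.1, 1, by = 0.1), lambda = 0.1,
                          response_index = NA_integer_), class = "lasso_fit")
  expect_length(select_candidates(fit10, 0.8)$index, 8L)

  empty <- structure(list(beta = rep(0, 4), lambda = 0.1,
                          response_index = NA_integer_), class = "lasso_fit")
  expect_length(select_candidates(empty, 0.8)$index, 0L)

  # ties on |coefficient| break towards the smaller index
  tied <- structure(list(beta = c(-0.5, 0.5, 0.2), lambda = 0.1,
                         response_index = NA_integer_), class = "lasso_fit")
  expect_identical(select_candidates(tied, 1)$index, c(1L, 2L, 3L))
})
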