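test_that("counters are zero for B = 0, bounded by B, and zero for dead predictors", {
  set.seed(41)
  X <- centred_gaussian(30, 6)
  X <- cbind(X, 0)           # a zero-variance predictor can never be selected
  y <- drop(X[, 1:6] %*% rnorm(6)); y <- y - mean(y)
  cand <- make_candidates(index = c(1L, 3L, 7L), coef = c(1, 0.5, 0.2))
  expect_identical(permutation_counters(y, X, 0.05, cand, B = 0, seed = 1),
                   integer(3))
  ct <- permutation_counters(y, X, 0.05, cand, B = 40, seed = 1)
  expect_true(all(ct >= 0 & ct <= 40))
  expect_identical(ct[3], 0L)
  expect_error(permutation_counters(y, X, 0.05, cand, B = -1, seed = 1),
               "non-negative")
  # empty candidate sets short-circuit
  expect_identical(
    permutation_counters(y, X, 0.05, make_candidates(integer(0), numeric(0)),
                         B = 10, seed = 1),
    integer(0))
})

test_that("the batched permutation loop reproduces a sequential per-fit oracle", {
  set.seed(42)
  X <- centred_gaussian(40, 19)
  y <- drop(X %*% (rnorm(19) * rbinom(19, 1, 0.3))) + rnorm(40)
  y <- y - mean(y)
  lam <- lambda_max(y, X) * 0.05
  cand <- make_candidates(index = 1:8, coef = seq(0.8, 0.1, length.out = 8))
  B <- 50L; seed <- 77L
  fast <- permutation_counters(y, X, lam, cand, B, seed)
  # sequential oracle: same seeded permutation stream, one lasso_fit per draw
  set.seed(seed)
  perms <- t(vapply(seq_len(B), function(b) sample.int(length(y)), integer(length(y))))
  slow <- integer(8)
  for (b in seq_len(B)) {
    beta <- lasso_fit(y[perms[b, ]], X, lam)$beta
    slow <- slow + (beta[cand$position] != 0)
  }
  expect_identical(fast, as.integer(slow))
  # and the counters are reproducible across calls
  expect_identical(fast, permutation_counters(y, X, lam, cand, B, seed))
})

test_that("a permuted refit has the same selected support as a glmnet refit", {
  skip_if_not_installed("glmnet")
  set.seed(43)
  X <- centred_gaussian(50, 12)
  y <- drop(X %*% c(2, -1.5, rep(0, 10))) + rnorm(50); y <- y - mean(y)
  lam <- lambda_max(y, X) * 0.2
  yp <- y[sample.int(50)]
  ours <- lasso_fit(yp, X, lam)$beta
  theirs <- glmnet_lasso(yp, X, lam)
  expect_identical(which(ours != 0), which(abs(theirs) > 1e-7))
})

test_that("stable selection ranks by counter with the documented tie-breaks", {
  cand <- make_candidates(index = c(4L, 7L, 9L), coef = c(1.0, 0.8, 0.3))
  r <- select_stable(c(0L, 3L, 7L), cand, fanout = 1, B = 10)
  expect_identical(r$selected, 4L)        # argmin counter (gate off at B < 20)
  expect_true(is.na(r$p_value))

  # equal counters fall back to the larger step-1 coefficient
  cand2 <- make_candidates(index = c(4L, 7L, 9L), coef = c(0.8, 1.0, 0.3))
  r2 <- select_stable(c(2L, 2L, 5L), cand2, fanout = 1, B = 10)
  expect_identical(r2$selected, 7L)

  # then to the smaller gene index
  cand3 <- make_candidates(index = c(9L, 4L), coef = c(0.5, 0.5))
  r3 <- select_stable(c(1L, 1L), cand3, fanout = 1, B = 10)
  expect_identical(r3$selected, 4L)

  # fanout larger than the candidate count returns everything, ordered
  r4 <- select_stable(c(5L, 1L, 3L), cand, fanout = 10, B = 10)
  expect_identical(r4$selected, c(7L, 9L, 4L))
})

test_that("the empirical-null gate keeps clear minima and rejects uniform counters", {
  cand <- make_candidates(index = 1:5, coef = seq(1, 0.2, length.out = 5))
  # uniform counters: the smallest is not unusual, p = 1, selection emptied
  r <- select_stable(rep(12L, 5), cand, fanout = 1, B = 100)
  expect_equal(r$p_value, 1)
  expect_length(r$selected, 0L)
  # a uniquely smallest counter is kept with p = 0
  r2 <- select_stable(c(2L, 30L, 31L, 29L, 33L), cand, fanout = 1, B = 100)
  expect_equal(r2$p_value, 0)
  expect_identical(r2$selected, 1L)
  # gate disabled: uniform counters still yield a (tie-broken) selection
  r3 <- select_stable(rep(12L, 5), cand, fanout = 1, B = 100,
                      gate_enabled = FALSE)
  expect_identical(r3$selected, 1L)
  expect_true(is.na(r3$p_value))
  # below the permutation support threshold the gate stays inactive
  r4 <- select_stable(rep(3L, 5), cand, fanout = 1, B = 10)
  expect_length(r4$selected, 1L)
})

test_that("neighbourhood inference composes the two steps and propagates emptiness", {
  set.seed(44)
  x <- standardize(expression_matrix(matrix(rnorm(40 * 8), 40, 8)))
  # a penalty at the global maximum empties step 1, hence the whole result
  lmaxg <- max(vapply(1:8, function(i)
    lambda_max(x$values[, i], x$values[, -i]), numeric(1)))
  r <- infer_neighbourhood(3, x, lmaxg * 1.01, pipeline_config(permutations = 20),
                           seed = 5)
  expect_length(r$candidates, 0L)
  expect_length(r$selected, 0L)
  expect_length(r$counters, 0L)
  expect_identical(r$response_index, 3L)
})

test_that("noiseless chain data recover a true neighbour of the interior gene", {
  for (s in 1:5) {
    cfg <- simulation_config(p = 3, n = 60, noise_sd = 0, seed = s)
    xs <- standardize(simulate_expression(chain3_network(), cfg))
    lam <- as.numeric(estimate_lambda(xs, seed = s))
    r <- infer_neighbourhood(2, xs, lam, pipeline_config(permutations = 100),
                             seed = s)
    expect_gt(length(r$selected), 0)
    expect_true(all(r$selected %in% c(1L, 3L)))
  }
})

test_that("true-parent candidates have stochastically smaller counters than decoys", {
  # multicollinear clones are the motivating pathology: a parent embedded in
  # a correlated pair should still out-rank unrelated candidates
  wins <- 0L; comparisons <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(p = 12, n = 100, collinear_block_size = 3,
                             collinear_rho = 0.95, seed = 200 + s)
    gold <- generate_gold_network(cfg)
    xs <- standardize(simulate_expression(gold, cfg))
    lam <- as.numeric(estimate_lambda(xs, seed = 200 + s))
    truth <- gold$adjacency
    for (i in 1:12) {
      r <- infer_neighbourhood(i, xs, lam, pipeline_config(permutations = 60),
                               seed = 200 + s)
      is_true <- r$candidates %in% which(truth[i, ] == 1)
      if (any(is_true) && any(!is_true)) {
        comparisons <- comparisons + 1L
        rk <- rank(r$counters)
        if (mean(rk[is_true]) <= mean(rk[!is_true])) wins <- wins + 1L
      }
    }
  }
  expect_gt(comparisons, 50)
  expect_lt(binom.test(wins, comparisons, p = 0.5, alternative = "greater")$p.value,
            0.01)
})
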