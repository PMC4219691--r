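#' Count candidate re-selections under response permutation
#'
#' For `b = 1..B`: permutes the response uniformly at random (seeded
#' stream), refits the intercept-free lasso at the same shared `lambda`,
#' and increments the counter of every candidate whose permuted-fit
#' coefficient is non-zero. Permuting the response destroys any genuine
#' association, so candidates that keep being re-selected owe their
#' selection to the predictor-side correlation structure rather than to
#' the response; low counters mark stable associations. Deterministic
#' given `seed`.
#'
#' @param y numeric response vector (centred).
#' @param X_others centred predictor matrix (all genes except the
#'   response).
#' @param lambda shared shrinkage factor from [estimate_lambda()].
#' @param candidates a [select_candidates()] result; an empty candidate
#'   set short-circuits to an empty counter vector.
#' @param B number of permutations (>= 0).
#' @param seed integer seed for the permutation stream.
#' @return Integer vector of counters aligned with the candidates, each in
#'   `[0, B]`.
#' @export
permutation_counters <- function(y, X_others, lambda, candidates, B, seed) {
  stopifnot(inherits(candidates, "candidate_set"))
  B <- as.integer(B)
  if (B < 0) stop2("number of permutations must be non-negative")
  m <- length(candidates$position)
  if (m == 0L) return(integer(0))
  y <- as.numeric(y)
  X_others <- as.matrix(X_others)
  n <- length(y)
  if (B == 0L) return(integer(m))
  # the whole seeded permutation stream is drawn up front, then the refit
  # loop runs in compiled code against the shared Gram matrix
  perms <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  })
  count_permuted_selections(X_others, y, lambda, perms,
                            as.integer(candidates$position), 1e-7, 100000L)
}

#' Select the most stable neighbours and apply the significance gate
#'
#' Sorts the candidates by counter ascending (ties broken by decreasing
#' step-1 absolute coefficient, then ascending gene index) and keeps the
#' first `fanout`. When the gate is enabled and `B` is large enough for
#' the empirical distribution to have support (>= 20 permutations), the
#' p-value of the smallest counter is its left-tail probability under the
#' leave-one-out empirical null — the fraction of the *other* candidates'
#' counters that are less than or equal to it — and the whole selection is
#' emptied when that p-value exceeds `significance_level`. A uniquely
#' smallest counter thus gets p = 0 and survives; uniform counters (the
#' pathological case where collinear candidates are swapped in and out
#' with similar frequency) get p = 1 and always yield an empty selection.
#' A single-candidate set is trivially its own minimum and passes
#' (p = 0).
#'
#' @param counters integer counters from [permutation_counters()],
#'   aligned with `candidates`.
#' @param candidates the [select_candidates()] result the counters refer
#'   to.
#' @param fanout maximum number of neighbours retained (>= 1).
#' @param B number of permutations the counters were accumulated over.
#' @param significance_level gate level (default 0.05).
#' @param gate_enabled apply the empirical-null gate?
#' @return An object of class `stability_result` with elements
#'   `response_index`, `candidates`, `counters`, `B`, `fanout`,
#'   `selected` (gene indices, possibly empty) and `p_value` (`NA` when
#'   the gate is inactive).
#' @export
select_stable <- function(counters, candidates, fanout, B,
                          significance_level = 0.05, gate_enabled = TRUE) {
  stopifnot(inherits(candidates, "candidate_set"))
  m <- length(candidates$index)
  if (length(counters) != m)
    stop2("counters (", length(counters), ") not aligned with candidates (", m, ")")
  fanout <- as.integer(fanout)
  if (fanout < 1) stop2("fanout must be at least 1")
  B <- as.integer(B)
  p_value <- NA_real_
  if (m == 0L) {
    selected <- integer(0)
  } else {
    ord <- order(counters, -abs(candidates$coef), candidates$index)
    selected <- candidates$index[ord[seq_len(min(fanout, m))]]
    if (gate_enabled && B >= 20L) {
      p_value <- if (m == 1L) 0 else
        (sum(counters <= min(counters)) - 1L) / (m - 1L)
      if (p_value > significance_level) selected <- integer(0)
    }
  }
  structure(list(response_index = candidates$response_index,
                 candidates = candidates$index,
                 counters = as.integer(counters),
                 B = B, fanout = fanout,
                 selected = as.integer(selected),
                 p_value = p_value),
            class = "stability_result")
}

#' Infer the stable neighbourhood of one response gene
#'
#' Per-response composition of the two-step procedure: step-1 lasso fit of
#' the response on all remaining genes at the shared `lambda`, truncation
#' to the best candidates, permutation counters, and stable selection with
#' the significance gate. The permutation stream is seeded from
#' `(seed, response_index)` so results do not depend on the order in which
#' response genes are processed or on the worker count.
#'
#' @param response_index index of the response gene in `x`.
#' @param x a standardized [expression_matrix()].
#' @param lambda shared shrinkage factor.
#' @param config a [pipeline_config()] supplying `best_fraction`,
#'   `permutations`, `fanout`, `significance_level` and `gate_enabled`.
#' @param seed global integer seed.
#' @return A `stability_result` whose `candidates` and `selected` entries
#'   are gene indices in `x`.
#' @export
infer_neighbourhood <- function(response_index, x, lambda,
                                config = pipeline_config(), seed) {
  stopifnot(inherits(x, "expression_matrix"), inherits(config, "pipeline_config"))
  X <- x$values
  p <- ncol(X)
  i <- as.integer(response_index)
  if (i < 1L || i > p) stop2("response_index out of range")
  others <- setdiff(seq_len(p), i)
  y <- X[, i]
  Xo <- X[, others, drop = FALSE]
  fit <- lasso_fit(y, Xo, lambda)
  fit$response_index <- i
  cand <- select_candidates(fit, config$best_fraction)
  cand$index <- others[cand$position]   # map predictor columns back to gene indices
  counters <- permutation_counters(y, Xo, lambda, cand, config$permutations,
                                   derive_seed(seed, i))
  select_stable(counters, cand, config$fanout, config$permutations,
                config$significance_level, config$gate_enabled)
}
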