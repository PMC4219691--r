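#' Smallest penalty with an all-zero lasso solution
#'
#' For centred predictors and response, `lambda_max = max_j |x_j' y| / n`
#' is the smallest shrinkage factor at which the intercept-free lasso
#' solution is identically zero; it anchors the cross-validation grid.
#'
#' @param y numeric response vector of length n.
#' @param X_others numeric n x (p-1) predictor matrix.
#' @return A non-negative scalar.
#' @export
lambda_max <- function(y, X_others) {
  X_others <- as.matrix(X_others)
  max(abs(crossprod(X_others, as.numeric(y)))) / length(y)
}

#' Intercept-free lasso regression of one response gene
#'
#' Minimises `(1/(2n)) ||y - X beta||^2 + lambda ||beta||_1` with no
#' intercept term, by cyclic coordinate descent on the Gram matrix
#' (`X'X/n`) with soft-thresholding updates. Inputs are assumed centred
#' (use [standardize()]); the response gene itself must not appear among
#' the predictors.
#'
#' @param y numeric response vector of length n (centred).
#' @param X_others numeric n x (p-1) matrix of the remaining genes (centred
#'   columns).
#' @param lambda positive shrinkage factor.
#' @param tol convergence tolerance on the largest coefficient update per
#'   sweep.
#' @param maxit maximum number of full coordinate sweeps.
#' @return An object of class `lasso_fit` with elements `beta` (named
#'   coefficient vector of length `ncol(X_others)`), `lambda` and
#'   `response_index` (`NA` unless set by the caller).
#' @export
lasso_fit <- function(y, X_others, lambda, tol = 1e-7, maxit = 100000L) {
  y <- as.numeric(y)
  X_others <- as.matrix(X_others)
  if (length(y) != nrow(X_others))
    stop2("response length does not match predictor rows")
  if (!all(is.finite(y)) || !all(is.finite(X_others)))
    stop2("non-finite values in lasso input")
  if (!is.finite(lambda) || lambda <= 0)
    stop2("lambda must be a positive number")
  n <- length(y)
  G <- crossprod(X_others) / n
  cc <- drop(crossprod(X_others, y)) / n
  beta <- cd_lasso_cov(G, cc, lambda, numeric(ncol(X_others)), tol, maxit)
  names(beta) <- colnames(X_others)
  structure(list(beta = beta, lambda = lambda, response_index = NA_integer_),
            class = "lasso_fit")
}

#' Estimate the shared shrinkage factor by cross-validation on a gene subset
#'
#' Draws `ceiling(subset_fraction * p)` response genes without replacement
#' (at least one), and for each runs `cv_folds`-fold cross-validation of
#' the intercept-free lasso over a log-spaced grid of `grid_size` penalty
#' values from that response's `lambda_max` down to `0.001 * lambda_max`,
#' recording the penalty that minimises the mean held-out squared error
#' (ties broken towards the larger penalty). Returns the median of the
#' per-response optima. This single estimate is reused for every response
#' gene and every permutation refit, so cross-validation is paid once.
#'
#' @param x a standardized [expression_matrix()].
#' @param cv_folds number of cross-validation folds (default 3).
#' @param subset_fraction fraction of genes entering cross-validation
#'   (default 0.10).
#' @param grid_size number of penalty values in the log-spaced grid.
#' @param seed integer seed controlling the gene subset and fold draws.
#' @return A positive scalar; attribute `responses` records which genes
#'   entered cross-validation and attribute `lambda_by_response` their
#'   per-response optima.
#' @export
estimate_lambda <- function(x, cv_folds = 3, subset_fraction = 0.10,
                            grid_size = 100, seed) {
  stopifnot(inherits(x, "expression_matrix"))
  if (missing(seed)) stop2("a seed is required")
  X <- x$values
  n <- nrow(X)
  p <- ncol(X)
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2) stop2("cv_folds must be at least 2")
  if (n < cv_folds) stop2("need at least as many samples (", n,
                          ") as folds (", cv_folds, ")")
  if (subset_fraction <= 0 || subset_fraction > 1)
    stop2("subset_fraction must be in (0, 1]")
  n_resp <- max(1L, as.integer(ceiling(subset_fraction * p)))
  with_seed(seed, {
    responses <- sort(sample.int(p, n_resp))
    lam <- vapply(responses, function(i) {
      y <- X[, i]
      Xo <- X[, -i, drop = FALSE]
      lmax <- lambda_max(y, Xo)
      if (lmax <= 0) return(NA_real_)
      grid <- exp(seq(log(lmax), log(0.001 * lmax), length.out = grid_size))
      fold <- sample(rep_len(seq_len(cv_folds), n))
      mse <- matrix(NA_real_, grid_size, cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        ntr <- sum(tr)
        G <- crossprod(Xo[tr, , drop = FALSE]) / ntr
        cc <- drop(crossprod(Xo[tr, , drop = FALSE], y[tr])) / ntr
        Xte <- Xo[!tr, , drop = FALSE]
        yte <- y[!tr]
        b <- numeric(ncol(Xo))
        for (g in seq_len(grid_size)) {   # warm starts down the path
          b <- cd_lasso_cov(G, cc, grid[g], b, 1e-7, 100000L)
          mse[g, f] <- mean((yte - drop(Xte %*% b))^2)
        }
      }
      grid[which.min(rowMeans(mse))]
    }, numeric(1))
    out <- median(lam, na.rm = TRUE)
    if (!is.finite(out)) stop2("lambda estimation failed: all responses degenerate")
    attr(out, "responses") <- responses
    attr(out, "lambda_by_response") <- lam
    out
  })
}

#' Rank and truncate the non-zero lasso coefficients
#'
#' Takes the genes with non-zero coefficients in a step-1 fit, sorts them
#' by decreasing absolute coefficient (ties broken by ascending index) and
#' keeps the first `ceiling(best_fraction * count)` as the candidate set
#' carried into the permutation stage.
#'
#' @param fit a [lasso_fit()].
#' @param best_fraction fraction of the non-zero coefficients retained,
#'   in (0, 1] (default 0.8).
#' @return An object of class `candidate_set` with elements
#'   `response_index`, `index` (candidate identity in the caller's gene
#'   numbering), `position` (column of the predictor matrix) and `coef`
#'   (signed step-1 coefficients), ordered by decreasing `|coef|`.
#' @export
select_candidates <- function(fit, best_fraction = 0.8) {
  stopifnot(inherits(fit, "lasso_fit"))
  if (best_fraction <= 0 || best_fraction > 1)
    stop2("best_fraction must be in (0, 1]")
  nz <- which(fit$beta != 0)
  ord <- nz[order(-abs(fit$beta[nz]), nz)]
  keep <- ord[seq_len(as.integer(ceiling(best_fraction * length(ord))))]
  structure(list(response_index = fit$response_index,
                 index = keep,
                 position = keep,
                 coef = unname(fit$beta[keep])),
            class = "candidate_set")
}
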