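#' Pipeline configuration
#'
#' Collects every tunable parameter of the inference pipeline. The
#' defaults are the benchmark settings: 3-fold cross-validation on 10% of
#' the genes for the shared shrinkage factor, the best 80% of step-1
#' coefficients carried into the permutation stage, fanout 1, 500
#' permutations, significance gate at 0.05, OR symmetrisation.
#'
#' @param cv_folds cross-validation folds for [estimate_lambda()].
#' @param lambda_subset_fraction fraction of genes entering
#'   cross-validation.
#' @param grid_size penalty-grid resolution for cross-validation.
#' @param best_fraction fraction of non-zero step-1 coefficients kept as
#'   candidates.
#' @param fanout maximum number of stable neighbours per response gene.
#' @param permutations number of response permutations B (0 disables the
#'   permutation stage and the gate).
#' @param significance_level level of the empirical-null gate.
#' @param gate_enabled apply the gate (only active when B >= 20)?
#' @param symmetrise_rule symmetrisation rule, see [symmetrise()].
#' @param workers number of parallel workers for the per-gene loop;
#'   results are identical for any worker count.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cv_folds = 3, lambda_subset_fraction = 0.10,
                            grid_size = 100, best_fraction = 0.80,
                            fanout = 1, permutations = 500,
                            significance_level = 0.05, gate_enabled = TRUE,
                            symmetrise_rule = "or", workers = 1) {
  permutations <- as.integer(permutations)
  if (permutations < 0) stop2("permutations must be non-negative")
  fanout <- as.integer(fanout)
  if (fanout < 1) stop2("fanout must be at least 1")
  if (best_fraction <= 0 || best_fraction > 1)
    stop2("best_fraction must be in (0, 1]")
  if (significance_level <= 0 || significance_level >= 1)
    stop2("significance_level must be in (0, 1)")
  symmetrise_rule <- match.arg(symmetrise_rule,
                               c("or", "and", "mean", "max", "min"))
  workers <- as.integer(workers)
  if (workers < 1) stop2("workers must be at least 1")
  structure(list(cv_folds = as.integer(cv_folds),
                 lambda_subset_fraction = lambda_subset_fraction,
                 grid_size = as.integer(grid_size),
                 best_fraction = best_fraction,
                 fanout = fanout,
                 permutations = permutations,
                 significance_level = significance_level,
                 gate_enabled = isTRUE(gate_enabled),
                 symmetrise_rule = symmetrise_rule,
                 workers = workers),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()].
#' @param path path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop2("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to a YAML file
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full network-inference pipeline
#'
#' Standardizes the expression data, estimates the shared shrinkage factor
#' once by cross-validation on a gene subset, infers the stable
#' neighbourhood of every gene (parallelisable across genes), assembles
#' the directed adjacency matrix and symmetrises it. All randomness
#' derives from `seed` through per-task substreams, so the output is
#' identical for any worker count.
#'
#' @param expr an [expression_matrix()] or the path of an expression file
#'   readable by [read_expression_matrix()].
#' @param config a [pipeline_config()].
#' @param seed global integer seed.
#' @param lambda optional shrinkage factor; when supplied the
#'   cross-validation step is skipped (used by [sweep_permutations()]).
#' @param workers parallel worker count, defaulting to `config$workers`.
#' @return An object of class `plnet_result` with elements `network`
#'   (undirected [gene_network()]), `directed` (pre-symmetrisation),
#'   `results` (per-gene `stability_result`s), `lambda`,
#'   `counter_matrix` (p x p matrix of permutation counters, a weighted
#'   diagnostic view of the adjacency), `config`, `seed` and `report`.
#' @export
infer_network <- function(expr, config = pipeline_config(), seed,
                          lambda = NULL, workers = config$workers) {
  if (missing(seed)) stop2("a seed is required")
  if (is.character(expr)) expr <- read_expression_matrix(expr)
  stopifnot(inherits(expr, "expression_matrix"), inherits(config, "pipeline_config"))
  xs <- standardize(expr)
  if (is.null(lambda)) {
    lambda <- estimate_lambda(xs, config$cv_folds,
                              config$lambda_subset_fraction,
                              config$grid_size, seed = derive_seed(seed, 0L))
  }
  p <- ncol(xs$values)
  run_one <- function(i) infer_neighbourhood(i, xs, lambda, config, seed)
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(p), run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(p), run_one)
  }
  failed <- vapply(results, inherits, logical(1), "try-error")
  if (any(failed)) stop2("neighbourhood inference failed for gene(s) ",
                         paste(which(failed), collapse = ", "))
  directed <- assemble_adjacency(results, xs$gene_ids)
  network <- symmetrise(directed, config$symmetrise_rule)
  counter_matrix <- matrix(0, p, p,
                           dimnames = list(xs$gene_ids, xs$gene_ids))
  for (r in results)
    if (length(r$candidates))
      counter_matrix[r$response_index, r$candidates] <- r$counters
  report <- list(
    lambda = as.numeric(lambda),
    n_edges = n_edges(network),
    selection_sizes = vapply(results, function(r) length(r$selected), integer(1)),
    candidate_sizes = vapply(results, function(r) length(r$candidates), integer(1)),
    p_values = vapply(results, function(r) r$p_value, numeric(1)))
  structure(list(network = network, directed = directed, results = results,
                 lambda = as.numeric(lambda), counter_matrix = counter_matrix,
                 config = config, seed = seed, report = report),
            class = "plnet_result")
}

#' @export
print.plnet_result <- function(x, ...) {
  cat(sprintf(paste0("plnet_result: %d genes, %d undirected edges ",
                     "(lambda = %.4g, B = %d, fanout = %d)\n"),
              length(x$network$gene_ids), x$report$n_edges,
              x$lambda, x$config$permutations, x$config$fanout))
  cat(sprintf("  non-empty selections: %d of %d responses\n",
              sum(x$report$selection_sizes > 0), length(x$report$selection_sizes)))
  invisible(x)
}

#' Sweep the permutation number and track network metrics
#'
#' Estimates the shrinkage factor once, then reruns the inference for each
#' value of B, evaluating against a gold standard when one is supplied.
#' Reproduces the connectivity-versus-permutations experiment.
#'
#' @param expr an [expression_matrix()] or expression file path.
#' @param b_values integer vector of permutation numbers.
#' @param config base [pipeline_config()]; its `permutations` entry is
#'   overridden by each `b_values` element in turn.
#' @param seed global integer seed (shared across the sweep, so runs
#'   differ only in B).
#' @param gold optional gold-standard [gene_network()] for evaluation.
#' @return A `data.frame` with one row per B: predicted edge count and,
#'   when `gold` is given, the [evaluate_networks()] metrics.
#' @export
sweep_permutations <- function(expr, b_values = c(0, 50, 200, 500),
                               config = pipeline_config(), seed, gold = NULL) {
  if (missing(seed)) stop2("a seed is required")
  if (is.character(expr)) expr <- read_expression_matrix(expr)
  xs <- standardize(expr)
  lambda <- estimate_lambda(xs, config$cv_folds, config$lambda_subset_fraction,
                            config$grid_size, seed = derive_seed(seed, 0L))
  rows <- lapply(b_values, function(b) {
    cfg <- config
    cfg$permutations <- as.integer(b)
    fit <- infer_network(xs, cfg, seed = seed, lambda = lambda)
    row <- data.frame(B = as.integer(b), edges = fit$report$n_edges,
                      lambda = as.numeric(lambda))
    if (!is.null(gold)) row <- cbind(row, evaluate_networks(fit$network, gold))
    row
  })
  do.call(rbind, rows)
}
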