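#' Configuration for the synthetic benchmark generator
#'
#' Bundles the parameters of the scale-free gold-network generator and of
#' the linear structural-equation expression simulator. Defaults give a
#' strong-but-noisy benchmark: edge coefficients drawn uniformly from
#' +/-[0.5, 1.5], Gaussian noise with standard deviation 0.1 on each
#' non-root gene, and n = 100 samples.
#'
#' @param p number of genes in the gold network (>= 2).
#' @param n number of samples (>= 3).
#' @param attachment_edges edges added per new node during preferential
#'   attachment (>= 1; must be < p). 1 yields a tree.
#' @param coef_low,coef_high positive bounds on the absolute value of the
#'   edge coefficients; the sign of each coefficient is random.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   each non-root gene (>= 0; 0 gives exact linear dependencies).
#' @param collinear_block_size number of extra genes appended as noisy
#'   copies of randomly chosen existing genes (multicollinearity block).
#' @param collinear_rho target correlation between each copy and its
#'   source, in [0, 1).
#' @param seed integer seed; every generator operation is a pure function
#'   of its inputs and this seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(p, n = 100, attachment_edges = 1,
                              coef_low = 0.5, coef_high = 1.5,
                              noise_sd = 0.1,
                              collinear_block_size = 0, collinear_rho = 0,
                              seed) {
  if (missing(seed)) stop2("a seed is required")
  p <- as.integer(p); n <- as.integer(n)
  attachment_edges <- as.integer(attachment_edges)
  collinear_block_size <- as.integer(collinear_block_size)
  if (p < 2) stop2("p must be at least 2")
  if (n < 3) stop2("n must be at least 3")
  if (attachment_edges < 1) stop2("attachment_edges must be at least 1")
  if (!(coef_low > 0 && coef_high > 0 && coef_low <= coef_high))
    stop2("need 0 < coef_low <= coef_high")
  if (noise_sd < 0) stop2("noise_sd must be non-negative")
  if (collinear_block_size < 0) stop2("collinear_block_size must be non-negative")
  if (collinear_rho < 0 || collinear_rho >= 1)
    stop2("collinear_rho must be in [0, 1)")
  structure(list(p = p, n = n, attachment_edges = attachment_edges,
                 coef_low = coef_low, coef_high = coef_high,
                 noise_sd = noise_sd,
                 collinear_block_size = collinear_block_size,
                 collinear_rho = collinear_rho,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a scale-free gold-standard network
#'
#' Draws an undirected connected network on `config$p` nodes by
#' preferential attachment (Barabasi-Albert), adding
#' `config$attachment_edges` edges per incoming node. The resulting degree
#' distribution is right-skewed, emulating the hub structure of curated
#' regulatory networks. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return An undirected [gene_network()] with gene ids `G1..Gp`.
#' @export
generate_gold_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$attachment_edges >= config$p)
    stop2("attachment_edges must be smaller than the number of genes")
  g <- with_seed(derive_seed(config$seed, 1L),
                 igraph::sample_pa(n = config$p, power = 1,
                                   m = config$attachment_edges,
                                   directed = FALSE))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj[adj > 0] <- 1
  gene_network(adj, paste0("G", seq_len(config$p)), directed = FALSE)
}

#' Simulate expression data from a gold network
#'
#' Steady-state surrogate of a kinetic simulator: genes are generated in a
#' topological order of an acyclic orientation of the network. Root genes
#' are standard normal; every other gene is the sum of
#' `coefficient x parent` over its parents plus Gaussian noise with
#' standard deviation `config$noise_sd`, with coefficients drawn uniformly
#' from +/-[coef_low, coef_high]. For an undirected input the orientation
#' comes from a random node ordering fixed by the seed; a directed input
#' must be acyclic and is used as-is. Optionally appends
#' `collinear_block_size` extra genes that are `collinear_rho`-correlated
#' copies of randomly chosen network genes. Deterministic given
#' `config$seed`.
#'
#' @param network a [gene_network()] over `config$p` genes.
#' @param config a [simulation_config()].
#' @return An [expression_matrix()] of dimension
#'   `n x (p + collinear_block_size)`.
#' @export
simulate_expression <- function(network, config) {
  stopifnot(inherits(network, "gene_network"), inherits(config, "simulation_config"))
  adj <- network$adjacency
  p <- length(network$gene_ids)
  if (p != config$p)
    stop2("network has ", p, " genes but config states p = ", config$p)
  n <- config$n
  with_seed(derive_seed(config$seed, 2L), {
    if (network$directed) {
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
      if (!igraph::is_dag(g))
        stop2("directed input network must be acyclic")
      topo_rank <- integer(p)
      topo_rank[as.integer(igraph::topo_sort(g))] <- seq_len(p)
      e <- which(adj == 1, arr.ind = TRUE)
      parent <- e[, 1L]
      child <- e[, 2L]
    } else {
      topo_rank <- sample.int(p)
      e <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
      swap <- topo_rank[e[, 1L]] > topo_rank[e[, 2L]]
      parent <- ifelse(swap, e[, 2L], e[, 1L])
      child <- ifelse(swap, e[, 1L], e[, 2L])
    }
    coefs <- runif(length(parent), config$coef_low, config$coef_high) *
      sample(c(-1, 1), length(parent), replace = TRUE)
    values <- matrix(0, n, p)
    for (i in order(topo_rank)) {
      pa <- which(child == i)
      values[, i] <- if (length(pa) == 0L) {
        rnorm(n)
      } else {
        drop(values[, parent[pa], drop = FALSE] %*% coefs[pa]) +
          rnorm(n, 0, config$noise_sd)
      }
    }
    ids <- network$gene_ids
    m <- config$collinear_block_size
    if (m > 0L) {
      src <- sample.int(p, m, replace = TRUE)
      clones <- matrix(0, n, m)
      for (k in seq_len(m)) {
        z <- values[, src[k]]
        z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
        clones[, k] <- config$collinear_rho * z +
          sqrt(1 - config$collinear_rho^2) * rnorm(n)
      }
      values <- cbind(values, clones)
      ids <- c(ids, sprintf("%s_clone%d", network$gene_ids[src], seq_len(m)))
    }
    expression_matrix(values, gene_ids = ids,
                      sample_ids = paste0("S", seq_len(n)))
  })
}

#' Standardize an expression matrix
#'
#' Centres every gene column to mean zero and scales it to unit standard
#' deviation, with the population (denominator n) convention so that for a
#' standardized design `max_j |x_j' y| / n` is exactly the smallest penalty
#' that zeroes all lasso coefficients. Required before intercept-free
#' lasso fitting. Idempotent.
#'
#' @param x an [expression_matrix()]; every gene must have non-zero variance.
#' @return A standardized [expression_matrix()].
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  centred <- sweep(v, 2L, colMeans(v))
  sd_n <- sqrt(colMeans(centred^2))
  if (any(sd_n < 1e-12)) {
    bad <- x$gene_ids[sd_n < 1e-12]
    stop2("zero-variance gene(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  expression_matrix(sweep(centred, 2L, sd_n, "/"),
                    gene_ids = x$gene_ids, sample_ids = x$sample_ids)
}
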