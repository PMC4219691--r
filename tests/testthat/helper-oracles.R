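# Brute-force betweenness by exhaustive shortest-path enumeration:
# BFS distances from each source, then backward depth-first enumeration of
# every shortest path. Only viable for tiny graphs; used as an independent
# oracle for the Brandes-based implementation.
bf_betweenness <- function(adj) {
  p <- nrow(adj)
  btw <- numeric(p)
  neigh <- lapply(seq_len(p), function(i) which(adj[i, ] == 1))
  dist_from <- function(s) {
    d <- rep(Inf, p)
    d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1L]
      q <- q[-1L]
      for (w in neigh[[v]]) if (!is.finite(d[w])) {
        d[w] <- d[v] + 1
        q <- c(q, w)
      }
    }
    d
  }
  if (p < 3) return(btw)
  for (s in seq_len(p - 1L)) {
    d <- dist_from(s)
    for (t in seq.int(s + 1L, p)) {
      if (!is.finite(d[t])) next
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) {
          paths[[length(paths) + 1L]] <<- acc
          return(invisible(NULL))
        }
        for (u in neigh[[v]]) if (d[u] == d[v] - 1) walk(u, c(u, acc))
      }
      walk(t, integer(0))
      total <- length(paths)
      for (pt in paths) {
        interior <- setdiff(pt, c(s, t))
        btw[interior] <- btw[interior] + 1 / total
      }
    }
  }
  btw
}

# Independent single-lambda lasso oracle via glmnet (the objective uses the
# same (1/(2n)) RSS + lambda*||beta||_1 scaling): fit a path containing the
# target lambda and extract its column.
glmnet_lasso <- function(y, X, lambda) {
  lmax <- max(max(abs(crossprod(X, y))) / length(y), lambda)
  path <- sort(unique(c(lmax * 10^seq(0, -3.5, length.out = 80), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        intercept = FALSE, standardize = FALSE,
                        lambda = path, thresh = 1e-14)
  as.numeric(fit$beta[, which(abs(path - lambda) < 1e-15)[1L]])
}

# n x p matrix with population-sd-1, mean-0 columns
centred_gaussian <- function(n, p) {
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  sweep(X, 2, sqrt(colMeans(X^2)), "/")
}

# directed 3-gene chain A -> B -> C as a gene_network
chain3_network <- function() {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- 1
  adj[2, 3] <- 1
  gene_network(adj, c("A", "B", "C"), directed = TRUE)
}

# random directed binary adjacency with zero diagonal, as a gene_network
random_directed_network <- function(p, density = 0.3) {
  adj <- matrix(rbinom(p * p, 1, density), p, p)
  diag(adj) <- 0
  gene_network(adj, paste0("G", seq_len(p)), directed = TRUE)
}

# hand-built candidate_set for select_stable unit tests
make_candidates <- function(index, coef, response_index = 1L) {
  structure(list(response_index = response_index, index = as.integer(index),
                 position = as.integer(index), coef = coef),
            class = "candidate_set")
}
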