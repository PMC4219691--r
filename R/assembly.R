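#' Assemble the directed adjacency matrix from per-response selections
#'
#' Sets `A[i, j] = 1` exactly when gene `j` belongs to the selected set of
#' response gene `i`. The diagonal stays zero because a response gene is
#' never among its own predictors.
#'
#' @param results list of `stability_result` objects, at most one per
#'   response gene.
#' @param gene_ids gene identifiers of the analysis, or a single integer
#'   gene count (ids then default to `G1..Gp`).
#' @return A directed [gene_network()].
#' @export
assemble_adjacency <- function(results, gene_ids) {
  if (is.numeric(gene_ids) && length(gene_ids) == 1L)
    gene_ids <- paste0("G", seq_len(as.integer(gene_ids)))
  gene_ids <- as.character(gene_ids)
  p <- length(gene_ids)
  resp <- vapply(results, function(r) as.integer(r$response_index), integer(1))
  if (anyDuplicated(resp))
    stop2("duplicate response index in results: ",
          paste(unique(resp[duplicated(resp)]), collapse = ", "))
  if (any(resp < 1L | resp > p)) stop2("response index out of range")
  adj <- matrix(0, p, p, dimnames = list(gene_ids, gene_ids))
  for (r in results) {
    sel <- r$selected
    if (length(sel)) {
      if (any(sel < 1L | sel > p)) stop2("selected gene index out of range")
      adj[r$response_index, sel] <- 1
    }
  }
  gene_network(adj, gene_ids, directed = TRUE)
}

#' Symmetrise a directed network
#'
#' The pipeline default is the OR rule: genes i and j are associated if at
#' least one of the two directed selections is present,
#' `A'[i,j] = A[i,j] | A[j,i]`. The AND rule requires both. The `mean`,
#' `max` and `min` rules operate on edge weights and binarise at strictly
#' positive weight; on binary input `mean` and `max` coincide with OR and
#' `min` with AND. Every rule returns a symmetric matrix with a zero
#' diagonal and is idempotent.
#'
#' @param network a [gene_network()] (binary adjacency).
#' @param rule one of `"or"`, `"and"`, `"mean"`, `"max"`, `"min"`.
#' @return An undirected [gene_network()].
#' @export
symmetrise <- function(network, rule = c("or", "and", "mean", "max", "min")) {
  stopifnot(inherits(network, "gene_network"))
  rule <- match.arg(rule)
  a <- network$adjacency
  ta <- t(a)
  out <- switch(rule,
    or   = (a + ta) > 0,
    and  = (a > 0) & (ta > 0),
    mean = ((a + ta) / 2) > 0,
    max  = pmax(a, ta) > 0,
    min  = pmin(a, ta) > 0)
  out <- out * 1
  diag(out) <- 0
  gene_network(out, network$gene_ids, directed = FALSE)
}
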