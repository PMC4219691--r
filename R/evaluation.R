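#' Confusion counts over unordered gene pairs
#'
#' Compares a predicted undirected network with a gold standard over all
#' `p(p-1)/2` unordered gene pairs. A directed gold standard is first
#' OR-symmetrised; the predicted network must already be undirected. Every
#' pair absent from the gold standard counts as a negative.
#'
#' @param predicted an undirected [gene_network()].
#' @param gold a [gene_network()] over the same genes (directed allowed).
#' @return An object of class `confusion_table` with integer elements
#'   `tp`, `fp`, `fn`, `tn` summing to `p(p-1)/2`.
#' @export
confusion_counts <- function(predicted, gold) {
  stopifnot(inherits(predicted, "gene_network"), inherits(gold, "gene_network"))
  if (!identical(predicted$gene_ids, gold$gene_ids))
    stop2("predicted and gold networks are over different gene sets")
  if (predicted$directed)
    stop2("predicted network must be undirected; apply symmetrise() first")
  if (gold$directed) gold <- symmetrise(gold, "or")
  up <- upper.tri(predicted$adjacency)
  pe <- predicted$adjacency[up] == 1
  ge <- gold$adjacency[up] == 1
  structure(list(tp = sum(pe & ge), fp = sum(pe & !ge),
                 fn = sum(!pe & ge), tn = sum(!pe & !ge)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion_table: TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a correlation
#' between observed and predicted edge indicators in `[-1, 1]` that keeps
#' the abundant true negatives of sparse networks from inflating the
#' score. Any zero factor in the denominator — in particular an empty
#' predicted network — yields 0 by convention.
#'
#' @param ct a [confusion_counts()] result.
#' @return A scalar in `[-1, 1]`.
#' @export
mcc <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  tp <- as.numeric(ct$tp); fp <- as.numeric(ct$fp)
  fn <- as.numeric(ct$fn); tn <- as.numeric(ct$tn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' True positive rate, false positive rate and precision
#'
#' `tpr = TP/(TP+FN)`, `fpr = FP/(FP+TN)`, `precision = TP/(TP+FP)`, with
#' the 0/0 convention resolved to 0.
#'
#' @param ct a [confusion_counts()] result.
#' @return Named list with elements `tpr`, `fpr` and `precision`.
#' @export
rates <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  list(tpr = safe_div(ct$tp, ct$tp + ct$fn),
       fpr = safe_div(ct$fp, ct$fp + ct$tn),
       precision = safe_div(ct$tp, ct$tp + ct$fp))
}

#' Per-gene degree vector
#'
#' @param network an undirected [gene_network()].
#' @return Named numeric vector of per-gene edge counts.
#' @export
degree_vector <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  if (network$directed) stop2("degree_vector expects an undirected network")
  d <- rowSums(network$adjacency)
  names(d) <- network$gene_ids
  d
}

#' Per-gene betweenness centrality
#'
#' Unnormalised betweenness: for each gene v, the sum over unordered node
#' pairs (s, t) with s != v != t of the fraction of shortest s-t paths
#' passing through v (computed with Brandes' algorithm). Pairs with no
#' connecting path contribute 0, so isolated genes score 0.
#'
#' @param network an undirected [gene_network()].
#' @return Named numeric vector of per-gene betweenness values.
#' @export
betweenness_vector <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  if (network$directed) stop2("betweenness_vector expects an undirected network")
  g <- igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  names(b) <- network$gene_ids
  b
}

#' Correlation between two centrality vectors
#'
#' Pearson (default) or Spearman correlation between per-gene centrality
#' vectors of equal length (at least 3). If either vector is constant the
#' correlation is undefined: `NaN` is returned with a warning.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A scalar correlation, or `NaN` when undefined.
#' @export
centrality_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop2("centrality vectors have different lengths (", length(a), " vs ", length(b), ")")
  if (length(a) < 3) stop2("centrality vectors must have length >= 3")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("centrality correlation undefined: constant vector", call. = FALSE)
    return(NaN)
  }
  cor(a, b, method = method)
}

#' Full evaluation report of a predicted network against a gold standard
#'
#' @param predicted an undirected [gene_network()].
#' @param gold a [gene_network()] over the same genes.
#' @param method correlation type for the centrality comparisons.
#' @return One-row `data.frame` with the confusion counts, tpr, fpr,
#'   precision, MCC, degree correlation, betweenness correlation and edge
#'   counts.
#' @export
evaluate_networks <- function(predicted, gold, method = "pearson") {
  ct <- confusion_counts(predicted, gold)
  r <- rates(ct)
  gold_u <- if (gold$directed) symmetrise(gold, "or") else gold
  data.frame(tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
             tpr = r$tpr, fpr = r$fpr, precision = r$precision,
             mcc = mcc(ct),
             degree_correlation = centrality_correlation(
               degree_vector(predicted), degree_vector(gold_u), method),
             betweenness_correlation = centrality_correlation(
               betweenness_vector(predicted), betweenness_vector(gold_u), method),
             edges_predicted = n_edges(predicted),
             edges_gold = n_edges(gold_u))
}
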