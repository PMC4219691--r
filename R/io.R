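#' Expression matrix container
#'
#' Holds an n samples x p genes matrix of expression values together with
#' ordered gene and sample identifiers. Values must be finite, gene
#' identifiers unique, and the dimensions large enough for downstream
#' 3-fold cross-validation (p >= 2, n >= 3).
#'
#' @param values numeric matrix, samples in rows and genes in columns.
#' @param gene_ids character vector of unique gene identifiers (length p).
#' @param sample_ids character vector of sample identifiers (length n).
#' @return An object of class `expression_matrix` with elements `values`,
#'   `gene_ids` and `sample_ids`.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop2("expression values must be numeric")
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != p)
    stop2("gene_ids length (", length(gene_ids), ") does not match gene count (", p, ")")
  if (length(sample_ids) != n)
    stop2("sample_ids length (", length(sample_ids), ") does not match sample count (", n, ")")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop2("duplicate gene identifier(s): ", paste(head(dup, 5L), collapse = ", "))
  if (p < 2) stop2("at least 2 genes are required, found ", p)
  if (n < 3) stop2("at least 3 samples are required for 3-fold cross-validation, found ", n)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop2(sprintf("non-finite expression value for gene '%s', sample '%s'",
                  gene_ids[bad[2L]], sample_ids[bad[1L]]))
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

n_genes <- function(x) length(x$gene_ids)
n_samples <- function(x) length(x$sample_ids)

infer_delimiter <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV file (delimiter inferred from the extension, tab by
#' default, overridable via `delimiter`) with one header line and one
#' identifier column. The default layout is genes in rows: the first column
#' holds gene identifiers and the header holds sample identifiers. The
#' returned matrix is always in canonical samples x genes orientation.
#'
#' @param path path to the delimited text file.
#' @param orientation `"genes-in-rows"` (default) or `"genes-in-columns"`.
#' @param delimiter field separator; `NULL` infers from the file extension.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes-in-rows", "genes-in-columns"),
                                   delimiter = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop2("file not found: ", path)
  delimiter <- delimiter %||% infer_delimiter(path)
  header <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1L]]
  dat <- read.table(path, header = FALSE, sep = delimiter, skip = 1L,
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = NULL, quote = "\"", comment.char = "")
  # header may or may not carry a corner label above the identifier column
  col_ids <- if (length(header) == ncol(dat)) header[-1L] else header
  if (length(col_ids) != ncol(dat) - 1L)
    stop2("header has ", length(header), " fields but data rows have ", ncol(dat))
  row_ids <- dat[[1L]]
  body <- as.matrix(dat[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop2(sprintf("non-numeric value '%s' at row '%s', column '%s' of %s",
                  body[bad[1L], bad[2L]], row_ids[bad[1L]], col_ids[bad[2L]], path))
  }
  if (orientation == "genes-in-rows") {
    expression_matrix(t(num), gene_ids = row_ids, sample_ids = col_ids)
  } else {
    expression_matrix(num, gene_ids = col_ids, sample_ids = row_ids)
  }
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]; writes a header line of sample
#' identifiers and one gene identifier column (genes-in-rows default).
#'
#' @inheritParams read_expression_matrix
#' @param x an [expression_matrix()].
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path,
                                    orientation = c("genes-in-rows", "genes-in-columns"),
                                    delimiter = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(x, "expression_matrix"))
  delimiter <- delimiter %||% infer_delimiter(path)
  if (orientation == "genes-in-rows") {
    m <- t(x$values)
    df <- data.frame(gene = x$gene_ids, m, check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("gene", x$sample_ids)
  } else {
    df <- data.frame(sample = x$sample_ids, x$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("sample", x$gene_ids)
  }
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Gene network container
#'
#' A network over an ordered gene set, stored as a p x p binary adjacency
#' matrix with an all-zero diagonal (self-interactions are excluded by
#' design). Undirected networks must have a symmetric adjacency matrix.
#'
#' @param adjacency p x p matrix with entries in {0, 1}.
#' @param gene_ids character vector of unique gene identifiers.
#' @param directed logical; interpret `adjacency[i, j]` as the directed
#'   selection "gene j chosen as neighbour of response i" when `TRUE`.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(adjacency, gene_ids = rownames(adjacency), directed = FALSE) {
  adjacency <- as.matrix(adjacency)
  p <- nrow(adjacency)
  if (ncol(adjacency) != p) stop2("adjacency matrix must be square")
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(p))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != p)
    stop2("gene_ids length does not match adjacency dimension")
  if (anyDuplicated(gene_ids)) stop2("gene identifiers must be unique")
  storage.mode(adjacency) <- "double"
  if (!all(adjacency %in% c(0, 1)))
    stop2("adjacency entries must be 0 or 1")
  if (any(diag(adjacency) != 0))
    stop2("adjacency diagonal must be zero: self-interactions are excluded")
  if (!directed && !identical(all.equal(adjacency, t(adjacency)), TRUE))
    stop2("undirected network requires a symmetric adjacency matrix")
  dimnames(adjacency) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, adjacency = adjacency,
                 directed = isTRUE(directed)),
            class = "gene_network")
}

#' Number of edges in a network
#'
#' Directed networks count arcs; undirected networks count unordered pairs.
#' @param network a [gene_network()].
#' @return Integer edge count.
#' @export
n_edges <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  s <- sum(network$adjacency)
  as.integer(if (network$directed) s else s / 2)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d %s edges\n", length(x$gene_ids),
              n_edges(x), if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Read a gold-standard network from an edge list
#'
#' Parses a 2- or 3-column TSV edge list (source, target, optional
#' weight/indicator). Rows whose third column is 0 are explicit negatives
#' and contribute no edge; rows with a non-zero third column, or no third
#' column at all, are present edges. Self-edges are skipped with a warning.
#' The node set is restricted to `gene_ids`, in that order; an edge naming
#' an unknown gene is an error.
#'
#' @param path path to the edge-list file (may be empty).
#' @param gene_ids ordered gene identifiers defining the analysis index.
#' @return A directed [gene_network()] over `gene_ids`.
#' @export
read_gold_network <- function(path, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop2("gene identifiers must be unique")
  if (!file.exists(path)) stop2("file not found: ", path)
  p <- length(gene_ids)
  adj <- matrix(0, p, p, dimnames = list(gene_ids, gene_ids))
  if (file.size(path) > 0) {
    df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                     quote = "", comment.char = "")
    if (!ncol(df) %in% 2:3)
      stop2("edge list must have 2 or 3 columns, found ", ncol(df))
    src <- as.character(df[[1L]])
    tgt <- as.character(df[[2L]])
    w <- if (ncol(df) == 3L) suppressWarnings(as.numeric(df[[3L]])) else rep(1, nrow(df))
    if (anyNA(w)) stop2("non-numeric weight in edge list column 3")
    unknown <- setdiff(c(src, tgt), gene_ids)
    if (length(unknown))
      stop2("edge list references unknown gene id(s): ",
            paste(head(unknown, 5L), collapse = ", "))
    self <- src == tgt
    if (any(self))
      warning(sum(self), " self-edge row(s) skipped: self-interactions are excluded",
              call. = FALSE)
    keep <- !self & w != 0
    if (any(keep))
      adj[cbind(match(src[keep], gene_ids), match(tgt[keep], gene_ids))] <- 1
  }
  gene_network(adj, gene_ids, directed = TRUE)
}

#' Write a network as a 3-column edge list
#'
#' Emits `source<TAB>target<TAB>1` lines. Undirected networks write each
#' unordered pair once, with the lexicographically smaller gene identifier
#' as the source. An empty network yields an empty file (the optional
#' header is off by default).
#'
#' @param network a [gene_network()].
#' @param path output path.
#' @param header write a `source target weight` header line?
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, header = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  idx <- which(network$adjacency == 1, arr.ind = TRUE)
  src <- network$gene_ids[idx[, 1L]]
  tgt <- network$gene_ids[idx[, 2L]]
  if (!network$directed) {
    keep <- src < tgt
    src <- src[keep]
    tgt <- tgt[keep]
  }
  o <- order(src, tgt)
  df <- data.frame(source = src[o], target = tgt[o],
                   weight = rep(1L, length(o)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(path)
}
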