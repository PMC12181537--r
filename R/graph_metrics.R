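#' Threshold a connectivity matrix into a binary undirected network
#'
#' Negative entries are discarded, then the `K = round(sparsity * R(R-1)/2)`
#' strongest positive upper-triangle entries become edges. Ties at the cut are
#' resolved deterministically: among equal-valued entries, those with the
#' smaller (row, column) index are kept.
#'
#' @param m A [connectivity_matrix()] or symmetric numeric matrix.
#' @param sparsity Fraction of possible edges to keep, in (0, 1); default 0.1.
#' @param source_kind Recorded provenance, `"fc"` or `"sc"`; taken from the
#'   input when it is a `connectivity_matrix`.
#' @return An object of class `binary_network` with fields `adjacency`
#'   (binary symmetric, zero diagonal), `sparsity`, and `source_kind`.
#' @export
binarize_sparsity <- function(m, sparsity = 0.1, source_kind = NULL) {
  stopifnot(is.numeric(sparsity), length(sparsity) == 1,
            sparsity > 0, sparsity < 1)
  if (is.null(source_kind) && inherits(m, "connectivity_matrix")) {
    source_kind <- m$kind
  }
  vals <- conn_values(m)
  R <- nrow(vals)
  stopifnot(R == ncol(vals))
  n_possible <- R * (R - 1) / 2
  K <- round(sparsity * n_possible)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  w <- vals[ut]
  pos <- w > 0
  if (sum(pos) < K) {
    stop("only ", sum(pos), " positive entries; requested sparsity ", sparsity,
         " needs ", K, " edges (achievable sparsity ",
         signif(sum(pos) / n_possible, 4), ")")
  }
  # strongest first; ties broken toward smaller (row, col)
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(K)]
  adj <- matrix(0L, R, R)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(vals)
  structure(list(adjacency = adj, sparsity = sparsity,
                 source_kind = source_kind %||% "fc"),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %.3g, source %s)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$sparsity, x$source_kind))
  invisible(x)
}

net_adjacency <- function(net) {
  if (inherits(net, "binary_network")) net$adjacency else net
}

net_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net_adjacency(net), mode = "undirected",
                                      diag = FALSE)
}

#' Nodal betweenness centrality
#'
#' Fraction of shortest paths between all other node pairs that pass through
#' each node, normalized by `(R - 1)(R - 2) / 2` (the number of unordered
#' pairs). Unreachable pairs contribute zero.
#'
#' @param net A `binary_network` (or binary symmetric adjacency matrix).
#' @return Numeric vector of length R, in \[0, 1\].
#' @export
nodal_betweenness <- function(net) {
  g <- net_graph(net)
  n <- igraph::vcount(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (n > 2) b <- 2 * b / ((n - 1) * (n - 2))
  unname(b)
}

#' Nodal degree centrality
#'
#' @param net A `binary_network` (or binary symmetric adjacency matrix).
#' @return Integer vector of edge counts per node.
#' @export
nodal_degree <- function(net) {
  unname(rowSums(net_adjacency(net)))
}

#' Nodal efficiency
#'
#' Inverse harmonic mean of shortest-path lengths from each node to all
#' others: `eff(v) = mean over u != v of 1 / d(v, u)`, with unreachable nodes
#' contributing zero.
#'
#' @param net A `binary_network` (or binary symmetric adjacency matrix).
#' @return Numeric vector in \[0, 1\].
#' @export
nodal_efficiency <- function(net) {
  g <- net_graph(net)
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  unname(rowSums(inv) / (n - 1))
}

#' Nodal clustering coefficient
#'
#' Proportion of each node's neighbour pairs that are themselves connected;
#' nodes with fewer than two neighbours get 0.
#'
#' @param net A `binary_network` (or binary symmetric adjacency matrix).
#' @return Numeric vector in \[0, 1\].
#' @export
nodal_clustering <- function(net) {
  g <- net_graph(net)
  unname(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' All four nodal graph metrics
#'
#' @param net A `binary_network`.
#' @return Data frame with columns `betweenness`, `degree`, `efficiency`,
#'   `clustering`, one row per node.
#' @export
nodal_metrics <- function(net) {
  data.frame(betweenness = nodal_betweenness(net),
             degree = nodal_degree(net),
             efficiency = nodal_efficiency(net),
             clustering = nodal_clustering(net))
}
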