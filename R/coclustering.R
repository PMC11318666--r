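#' Build the contact graph of a distance matrix
#'
#' Bins form an undirected network: there is an edge between `i` and `j`
#' (`i != j`) exactly where `D_ij` is finite, i.e. where a contact was
#' observed (`F_ij > 0`).  No self loops.
#'
#' @param D a `DistanceMatrix` from [freq_to_dist()].
#' @return object of class `ContactGraph`: `n_nodes` and logical
#'   `adjacency` matrix.
#' @export
build_graph <- function(D) {
  stopifnot(inherits(D, "DistanceMatrix"))
  A <- is.finite(D$D) & D$D > 0
  diag(A) <- FALSE
  structure(list(n_nodes = D$n_bins, adjacency = A), class = "ContactGraph")
}

#' @export
print.ContactGraph <- function(x, ...) {
  cat("ContactGraph:", x$n_nodes, "nodes,",
      sum(x$adjacency[upper.tri(x$adjacency)]), "edges\n")
  invisible(x)
}

#' Clustering coefficient of one node
#'
#' `CC_i = 2 e_i / (k_i (k_i - 1))` where `k_i` is the number of
#' neighbours of node `i` and `e_i` the number of edges among those
#' neighbours.  Defined as 0 when `k_i <= 1` (no clustering evidence).
#'
#' @param g a [build_graph()] result.
#' @param i node index (1-based).
#' @return clustering coefficient in `[0, 1]`.
#' @export
node_clustering <- function(g, i) {
  stopifnot(inherits(g, "ContactGraph"))
  if (i < 1 || i > g$n_nodes) stop("node index out of range: ", i)
  nb <- which(g$adjacency[i, ])
  k <- length(nb)
  if (k <= 1) return(0)
  e <- sum(g$adjacency[nb, nb]) / 2
  2 * e / (k * (k - 1))
}

#' Co-clustering coefficient of a node pair
#'
#' Let `U_ij = N_i` union `N_j` (the two neighbour sets; when `i` and `j`
#' are adjacent each belongs to the other's set and hence to `U_ij`),
#' `k_ij = |U_ij|`, and `e_ij` the number of graph edges with both
#' endpoints in `U_ij` (the edge `(i,j)` itself counts when both ends lie
#' in the union).  Then `coCC_ij = 2 e_ij / (k_ij (k_ij - 1))`, or 0 when
#' `k_ij <= 1`.
#'
#' @param g a [build_graph()] result.
#' @param i,j distinct node indices (1-based).
#' @return co-clustering coefficient in `[0, 1]`.
#' @export
cocc_pair <- function(g, i, j) {
  stopifnot(inherits(g, "ContactGraph"))
  if (i == j) stop("co-clustering coefficient requires two distinct nodes")
  if (min(i, j) < 1 || max(i, j) > g$n_nodes)
    stop("node index out of range")
  U <- which(g$adjacency[i, ] | g$adjacency[j, ])
  k <- length(U)
  if (k <= 1) return(0)
  e <- sum(g$adjacency[U, U]) / 2
  2 * e / (k * (k - 1))
}

#' Co-clustering coefficient matrix
#'
#' Computes [cocc_pair()] for every unordered pair of bins.  The weights
#' depend only on the input contact graph, so the matrix is computed once
#' before optimization and held fixed throughout the iteration.
#'
#' @param g a [build_graph()] result.
#' @return object of class `CoCCMatrix` with symmetric `values` in
#'   `[0, 1]` (diagonal unused, stored 0).
#' @export
cocc_matrix <- function(g) {
  stopifnot(inherits(g, "ContactGraph"))
  V <- cocc_matrix_cpp(g$adjacency)
  structure(list(values = V, n_bins = g$n_nodes), class = "CoCCMatrix")
}

#' @export
print.CoCCMatrix <- function(x, ...) {
  ut <- x$values[upper.tri(x$values)]
  cat("CoCCMatrix:", x$n_bins, "bins, mean coCC =",
      signif(mean(ut), 4), "\n")
  invisible(x)
}
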