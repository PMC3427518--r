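#' Simple undirected graphs
#'
#' `pin_graph()` constructs the light-weight undirected-graph container used
#' throughout the package: `n_nodes` labelled nodes `1..n` and a set of
#' unordered edges.  Self-loops and duplicate edges are rejected; isolated
#' (degree-zero) nodes are first-class citizens because the node-sampling
#' model produces them.
#'
#' @param n_nodes Number of nodes (nonnegative integer).  Nodes are the
#'   integers `1..n_nodes`.
#' @param edges Two-column integer matrix (or empty) of node pairs, one row
#'   per undirected edge.  Order within a row is irrelevant.
#' @return An object of class `pin_graph`: a list with elements `n` and
#'   `edges` (canonicalised so each row has `edges[, 1] < edges[, 2]`).
#' @examples
#' g <- pin_graph(3, rbind(c(1, 2), c(2, 3)))
#' n_edges(g)
#' degrees(g)
#' @export
pin_graph <- function(n_nodes, edges = NULL) {
  n <- as.integer(n_nodes)
  if (length(n) != 1L || is.na(n) || n < 0L) {
    stop("`n_nodes` must be a single nonnegative integer", call. = FALSE)
  }
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (anyNA(edges)) stop("edges contain missing values", call. = FALSE)
  if (nrow(edges) > 0L) {
    if (min(edges) < 1L || max(edges) > n) {
      stop("edge endpoints must lie in 1..", n, call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, 2:1]
    key <- (edges[, 1L] - 1) * as.double(n) + edges[, 2L]
    if (anyDuplicated(key)) stop("duplicate edges are not allowed", call. = FALSE)
  }
  structure(list(n = n, edges = edges), class = "pin_graph")
}

#' @export
print.pin_graph <- function(x, ...) {
  cat("<pin_graph> ", x$n, " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @rdname pin_graph
#' @param g A `pin_graph`.
#' @export
n_nodes <- function(g) {
  stopifnot(inherits(g, "pin_graph"))
  g$n
}

#' @rdname pin_graph
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "pin_graph"))
  nrow(g$edges)
}

#' @rdname pin_graph
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "pin_graph"))
  tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = g$n)
}

#' Adjacency matrix of a graph
#'
#' Returns the dense symmetric 0/1 adjacency matrix with zero diagonal; this
#' is the complete representation of the network that the spectral distance
#' operates on (rather than a summary statistic of it).
#'
#' @param g A [pin_graph].
#' @return A `n x n` numeric matrix.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "pin_graph"))
  A <- matrix(0, g$n, g$n)
  if (nrow(g$edges) > 0L) {
    A[g$edges] <- 1
    A[g$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Adjacency spectrum
#'
#' Eigenvalues of the adjacency matrix, sorted in descending order.  The
#' spectrum is invariant under any relabelling of the nodes, which is what
#' makes it usable as a comparison of unlabelled networks; its sum is zero
#' (the adjacency matrix is hollow).
#'
#' @param g A [pin_graph].
#' @return Numeric vector of length `n_nodes(g)`, descending.
#' @export
graph_spectrum <- function(g) {
  stopifnot(inherits(g, "pin_graph"))
  if (g$n == 0L) return(numeric(0))
  ev <- eigen(adjacency_matrix(g), symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

#' Empirical degree distribution
#'
#' Fraction of nodes at each degree, degree zero included.
#'
#' @param g A [pin_graph] with at least one node.
#' @return A tibble with columns `degree` (0 .. max degree) and
#'   `probability`, summing to 1.
#' @export
degree_distribution <- function(g) {
  stopifnot(inherits(g, "pin_graph"))
  if (g$n == 0L) stop("degree distribution of an empty graph is undefined", call. = FALSE)
  d <- degrees(g)
  counts <- tabulate(d + 1L, nbins = max(d) + 1L)
  tibble::tibble(degree = 0:max(d), probability = counts / g$n)
}

#' Relabel the nodes of a graph
#'
#' @param g A [pin_graph].
#' @param perm Integer permutation of `1:n_nodes(g)`; node `i` becomes
#'   `perm[i]`.
#' @return A `pin_graph` isomorphic to `g`.
#' @export
permute_nodes <- function(g, perm) {
  stopifnot(inherits(g, "pin_graph"))
  perm <- as.integer(perm)
  if (length(perm) != g$n || !all(sort(perm) == seq_len(g$n))) {
    stop("`perm` must be a permutation of 1..n", call. = FALSE)
  }
  e <- g$edges
  e[] <- perm[e]
  pin_graph(g$n, e)
}

#' Convert to an igraph object
#'
#' @param g A [pin_graph].
#' @return An `igraph` graph (requires the igraph package).
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "pin_graph"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for `as_igraph()`", call. = FALSE)
  }
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges) > 0L) ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  ig
}

# integer keys identifying undirected edges of an n-node graph
.edge_keys <- function(g) {
  if (nrow(g$edges) == 0L) return(double(0))
  (g$edges[, 1L] - 1) * as.double(g$n) + g$edges[, 2L]
}
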