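#' Spectral lower bound on graph edit distance
#'
#' The data-comparison metric of the ABC sampler: the Euclidean distance
#' between the descending-ordered adjacency spectra of two graphs,
#' \deqn{d(A, B) = \sqrt{\sum_i (\alpha_i - \beta_i)^2},}
#' which by Umeyama's theorem is a lower bound on the permutation-minimised
#' edit distance between the (unlabelled) graphs, on the scale that counts
#' each differing undirected edge twice (once per ordered node pair).  It is
#' exactly zero for isomorphic graphs and is cheap enough to compare networks
#' for which enumerating node correspondences is hopeless.
#'
#' @param g1,g2 [pin_graph] objects (or, for `g2`, a precomputed descending
#'   spectrum as returned by [graph_spectrum()] — useful when one network is
#'   compared against many simulations).
#' @param pad If `TRUE`, graphs of unequal size are compared by padding the
#'   shorter spectrum with zeros.  The default (`FALSE`) treats a size
#'   mismatch as an error, because simulated networks are grown or sampled to
#'   the observed network's size and a mismatch normally indicates user
#'   error.
#' @return Nonnegative number.
#' @seealso [labelled_edit_distance()], [min_edit_distance()]
#' @export
spectral_distance <- function(g1, g2, pad = FALSE) {
  s1 <- if (inherits(g1, "pin_graph")) graph_spectrum(g1) else as.numeric(g1)
  s2 <- if (inherits(g2, "pin_graph")) graph_spectrum(g2) else as.numeric(g2)
  if (length(s1) != length(s2)) {
    if (!pad) {
      stop("graphs have different node counts (", length(s1), " vs ",
           length(s2), "); grow or sample to a common size, or set pad = TRUE",
           call. = FALSE)
    }
    d <- abs(length(s1) - length(s2))
    if (length(s1) < length(s2)) s1 <- sort(c(s1, rep(0, d)), decreasing = TRUE)
    else s2 <- sort(c(s2, rep(0, d)), decreasing = TRUE)
  }
  sqrt(sum((s1 - s2)^2))
}

#' Edit distance between two labelled graphs
#'
#' Number of differing adjacency-matrix entries under the identity node
#' correspondence.  Each undirected edge present in one graph but not the
#' other contributes 2 (its two ordered entries), so the value is always an
#' even integer and lives on the same scale as [spectral_distance()].
#'
#' @param g1,g2 [pin_graph] objects with equal node counts.
#' @return Nonnegative even integer.
#' @export
labelled_edit_distance <- function(g1, g2) {
  stopifnot(inherits(g1, "pin_graph"), inherits(g2, "pin_graph"))
  if (g1$n != g2$n) {
    stop("graphs have different node counts (", g1$n, " vs ", g2$n, ")",
         call. = FALSE)
  }
  k1 <- .edge_keys(g1)
  k2 <- .edge_keys(g2)
  2L * (sum(!(k1 %in% k2)) + sum(!(k2 %in% k1)))
}

#' Permutation-minimised edit distance (exhaustive oracle)
#'
#' Minimum of [labelled_edit_distance()] over every relabelling of `g2`.
#' Enumeration over all `n!` permutations restricts it to tiny graphs; it
#' exists as the exact reference against which the spectral lower bound is
#' validated, not as a production distance.
#'
#' @param g1,g2 [pin_graph] objects with equal node counts, at most
#'   `max_nodes` nodes.
#' @param max_nodes Enumeration guard (default 8).
#' @return Nonnegative even integer, `<= labelled_edit_distance(g1, g2)`.
#' @export
min_edit_distance <- function(g1, g2, max_nodes = 8L) {
  stopifnot(inherits(g1, "pin_graph"), inherits(g2, "pin_graph"))
  if (g1$n != g2$n) {
    stop("graphs have different node counts (", g1$n, " vs ", g2$n, ")",
         call. = FALSE)
  }
  if (g1$n > max_nodes) {
    stop("exhaustive edit distance enumerates n! permutations and is ",
         "intended for validation on graphs of at most ", max_nodes,
         " nodes", call. = FALSE)
  }
  if (g1$n == 0L) return(0L)
  A <- adjacency_matrix(g1)
  B <- adjacency_matrix(g2)
  best <- Inf
  for (perm in .permutations(g1$n)) {
    d <- sum(abs(A - B[perm, perm, drop = FALSE]))
    if (d < best) best <- d
  }
  as.integer(best)
}

# all permutations of 1..n as a list of integer vectors
.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}
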